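#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks for ties). Fails
#' explicitly on constant input, where the coefficient is undefined.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return rho in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("at least 3 observations required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("Spearman correlation undefined for a constant vector")
  stats::cor(x, y, method = "spearman")
}

# Weighted overlap of two rankings: positions pos_a, pos_b are descending
# ranks (1 = largest value). With N items and weights w_n = exp(-beta n),
# score = sum_n w_n * (|topA_n ^ topB_n| + |botA_n ^ botB_n|); an item is in
# both top-n lists for all n >= max(pos_a, pos_b), so the overlap curve is a
# cumulative histogram of pairwise max positions.
ordered_list_score <- function(pos_a, pos_b, w, two_sided_ends = TRUE) {
  N <- length(pos_a)
  top <- cumsum(tabulate(pmax(pos_a, pos_b), N))
  sc <- sum(w * top)
  if (two_sided_ends) {
    bot <- cumsum(tabulate(pmax(N + 1L - pos_a, N + 1L - pos_b), N))
    sc <- sc + sum(w * bot)
  }
  sc
}

#' Weighted ordered-list similarity with a permutation null
#'
#' Both value lists are ranked in decreasing order and compared through an
#' exponentially weighted overlap of their top-n (and, by default, also
#' bottom-n) sets: score = sum over n of exp(-beta n) times the overlap
#' sizes. More weight therefore falls on the extremes of the lists. The
#' null distribution is obtained by scoring `n_perm` random permutations of
#' the second list's order; the empirical p-value uses the +1 correction so
#' it can never be 0.
#'
#' @param values_a,values_b named numeric vectors over the same identifier
#'   universe.
#' @param beta weight decay > 0; the default `log(100)/100` keeps the
#'   effective weight above 0.01 over roughly the top 100 ranks.
#' @param n_perm number of permutations (default 1000).
#' @param two_sided_ends include the bottom-of-list overlap term.
#' @param seed integer seed for the permutation null.
#' @return `ordered_list_sim`: list with `score`, `null_scores`, `p_value`,
#'   `beta`, `n_perm`, `two_sided_ends`.
#' @export
ordered_list_similarity <- function(values_a, values_b,
                                    beta = log(100) / 100, n_perm = 1000,
                                    two_sided_ends = TRUE, seed = 1) {
  if (beta <= 0) stop("beta must be > 0")
  if (is.null(names(values_a)) || is.null(names(values_b)) ||
      !setequal(names(values_a), names(values_b)))
    stop("both lists must be named over the same identifier universe")
  ids <- sort(names(values_a))
  a <- values_a[ids]; b <- values_b[ids]
  N <- length(ids)
  pos_a <- rank(-a, ties.method = "first")
  pos_b <- rank(-b, ties.method = "first")
  w <- exp(-beta * seq_len(N))
  score <- ordered_list_score(pos_a, pos_b, w, two_sided_ends)
  if (!is.null(seed)) set.seed(seed)
  null_scores <- vapply(seq_len(n_perm), function(i)
    ordered_list_score(pos_a, sample(N), w, two_sided_ends), numeric(1))
  p <- (1 + sum(null_scores >= score)) / (n_perm + 1)
  structure(list(score = score, null_scores = null_scores, p_value = p,
                 beta = beta, n_perm = n_perm,
                 two_sided_ends = two_sided_ends),
            class = "ordered_list_sim")
}

#' @export
print.ordered_list_sim <- function(x, ...) {
  cat(sprintf(
    "ordered-list similarity: score %.4f (null mean %.4f), p = %.4g (beta %.3g, %d perms)\n",
    x$score, mean(x$null_scores), x$p_value, x$beta, x$n_perm))
  invisible(x)
}

#' Pairwise replicate concordance
#'
#' Spearman correlation of normalized concentrations between every pair of
#' libraries, restricted for each pair to the miRNAs with a nonzero count
#' in both libraries. Used to check that differently indexed technical
#' replicates agree.
#'
#' @param ct a `count_table`.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
replicate_concordance <- function(ct) {
  if (ncol(ct$counts) < 2) stop("at least 2 libraries required")
  conc <- normalize_geometric(ct)$concentration
  libs <- colnames(conc)
  n <- length(libs)
  out <- diag(1, n)
  dimnames(out) <- list(libs, libs)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    both <- ct$counts[, i] > 0 & ct$counts[, j] > 0
    out[i, j] <- out[j, i] <- spearman_rho(conc[both, i], conc[both, j])
  }
  out
}
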