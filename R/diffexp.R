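#' Geometric-mean library normalization
#'
#' Library size factors are each library's total divided by the geometric
#' mean of all totals. The reported "count concentration" is the count
#' divided by `factor * geometric mean` (equivalently, the within-library
#' proportion), matching the normalized expression-level semantics of
#' exact-test count analyses. A log2 view with pseudo-count 0.5 on the
#' size-equalized counts is also returned.
#'
#' @param ct a `count_table`.
#' @return list with `factors`, `geo_mean`, `concentration` (matrix),
#'   `equalized` (counts scaled to the geometric-mean library size),
#'   `log2_concentration`.
#' @export
normalize_geometric <- function(ct) {
  counts <- ct$counts
  totals <- colSums(counts)
  if (any(totals == 0)) {
    warning("excluding ", sum(totals == 0), " zero-total library(ies)")
    counts <- counts[, totals > 0, drop = FALSE]
    totals <- totals[totals > 0]
  }
  if (!length(totals)) stop("no library with positive total")
  gm <- exp(mean(log(totals)))
  factors <- totals / gm
  concentration <- sweep(counts, 2, factors * gm, "/")
  equalized <- sweep(counts, 2, factors, "/")
  list(factors = factors, geo_mean = gm,
       concentration = concentration,
       equalized = equalized,
       log2_concentration = log2(sweep(counts + 0.5, 2, factors * gm, "/")))
}

#' Method-of-moments common dispersion
#'
#' A single dispersion phi (variance = mu + phi mu^2) shared across miRNAs,
#' estimated from within-group moments of size-equalized counts:
#' phi-hat = sum(v - c m) / sum(m^2 - v/n), where m and v are the per-miRNA
#' within-group sample mean and variance of equalized counts, c corrects
#' for the Poisson-level variance inflation of dividing by size factors,
#' and the denominator is the unbiased estimate of mu^2. Floored at 0.
#'
#' Features holding more than `max_share` of all counts are excluded from
#' the moment sums: under a fixed per-library sequencing total the
#' within-library variance of a dominant feature is compositionally
#' suppressed (by roughly `(1 - share)^2`), and because the sums are
#' mu^2-weighted a single such feature would drag the common dispersion
#' towards zero for every other feature.
#'
#' @param ct a `count_table`.
#' @param max_share largest count share a feature may hold and still enter
#'   the moment sums (default 0.05); ignored when fewer than 20 features
#'   would remain.
#' @return list with `phi` (>= 0) and `method`.
#' @export
estimate_common_dispersion <- function(ct, max_share = 0.05) {
  norm <- normalize_geometric(ct)
  z <- norm$equalized
  groups <- ct$groups[colnames(z)]
  share <- rowSums(z) / sum(z)
  small <- share <= max_share
  if (sum(small) < 20) small <- rep(TRUE, length(share))
  num <- 0; den <- 0; any_rep <- FALSE
  for (g in unique(groups)) {
    sel <- groups == g
    n <- sum(sel)
    if (n < 2) next
    any_rep <- TRUE
    zg <- z[small, sel, drop = FALSE]
    m <- rowMeans(zg)
    v <- apply(zg, 1, stats::var)
    cc <- mean(1 / norm$factors[sel])
    use <- m > 0
    num <- num + sum(v[use] - cc * m[use])
    den <- den + sum(pmax(m[use]^2 - v[use] / n, 0))
  }
  if (!any_rep) {
    warning("no group has replicates; dispersion set to 0")
    return(list(phi = 0, method = "moments"))
  }
  list(phi = max(0, if (den > 0) num / den else 0), method = "moments")
}

#' Two-group negative-binomial exact test
#'
#' Conditions on the total s = y1 + y2 of the two groups' size-equalized
#' count sums and enumerates all splits (a, s - a). Under a shared
#' relative abundance, group totals are NB with means n_g * mu and sizes
#' n_g / phi (mu estimated as s / (n1 + n2)); the two-sided p-value is the
#' total conditional probability of all splits no more likely than the
#' observed one, in direct analogy to Fisher's exact test. At phi = 0 the
#' conditional law is exactly Binomial(s, n1 / (n1 + n2)).
#'
#' @param y1_total,y2_total group-summed equalized counts (rounded to
#'   integers internally).
#' @param n1,n2 number of libraries per group.
#' @param phi common dispersion (>= 0).
#' @return two-sided p-value in (0, 1].
#' @export
nb_exact_test <- function(y1_total, y2_total, n1, n2, phi = 0) {
  stopifnot(y1_total >= 0, y2_total >= 0, n1 >= 1, n2 >= 1, phi >= 0)
  y1 <- round(y1_total); y2 <- round(y2_total)
  s <- y1 + y2
  if (s == 0) return(1)
  a <- 0:s
  if (phi == 0) {
    logp <- stats::dbinom(a, s, n1 / (n1 + n2), log = TRUE)
  } else {
    mu <- s / (n1 + n2)
    logp <- stats::dnbinom(a, size = n1 / phi, mu = n1 * mu, log = TRUE) +
      stats::dnbinom(s - a, size = n2 / phi, mu = n2 * mu, log = TRUE)
  }
  obs <- logp[y1 + 1L]
  pr <- exp(logp - max(logp))
  min(1, sum(pr[logp <= obs + 1e-10]) / sum(pr))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control: q_i is the smallest
#' p_(k) * m / k over all k with p_(k) >= p_i, capped at 1. Reported
#' alongside exact-test p-values but not used as the default selection
#' criterion.
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @return q-values in the input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Exact-test differential expression table
#'
#' Per-miRNA two-group comparison on the union of the groups' detected
#' sets: concentrations per group, log2 fold change (pseudo-count 0.5 on
#' mean equalized counts), NB exact-test p-value on group-summed equalized
#' counts, and BH q-value. Significance is flagged at `p < alpha` without
#' multiple-testing selection; q-values are reported alongside.
#'
#' @param ct a `count_table` with exactly two groups.
#' @param phi common dispersion; NULL estimates it with
#'   [estimate_common_dispersion()].
#' @param alpha significance threshold (default 0.05).
#' @return data.frame of class `de_table` with columns `mirna`, `conc_g1`,
#'   `conc_g2`, `logFC`, `p_value`, `bh_q`, `significant`, `direction`,
#'   `platform`; attribute `groups` gives the group order (logFC is
#'   log2(group2 / group1)).
#' @export
de_table <- function(ct, phi = NULL, alpha = 0.05) {
  grp_levels <- unique(ct$groups)
  if (length(grp_levels) != 2) stop("exactly two groups required")
  if (is.null(phi)) phi <- estimate_common_dispersion(ct)$phi
  norm <- normalize_geometric(ct)
  groups <- ct$groups[colnames(norm$equalized)]
  use <- rownames(ct$counts) %in% unique(unlist(ct$detected))
  z <- norm$equalized[use, , drop = FALSE]
  conc <- norm$concentration[use, , drop = FALSE]
  sel1 <- groups == grp_levels[1]; sel2 <- groups == grp_levels[2]
  n1 <- sum(sel1); n2 <- sum(sel2)
  s1 <- rowSums(z[, sel1, drop = FALSE]); s2 <- rowSums(z[, sel2, drop = FALSE])
  p <- vapply(seq_along(s1), function(i)
    nb_exact_test(s1[i], s2[i], n1, n2, phi), numeric(1))
  m1 <- s1 / n1; m2 <- s2 / n2
  logFC <- log2((m2 + 0.5) / (m1 + 0.5))
  out <- data.frame(
    mirna = rownames(z),
    conc_g1 = rowMeans(conc[, sel1, drop = FALSE]),
    conc_g2 = rowMeans(conc[, sel2, drop = FALSE]),
    logFC = logFC,
    p_value = p,
    bh_q = bh_adjust(p),
    significant = p < alpha,
    direction = ifelse(logFC >= 0, grp_levels[2], grp_levels[1]),
    platform = "seq",
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "groups") <- grp_levels
  attr(out, "phi") <- phi
  class(out) <- c("de_table", "data.frame")
  out
}

#' @export
print.de_table <- function(x, ...) {
  g <- attr(x, "groups")
  cat("de_table (", x$platform[1] %||% "?", "): ", nrow(x), " features, ",
      sum(x$significant), " significant; logFC = log2(", g[2], "/", g[1], ")\n",
      sep = "")
  NextMethod()
}

#' Array present calls
#'
#' A miRNA is present in a replicate if its log2 signal exceeds the
#' background threshold, and detected in a group iff present in at least 2
#' replicates of that group. The threshold is the `background_quantile` of
#' a null signal set; with no null set supplied, the Gaussian background
#' model of the simulator (mean `background`, sd `noise_sd`) is used in
#' closed form.
#'
#' @param am an `array_matrix`.
#' @param null_signals optional numeric vector of background signals.
#' @param background_quantile quantile of the null defining the threshold.
#' @return list with `threshold`, `present` (logical matrix), `detected`
#'   (list group -> miRNA names).
#' @export
array_present_calls <- function(am, null_signals = NULL,
                                background_quantile = 0.9) {
  grp <- attr(am, "groups")
  if (min(table(grp)) < 2) stop("at least 2 replicates per group required")
  thr <- if (!is.null(null_signals)) {
    stats::quantile(null_signals, background_quantile, names = FALSE)
  } else {
    attr(am, "background") +
      stats::qnorm(background_quantile) * attr(am, "noise_sd")
  }
  present <- unclass(am) > thr
  detected <- lapply(unique(grp), function(g)
    rownames(am)[rowSums(present[, grp == g, drop = FALSE]) >= 2])
  names(detected) <- unique(grp)
  list(threshold = thr, present = present, detected = detected)
}

# Empirical-Bayes squeeze of per-feature variances: the sample variances
# s^2 (df d) are modelled as scaled F; (d0, s0^2) are fitted by matching
# mean and variance of log s^2, and the posterior variance is
# (d0 s0^2 + d s^2) / (d0 + d).
fit_f_dispersion <- function(s2, d) {
  ok <- s2 > 0
  if (!any(ok)) return(list(d0 = Inf, s02 = mean(s2)))
  e <- log(s2[ok])
  rhs <- stats::var(e) - trigamma(d / 2)
  if (!is.finite(rhs) || rhs <= 0) {
    d0 <- Inf
    s02 <- exp(mean(e) - digamma(d / 2) + log(d / 2))
  } else {
    x <- stats::uniroot(function(x) trigamma(x) - rhs,
                        lower = 1e-8, upper = 1e8, extendInt = "downX",
                        tol = 1e-12)$root
    d0 <- 2 * x
    s02 <- exp(mean(e) - digamma(d / 2) + log(d / 2) +
                 digamma(d0 / 2) - log(d0 / 2))
  }
  list(d0 = d0, s02 = s02)
}

moderated_t_stats <- function(m1, m2, s2, n1, n2, d0, s02) {
  d <- n1 + n2 - 2
  s2_post <- if (is.infinite(d0)) rep(s02, length(s2)) else
    (d0 * s02 + d * s2) / (d0 + d)
  tstat <- (m2 - m1) / sqrt(s2_post * (1 / n1 + 1 / n2))
  df <- d0 + d
  p <- 2 * stats::pt(-abs(tstat), df = df)
  list(t = tstat, p = p, df = df, s2_post = s2_post)
}

#' Moderated-t differential expression for array signals
#'
#' Empirical-Bayes moderated two-sample t-test on normalized log2 signals:
#' per-miRNA pooled variances are squeezed towards a common prior fitted by
#' moment matching of the scaled-F distribution of sample variances, and
#' the t-statistic uses the squeezed variance with d0 + d degrees of
#' freedom. With no variance anywhere, an ordinary pooled t-test is used
#' with a warning.
#'
#' @param am an `array_matrix`.
#' @param alpha significance threshold.
#' @return a `de_table` (platform `"array"`); `conc_g*` columns carry
#'   group-mean log2 signals, `logFC` their difference (group2 - group1).
#' @export
array_de_moderated_t <- function(am, alpha = 0.05) {
  grp <- attr(am, "groups")
  grp_levels <- unique(grp)
  if (length(grp_levels) != 2) stop("exactly two groups required")
  x <- unclass(am)
  sel1 <- grp == grp_levels[1]; sel2 <- grp == grp_levels[2]
  n1 <- sum(sel1); n2 <- sum(sel2)
  if (min(n1, n2) < 2) stop("at least 2 replicates per group required")
  m1 <- rowMeans(x[, sel1, drop = FALSE]); m2 <- rowMeans(x[, sel2, drop = FALSE])
  v1 <- apply(x[, sel1, drop = FALSE], 1, stats::var)
  v2 <- apply(x[, sel2, drop = FALSE], 1, stats::var)
  d <- n1 + n2 - 2
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / d
  if (all(s2 == 0)) {
    warning("zero variance everywhere; falling back to ordinary t")
    fit <- list(d0 = 0, s02 = 0)
  } else {
    fit <- fit_f_dispersion(s2, d)
  }
  mt <- moderated_t_stats(m1, m2, s2, n1, n2, fit$d0, fit$s02)
  out <- data.frame(
    mirna = rownames(x),
    conc_g1 = m1, conc_g2 = m2,
    logFC = m2 - m1,
    p_value = mt$p,
    bh_q = bh_adjust(pmin(pmax(mt$p, .Machine$double.xmin), 1)),
    significant = mt$p < alpha,
    direction = ifelse(m2 - m1 >= 0, grp_levels[2], grp_levels[1]),
    platform = "array",
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "groups") <- grp_levels
  attr(out, "prior") <- fit
  class(out) <- c("de_table", "data.frame")
  out
}

#' Group differentially expressed miRNAs by family and cluster
#'
#' Collects miRNAs called significant on either platform, annotates them
#' with seed-family and genomic-cluster ids and a detection-source tag
#' (`"MS"`, `"MA"` or `"MA; MS"`), and highlights families and clusters
#' with at least two significant members changing in the same direction --
#' the signature of a co-regulated family or polycistronic cluster.
#'
#' @param de_seq sequencing `de_table` (or NULL).
#' @param de_array array `de_table` (or NULL).
#' @param family_map,cluster_map named vectors (miRNA -> id), e.g. from
#'   [assign_families()] / [assign_clusters()].
#' @return data.frame of class `family_cluster_report` with one row per
#'   significant miRNA and logical columns `family_highlighted`,
#'   `cluster_highlighted`.
#' @export
group_de_by_family_cluster <- function(de_seq = NULL, de_array = NULL,
                                       family_map, cluster_map) {
  pick <- function(de) if (is.null(de)) de else de[de$significant, , drop = FALSE]
  ds <- pick(de_seq); da <- pick(de_array)
  mirnas <- union(if (!is.null(ds)) ds$mirna, if (!is.null(da)) da$mirna)
  empty <- data.frame(mirna = character(0), family_id = character(0),
                      cluster_id = character(0), detected_by = character(0),
                      direction = character(0), is_star = logical(0),
                      logFC_seq = numeric(0), p_seq = numeric(0),
                      logFC_array = numeric(0), p_array = numeric(0),
                      family_highlighted = logical(0),
                      cluster_highlighted = logical(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("family_cluster_report", "data.frame")
  if (!length(mirnas)) return(empty)
  if (!all(mirnas %in% names(family_map)) || !all(mirnas %in% names(cluster_map)))
    stop("family/cluster maps must cover all reported miRNAs")
  iseq <- if (!is.null(ds)) match(mirnas, ds$mirna) else rep(NA_integer_, length(mirnas))
  iarr <- if (!is.null(da)) match(mirnas, da$mirna) else rep(NA_integer_, length(mirnas))
  in_seq <- !is.na(iseq); in_arr <- !is.na(iarr)
  direction <- ifelse(in_seq, ds$direction[iseq], da$direction[iarr])
  out <- data.frame(
    mirna = mirnas,
    family_id = unname(family_map[mirnas]),
    cluster_id = unname(cluster_map[mirnas]),
    detected_by = ifelse(in_seq & in_arr, "MA; MS", ifelse(in_seq, "MS", "MA")),
    direction = direction,
    is_star = grepl("*", mirnas, fixed = TRUE),
    logFC_seq = ifelse(in_seq, ds$logFC[iseq], NA_real_),
    p_seq = ifelse(in_seq, ds$p_value[iseq], NA_real_),
    logFC_array = ifelse(in_arr, da$logFC[iarr], NA_real_),
    p_array = ifelse(in_arr, da$p_value[iarr], NA_real_),
    stringsAsFactors = FALSE)
  hi <- function(id) {
    key <- paste(id, out$direction)
    key %in% key[duplicated(key)]
  }
  out$family_highlighted <- hi(out$family_id)
  out$cluster_highlighted <- hi(out$cluster_id)
  out <- out[order(out$direction, out$cluster_id, out$mirna), ]
  rownames(out) <- NULL
  class(out) <- c("family_cluster_report", "data.frame")
  out
}
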