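#' Poisson multiple-binding-site p-value
#'
#' Upper-tail probability of observing at least `k_sites` predicted binding
#' sites on a 3'UTR of the given length when sites accrue at
#' `background_rate` per nucleotide: p = P(X >= k), X ~ Poisson(rate *
#' length). By convention p(k = 0) = 1.
#'
#' @param k_sites observed site count (>= 0).
#' @param utr_length 3'UTR length in nucleotides (> 0).
#' @param background_rate expected sites per nucleotide (>= 0).
#' @return p-value in (0, 1].
#' @export
poisson_site_pvalue <- function(k_sites, utr_length, background_rate) {
  if (any(k_sites < 0) || any(utr_length <= 0) || any(background_rate < 0))
    stop("k_sites, utr_length and background_rate must be non-negative (utr_length > 0)")
  lambda <- background_rate * utr_length
  ifelse(k_sites == 0, 1,
         stats::ppois(k_sites - 1, lambda, lower.tail = FALSE))
}

#' Consensus target-prediction filter
#'
#' Applies the two-criterion consensus rule to a table of per-program
#' binding-site predictions: a (miRNA, gene) pair passes iff its Poisson
#' multiple-binding-site p-value is below `alpha` AND at least
#' `min_programs` distinct programs predict the pair. Star miRNAs (name
#' containing `*`) are excluded before any calling. Site counts are
#' aggregated across programs by maximum to avoid double-counting the same
#' site. The background rate defaults to a per-miRNA estimate from the
#' input itself (total sites / total scanned UTR length), which keeps the
#' null scale-free; a fixed rate can be supplied instead.
#'
#' @param predictions data.frame with columns `mirna`, `gene`, `program`,
#'   `n_sites` (>= 1), `utr_length` (> 0).
#' @param alpha Poisson significance threshold (default 0.05).
#' @param min_programs minimum distinct supporting programs (default 2).
#' @param background_rate fixed per-nucleotide rate, or NULL to estimate
#'   per miRNA from the table.
#' @param programs allowed program labels; an unknown label is an error.
#' @return data.frame of class `target_calls`: `mirna`, `gene`,
#'   `max_sites`, `utr_length`, `poisson_p`, `n_programs`, `pass`.
#' @export
consensus_filter <- function(predictions, alpha = 0.05, min_programs = 2,
                             background_rate = NULL,
                             programs = paste0("P", 1:5)) {
  need <- c("mirna", "gene", "program", "n_sites", "utr_length")
  if (!all(need %in% names(predictions)))
    stop("predictions must have columns ", paste(need, collapse = ", "))
  if (!all(predictions$program %in% programs))
    stop("unknown program label: ",
         paste(setdiff(predictions$program, programs), collapse = ", "))
  stopifnot(all(predictions$n_sites >= 1), all(predictions$utr_length > 0))

  pr <- predictions[!grepl("*", predictions$mirna, fixed = TRUE), , drop = FALSE]
  empty <- data.frame(mirna = character(0), gene = character(0),
                      max_sites = integer(0), utr_length = numeric(0),
                      poisson_p = numeric(0), n_programs = integer(0),
                      pass = logical(0), stringsAsFactors = FALSE)
  class(empty) <- c("target_calls", "data.frame")
  if (!nrow(pr)) return(empty)

  rate_of <- if (is.null(background_rate)) {
    tapply(pr$n_sites, pr$mirna, sum) / tapply(pr$utr_length, pr$mirna, sum)
  } else NULL

  key <- paste(pr$mirna, pr$gene, sep = "\r")
  agg <- data.frame(
    mirna = tapply(pr$mirna, key, `[`, 1),
    gene = tapply(pr$gene, key, `[`, 1),
    max_sites = as.integer(tapply(pr$n_sites, key, max)),
    utr_length = as.numeric(tapply(pr$utr_length, key, max)),
    n_programs = as.integer(tapply(pr$program, key, function(x) length(unique(x)))),
    stringsAsFactors = FALSE)
  rate <- if (is.null(background_rate)) as.numeric(rate_of[agg$mirna])
          else rep(background_rate, nrow(agg))
  agg$poisson_p <- poisson_site_pvalue(agg$max_sites, agg$utr_length, rate)
  agg$pass <- agg$poisson_p < alpha & agg$n_programs >= min_programs
  agg <- agg[order(agg$mirna, agg$gene),
             c("mirna", "gene", "max_sites", "utr_length", "poisson_p",
               "n_programs", "pass")]
  rownames(agg) <- NULL
  class(agg) <- c("target_calls", "data.frame")
  agg
}

#' Summarize consensus target calls per miRNA and across regions
#'
#' Counts passing target genes per miRNA and, given the region-specific
#' up-regulated miRNA sets, forms each region's target-gene union and the
#' fraction of each region's targets shared with the other region.
#'
#' @param calls a `target_calls` data.frame from [consensus_filter()].
#' @param de_mirnas_by_region named list (region -> character vector of
#'   miRNA names up-regulated in that region), or NULL.
#' @return list with `per_mirna` (named target counts), `region_targets`
#'   (list of gene sets), `shared_fraction` (named per-region fractions of
#'   targets shared with the other region), `shared_overall`
#'   (|intersection| / |union|).
#' @export
target_summary <- function(calls, de_mirnas_by_region = NULL) {
  pass <- calls[calls$pass, , drop = FALSE]
  per_mirna <- table(factor(pass$mirna, levels = unique(calls$mirna)))
  out <- list(per_mirna = stats::setNames(as.integer(per_mirna),
                                          names(per_mirna)))
  if (!is.null(de_mirnas_by_region)) {
    sets <- lapply(de_mirnas_by_region, function(ms)
      unique(pass$gene[pass$mirna %in% ms]))
    out$region_targets <- sets
    if (length(sets) == 2) {
      inter <- intersect(sets[[1]], sets[[2]])
      out$shared_fraction <- stats::setNames(
        vapply(sets, function(s)
          if (length(s)) length(inter) / length(s) else 0, numeric(1)),
        names(sets))
      uni <- union(sets[[1]], sets[[2]])
      out$shared_overall <- if (length(uni)) length(inter) / length(uni) else 0
    }
  }
  out
}
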