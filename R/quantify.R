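#' Align inserts to the mature miRNA reference
#'
#' 5'-anchored ungapped comparison of each insert against every mature
#' sequence over the first `min(length)` bases, allowing a 3' length
#' difference of at most `max_overhang` (isomiR-like length variation). The
#' best hit is the reference with the fewest mismatches; ties are broken
#' deterministically by the lexicographically smallest miRNA name. Inserts
#' with more than `max_mm` mismatches everywhere are unaligned.
#'
#' @param inserts character vector of DNA inserts (>= 14 nt).
#' @param reference a `mirna_reference`.
#' @param max_mm maximum mismatches (default 2).
#' @param max_overhang maximum absolute 3' length difference (default 3).
#' @return data.frame with columns `insert`, `mirna` (NA if unaligned),
#'   `mismatches` (NA if unaligned), one row per input insert.
#' @export
align_inserts <- function(inserts, reference, max_mm = 2, max_overhang = 3) {
  if (nrow(reference$mirnas) == 0L) stop("empty reference")
  ref_name <- reference$mirnas$name
  ord <- order(ref_name)                        # lexicographic tie-break
  ref_name <- ref_name[ord]
  ref_seq <- as_dna(reference$mirnas$sequence)[ord]
  ref_len <- nchar(ref_seq)
  ref_ints <- lapply(ref_seq, seq_ints)

  uniq <- unique(inserts)
  lens <- nchar(uniq)
  best_mm <- rep(Inf, length(uniq))
  best_ref <- rep(NA_integer_, length(uniq))
  for (L in sort(unique(lens))) {
    sel <- which(lens == L)
    M <- seq_int_matrix(uniq[sel], L)
    cand <- which(abs(ref_len - L) <= max_overhang)
    for (r in cand) {                           # ascending name order
      Lmin <- min(L, ref_len[r])
      mm <- colSums(M[seq_len(Lmin), , drop = FALSE] != ref_ints[[r]][seq_len(Lmin)])
      upd <- mm < best_mm[sel]                  # strict: first name wins ties
      best_mm[sel][upd] <- mm[upd]
      best_ref[sel][upd] <- r
    }
  }
  miss <- best_mm > max_mm
  best_ref[miss] <- NA_integer_
  best_mm[miss] <- NA_real_
  i <- match(inserts, uniq)
  data.frame(insert = inserts,
             mirna = ref_name[best_ref[i]],
             mismatches = as.integer(best_mm[i]),
             stringsAsFactors = FALSE)
}

#' Build the miRNA x library count table
#'
#' Counts best-hit inserts per (miRNA, library). Mirroring the rule that
#' miRNAs detected with only one count are eliminated, a miRNA whose summed
#' count within a group is exactly 1 is removed from that group's detected
#' set; the detected set thus holds miRNAs with a group total of at least 2.
#' miRNAs with zero counts in every library are absent from the table.
#'
#' @param hits_by_library named list (library -> character vector of miRNA
#'   assignments, NA for unaligned inserts).
#' @param groups named character vector: library -> group label.
#' @return `count_table`: list with `counts` (integer matrix), `groups`,
#'   and `detected` (list group -> miRNA names with group total >= 2).
#' @export
build_count_table <- function(hits_by_library, groups) {
  if (!all(names(hits_by_library) %in% names(groups)))
    stop("every library needs a group label")
  groups <- groups[names(hits_by_library)]
  mirnas <- sort(unique(unlist(lapply(hits_by_library, function(h) h[!is.na(h)]))))
  counts <- vapply(hits_by_library, function(h)
    as.integer(table(factor(h[!is.na(h)], levels = mirnas))),
    integer(length(mirnas)))
  if (length(mirnas) == 0L)
    counts <- matrix(0L, 0L, length(hits_by_library),
                     dimnames = list(NULL, names(hits_by_library)))
  if (is.null(dim(counts)))
    counts <- matrix(counts, nrow = length(mirnas),
                     dimnames = list(mirnas, names(hits_by_library)))
  rownames(counts) <- mirnas
  count_table(counts, groups)
}

#' Construct a `count_table` from a count matrix
#'
#' @param counts non-negative integer matrix, miRNAs in rows, libraries in
#'   columns.
#' @param groups named character vector: library -> group label.
#' @return a `count_table` (see [build_count_table()]).
#' @export
count_table <- function(counts, groups) {
  stopifnot(is.matrix(counts), all(counts >= 0),
            !is.null(colnames(counts)), !is.null(names(groups)))
  groups <- groups[colnames(counts)]
  if (anyNA(groups)) stop("every library needs a group label")
  keep <- rowSums(counts) > 0
  counts <- counts[keep, , drop = FALSE]
  detected <- lapply(unique(groups), function(g) {
    tot <- rowSums(counts[, groups == g, drop = FALSE])
    rownames(counts)[tot >= 2]
  })
  names(detected) <- unique(groups)
  structure(list(counts = counts, groups = groups, detected = detected),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat("count_table:", nrow(x$counts), "miRNAs x", ncol(x$counts),
      "libraries; library totals:\n")
  print(colSums(x$counts))
  for (g in names(x$detected))
    cat(" detected (>=2 reads) in", g, ":", length(x$detected[[g]]), "\n")
  invisible(x)
}

#' Share of counts (or array signal) held by the top-k miRNAs
#'
#' For a count table, the per-group fraction of all counts carried by the k
#' most abundant miRNAs; for an array matrix, the same fraction computed on
#' linear-scale (2^log2) signal totals.
#'
#' @param x a `count_table` or `array_matrix`.
#' @param k number of top miRNAs (default 15).
#' @param group group label; NULL pools all libraries.
#' @return fraction in `[0, 1]`.
#' @export
abundance_share <- function(x, k = 15, group = NULL) {
  stopifnot(k >= 1)
  if (inherits(x, "count_table")) {
    sel <- if (is.null(group)) rep(TRUE, ncol(x$counts)) else x$groups == group
    tot <- rowSums(x$counts[, sel, drop = FALSE])
  } else if (inherits(x, "array_matrix")) {
    grp <- attr(x, "groups")
    sel <- if (is.null(group)) rep(TRUE, ncol(x)) else grp == group
    tot <- rowSums(2^unclass(x)[, sel, drop = FALSE])
  } else stop("x must be a count_table or array_matrix")
  if (k > length(tot)) {
    warning("k exceeds the number of miRNAs; share is 1")
    return(1)
  }
  if (sum(tot) == 0) return(0)
  sum(sort(tot, decreasing = TRUE)[seq_len(k)]) / sum(tot)
}

#' Assemble the per-group run report
#'
#' Reproduces the read-accounting schema of an indexed miRNA-Seq workflow:
#' pre-filtered reads, index-sorted reads, indexing efficiency, index
#' distribution, trimmed reads surviving the contaminant filters, reads
#' aligned to the mature reference, detected miRNAs, and detected miRNAs
#' with at least 2 reads, aggregated per group.
#'
#' @param preprocess list returned by [run_preprocess()].
#' @param aligned_by_library named list (library -> miRNA assignment vector,
#'   as given to [build_count_table()]).
#' @param ct the `count_table`.
#' @param groups named character vector: library -> group.
#' @return data.frame with a `row_label` column and one column per group;
#'   class `run_report`.
#' @export
summarize_run <- function(preprocess, aligned_by_library, ct, groups) {
  grp_levels <- unique(groups)
  idx_names <- names(preprocess[[1]]$stats$per_index)
  per_group <- function(g) {
    libs <- names(groups)[groups == g]
    st <- lapply(preprocess[libs], `[[`, "stats")
    input <- sum(vapply(st, `[[`, numeric(1), "input"))
    assigned <- sum(vapply(st, `[[`, numeric(1), "index_assigned"))
    per_idx <- Reduce(`+`, lapply(st, `[[`, "per_index"))
    retained <- sum(vapply(st, `[[`, numeric(1), "retained"))
    al <- unlist(aligned_by_library[libs], use.names = FALSE)
    n_aligned <- sum(!is.na(al))
    cc <- ct$counts[, intersect(libs, colnames(ct$counts)), drop = FALSE]
    tot <- rowSums(cc)
    det <- ct$detected[[g]]
    c(`# of technical replicates` = length(libs),
      `# of pre-filtered reads after base calling` = input,
      `# of sorted reads with indexes` = assigned,
      `Indexing efficiency (%)` = if (input > 0) round(100 * assigned / input, 1) else 0,
      stats::setNames(
        if (assigned > 0) round(100 * per_idx / assigned, 1) else rep(0, length(per_idx)),
        paste0("Distribution of indexes (%): ", idx_names)),
      `# of trimmed reads without mitochondrial and ribosomal sequences` = retained,
      `# of reads aligning against the mature reference` = n_aligned,
      `# of known miRNAs` = sum(tot > 0),
      `# of reads aligning against the mature reference with >=2 reads` =
        sum(tot[rownames(cc) %in% det]),
      `# of known miRNAs with >=2 reads` = length(det))
  }
  cols <- lapply(grp_levels, per_group)
  out <- data.frame(row_label = names(cols[[1]]), stringsAsFactors = FALSE)
  for (i in seq_along(grp_levels)) out[[grp_levels[i]]] <- unname(cols[[i]])
  class(out) <- c("run_report", "data.frame")
  out
}

#' @export
print.run_report <- function(x, ...) {
  df <- as.data.frame(x)
  cat("Run accounting\n")
  print(df, row.names = FALSE, right = FALSE)
  invisible(x)
}
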