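#' Demultiplex reads by exact 6-nt index prefix
#'
#' A read is assigned to an index iff its first 6 bases exactly equal the
#' DNA form of that index; anything else is unassigned. Exact matching on
#' pairwise-distinct indexes makes the assignment unique. Mismatch rescue is
#' deliberately not performed by default: only reads carrying an intact
#' index are retained.
#'
#' @param reads character vector of DNA reads.
#' @param index_set named character vector of 6-nt indexes (RNA or DNA).
#' @return list with `by_index` (named list of integer read positions per
#'   index) and `unassigned` (integer vector).
#' @export
demultiplex <- function(reads, index_set = default_indexes()) {
  idx_dna <- as_dna(index_set)
  if (any(nchar(idx_dna) != 6)) stop("all indexes must be 6 nt")
  if (anyDuplicated(idx_dna)) stop("duplicate indexes in index set")
  if (is.null(names(idx_dna))) names(idx_dna) <- idx_dna
  pre <- substr(reads, 1, 6)
  hit <- match(pre, idx_dna)
  by_index <- lapply(seq_along(idx_dna), function(i) which(hit == i))
  names(by_index) <- names(idx_dna)
  list(by_index = by_index, unassigned = which(is.na(hit)))
}

#' Trim the index and locate the 3' adapter
#'
#' After stripping the 6-nt index, the earliest read position is sought at
#' which a prefix of the 3' adapter aligns with at most
#' `floor(overlap * mismatch_rate)` mismatches, requiring an overlap of at
#' least `min_overlap` bases (a shorter read tail qualifies only if it
#' matches the adapter prefix exactly). Everything before that position is
#' the insert. A zero-length insert is an adapter dimer; if the adapter is
#' not found the whole remaining read is kept as the insert (it may be a
#' long insert) and flagged untrimmed.
#'
#' @param reads character vector of fixed-length DNA reads that start with
#'   their index.
#' @param index_len index length to strip (default 6).
#' @param adapter3 3' adapter sequence (RNA or DNA).
#' @param min_overlap minimum adapter overlap for a mismatch-tolerant match.
#' @param mismatch_rate allowed mismatches per adapter-overlap base
#'   (default 0.1, i.e. 1 per 10 bases).
#' @return data.frame with columns `insert`, `status` in
#'   `{"trimmed","dimer","untrimmed"}`.
#' @export
trim_reads <- function(reads, index_len = 6, adapter3 = default_adapter3(),
                       min_overlap = 7, mismatch_rate = 0.1) {
  n <- length(reads)
  if (n == 0L)
    return(data.frame(insert = character(0), status = character(0),
                      stringsAsFactors = FALSE))
  W_all <- unique(nchar(reads))
  if (length(W_all) != 1L) stop("reads must be fixed-length")
  if (W_all < index_len + 1L) stop("reads shorter than index + 1 nt")
  rem <- substr(reads, index_len + 1L, W_all)
  W <- W_all - index_len
  A <- seq_ints(as_dna(adapter3))
  la <- length(A)
  M <- t(seq_int_matrix(rem, W))          # reads x positions

  best <- integer(n)                      # 0 = adapter not found
  unresolved <- seq_len(n)
  for (p in seq_len(W)) {
    if (!length(unresolved)) break
    L <- min(W - p + 1L, la)
    allowed <- if (L >= min_overlap) floor(L * mismatch_rate) else 0L
    mm <- integer(length(unresolved))
    for (j in seq_len(L))
      mm <- mm + (M[unresolved, p + j - 1L] != A[j])
    hit <- mm <= allowed
    best[unresolved[hit]] <- p
    unresolved <- unresolved[!hit]
  }
  insert <- ifelse(best > 0L, substr(rem, 1L, best - 1L), rem)
  status <- ifelse(best == 1L, "dimer", ifelse(best > 1L, "trimmed", "untrimmed"))
  data.frame(insert = insert, status = status, stringsAsFactors = FALSE)
}

#' Classify trimmed inserts: keep or discard with a single reason
#'
#' Discard precedence is fixed so every discarded insert has exactly one
#' reason: adapter dimer (zero-length insert), then contaminant (ungapped
#' match to any contaminant subsequence with at most `max_mm` mismatches
#' over the insert length), then homopolymer (one base strictly exceeding
#' `homopolymer_frac` of the insert), then short (< `min_len` nt).
#'
#' @param inserts character vector of trimmed inserts.
#' @param contaminants character vector of contaminant DNA sequences.
#' @param dimer logical vector marking adapter-dimer inserts (from
#'   [trim_reads()]); zero-length inserts are dimers regardless.
#' @param max_mm maximum mismatches for a contaminant match.
#' @param homopolymer_frac strict single-base frequency threshold.
#' @param min_len minimum insert length to keep.
#' @return character vector in
#'   `{"keep","dimer","contaminant","homopolymer","short"}`.
#' @export
classify_inserts <- function(inserts, contaminants, dimer = NULL,
                             max_mm = 2, homopolymer_frac = 0.8,
                             min_len = 14) {
  n <- length(inserts)
  if (is.null(dimer)) dimer <- rep(FALSE, n)
  reason <- rep("keep", n)
  reason[dimer | nchar(inserts) == 0L] <- "dimer"

  open <- which(reason == "keep")
  if (length(open) && length(contaminants)) {
    uniq <- unique(inserts[open])
    is_cont <- contaminant_match(uniq, as_dna(contaminants), max_mm)
    reason[open][inserts[open] %in% uniq[is_cont]] <- "contaminant"
  }
  open <- which(reason == "keep")
  if (length(open)) {
    hp <- max_base_fraction(inserts[open]) > homopolymer_frac
    reason[open[hp]] <- "homopolymer"
  }
  open <- which(reason == "keep")
  if (length(open))
    reason[open[nchar(inserts[open]) < min_len]] <- "short"
  reason
}

# TRUE for each query that matches a window of any contaminant with <= max_mm
# mismatches over the query length (ungapped, query no longer than window).
contaminant_match <- function(queries, contaminants, max_mm = 2) {
  out <- rep(FALSE, length(queries))
  lens <- nchar(queries)
  cont_ints <- lapply(contaminants, seq_ints)
  for (L in sort(unique(lens))) {
    sel <- which(lens == L & !out)
    if (!length(sel)) next
    M <- seq_int_matrix(queries[sel], L)   # L x m
    matched <- rep(FALSE, length(sel))
    for (ci in cont_ints) {
      lc <- length(ci)
      if (lc < L) next
      for (o in seq_len(lc - L + 1L)) {
        todo <- which(!matched)
        if (!length(todo)) break
        w <- ci[o:(o + L - 1L)]
        mm <- colSums(M[, todo, drop = FALSE] != w)
        matched[todo[mm <= max_mm]] <- TRUE
      }
      if (all(matched)) break
    }
    out[sel] <- matched
  }
  out
}

#' Run the full preprocessing cascade with per-stage accounting
#'
#' Demultiplexes each library by exact index, trims index and 3' adapter,
#' applies the filter cascade, and reports per-stage read counts that
#' partition the input exactly: input = assigned + unassigned and
#' assigned = retained + sum of per-reason discards.
#'
#' @param libraries a `seq_library` or list of them (or plain named list
#'   with `reads`, `sample_id`).
#' @param reference a `mirna_reference` supplying the contaminant set.
#' @param index_set named 6-nt index set used for demultiplexing.
#' @param adapter3,min_overlap,mismatch_rate see [trim_reads()].
#' @param max_mm,homopolymer_frac,min_len see [classify_inserts()].
#' @return list of per-library results, each with `inserts` (data.frame:
#'   read_id, index, insert) and `stats` (class `preprocess_stats`).
#' @export
run_preprocess <- function(libraries, reference,
                           index_set = default_indexes(),
                           adapter3 = default_adapter3(),
                           min_overlap = 7, mismatch_rate = 0.1,
                           max_mm = 2, homopolymer_frac = 0.8, min_len = 14) {
  if (inherits(libraries, "seq_library")) libraries <- list(libraries)
  out <- lapply(libraries, function(lib) {
    reads <- lib$reads
    ids <- names(reads) %||% sprintf("read-%06d", seq_along(reads))
    dmx <- demultiplex(reads, index_set)
    assigned <- unlist(dmx$by_index, use.names = FALSE)
    per_index <- vapply(dmx$by_index, length, integer(1))
    index_of <- rep(names(dmx$by_index), per_index)

    if (length(assigned)) {
      tr <- trim_reads(reads[assigned], adapter3 = adapter3,
                       min_overlap = min_overlap, mismatch_rate = mismatch_rate)
      reason <- classify_inserts(tr$insert, reference$contaminants$sequence,
                                 dimer = tr$status == "dimer",
                                 max_mm = max_mm,
                                 homopolymer_frac = homopolymer_frac,
                                 min_len = min_len)
    } else {
      tr <- data.frame(insert = character(0), status = character(0))
      reason <- character(0)
    }
    keep <- reason == "keep"
    stats <- structure(list(
      sample_id = lib$sample_id %||% "library",
      input = length(reads),
      index_assigned = length(assigned),
      unassigned = length(dmx$unassigned),
      per_index = per_index,
      dimer_discarded = sum(reason == "dimer"),
      contaminant_discarded = sum(reason == "contaminant"),
      homopolymer_discarded = sum(reason == "homopolymer"),
      short_discarded = sum(reason == "short"),
      retained = sum(keep),
      indexing_efficiency = if (length(reads)) length(assigned) / length(reads) else 0
    ), class = "preprocess_stats")
    validate_preprocess_stats(stats)
    list(inserts = data.frame(read_id = ids[assigned][keep],
                              index = index_of[keep],
                              insert = tr$insert[keep],
                              stringsAsFactors = FALSE),
         stats = stats)
  })
  names(out) <- vapply(out, function(x) x$stats$sample_id, character(1))
  out
}

validate_preprocess_stats <- function(s) {
  stopifnot(
    s$input == s$index_assigned + s$unassigned,
    s$index_assigned == sum(s$per_index),
    s$index_assigned == s$retained + s$dimer_discarded +
      s$contaminant_discarded + s$homopolymer_discarded + s$short_discarded)
  invisible(s)
}

#' @export
print.preprocess_stats <- function(x, ...) {
  cat("preprocess_stats [", x$sample_id, "]\n", sep = "")
  cat(sprintf("  input %d | with index %d (%.1f%%) | retained %d\n",
              x$input, x$index_assigned, 100 * x$indexing_efficiency,
              x$retained))
  cat(sprintf("  discarded: dimer %d, contaminant %d, homopolymer %d, short %d\n",
              x$dimer_discarded, x$contaminant_discarded,
              x$homopolymer_discarded, x$short_discarded))
  invisible(x)
}
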