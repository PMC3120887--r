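#' @keywords internal
"_PACKAGE"

DNA_BASES <- c("A", "C", "G", "T")

#' Convert between RNA and DNA alphabets
#'
#' Sequencer output is DNA-space; mature miRNA and adapter sequences are
#' RNA-space. `as_dna()` maps U->T, `as_rna()` maps T->U; both uppercase.
#'
#' @param x character vector of sequences.
#' @return character vector in the target alphabet.
#' @export
as_dna <- function(x) chartr("U", "T", toupper(x))

#' @rdname as_dna
#' @export
as_rna <- function(x) chartr("T", "U", toupper(x))

# Integer (UTF-8 code) matrix of equal-width sequences, positions in rows,
# sequences in columns. Fast path for mismatch counting.
seq_int_matrix <- function(x, width = unique(nchar(x))) {
  if (length(width) != 1L)
    stop("sequences must all have the same length")
  if (length(x) == 0L)
    return(matrix(integer(0), nrow = width, ncol = 0L))
  matrix(utf8ToInt(paste(x, collapse = "")), nrow = width)
}

seq_ints <- function(x) utf8ToInt(x)

random_dna <- function(n, len, rng_len = NULL) {
  lens <- if (is.null(rng_len)) rep_len(len, n) else sample(len, n, replace = TRUE)
  vapply(lens, function(L) paste(sample(DNA_BASES, L, replace = TRUE), collapse = ""),
         character(1))
}

# Hamming distance of two equal-or-unequal length strings over the first
# min(length) positions.
hamming_prefix <- function(a, b) {
  L <- min(nchar(a), nchar(b))
  sum(utf8ToInt(substr(a, 1, L)) != utf8ToInt(substr(b, 1, L)))
}

# max single-base frequency of each sequence
max_base_fraction <- function(x) {
  n <- nchar(x)
  best <- rep(0L, length(x))
  for (b in DNA_BASES) {
    cnt <- n - nchar(gsub(b, "", x, fixed = TRUE))
    best <- pmax(best, cnt)
  }
  ifelse(n > 0L, best / n, 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
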