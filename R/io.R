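#' Read and write sequence files
#'
#' Thin wrappers around Biostrings for the package's on-disk formats:
#' FASTQ reads (constant Phred-33 quality on write), FASTA references, and
#' TSV tables. [read_fastq()] aborts naming the first corrupt record if the
#' file cannot be parsed.
#'
#' @param path file path.
#' @return `read_fastq()`: named character vector of reads.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) %% 4 != 0)
    stop("corrupt FASTQ record ", length(lines) %/% 4 + 1, " in ", path)
  for (i in seq_len(length(lines) %/% 4)) {
    blk <- lines[(4 * i - 3):(4 * i)]
    ok <- startsWith(blk[1], "@") && startsWith(blk[3], "+") &&
      nchar(blk[2]) == nchar(blk[4]) && nchar(blk[2]) > 0
    if (!ok) stop("corrupt FASTQ record ", i, " in ", path)
  }
  res <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = FALSE)
  stats::setNames(as.character(res), names(res))
}

#' @param reads named character vector of DNA reads.
#' @param quality_char constant quality character (default "I", Q40).
#' @rdname read_fastq
#' @export
write_fastq <- function(reads, path, quality_char = "I") {
  x <- Biostrings::DNAStringSet(reads)
  if (is.null(names(x))) names(x) <- sprintf("read-%06d", seq_along(x))
  q <- Biostrings::BStringSet(strrep(quality_char, nchar(reads)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' @param seqs named character vector of sequences (RNA or DNA).
#' @rdname read_fastq
#' @export
write_fasta <- function(seqs, path) {
  x <- if (any(grepl("U", seqs, fixed = TRUE)))
    Biostrings::RNAStringSet(seqs) else Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname read_fastq
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(as.character(x), names(x))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the reference as FASTA + locus annotation
#'
#' Writes `mirnas.fa` (RNA), `contaminants.fa` (DNA) and `loci.tsv`
#' (name, chrom, start, end, strand, family_id, cluster_id; 1-based
#' inclusive coordinates) into `dir`.
#'
#' @param reference a `mirna_reference`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_reference <- function(reference, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(stats::setNames(reference$mirnas$sequence, reference$mirnas$name),
              file.path(dir, "mirnas.fa"))
  if (nrow(reference$contaminants))
    write_fasta(stats::setNames(reference$contaminants$sequence,
                                reference$contaminants$name),
                file.path(dir, "contaminants.fa"))
  write_tsv(reference$mirnas[, c("name", "chrom", "start", "end", "strand",
                                 "family_id", "cluster_id")],
            file.path(dir, "loci.tsv"))
  invisible(dir)
}

#' Write / read a count table as TSV
#'
#' Columns are `<library>:<group>` so the header carries the group labels.
#'
#' @param ct a `count_table`.
#' @param path file path.
#' @export
write_count_table <- function(ct, path) {
  m <- ct$counts
  df <- data.frame(mirna = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[-1] <- paste0(colnames(m), ":", ct$groups[colnames(m)])
  write_tsv(df, path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  parts <- strsplit(colnames(m), ":", fixed = TRUE)
  libs <- vapply(parts, `[`, character(1), 1)
  grp <- stats::setNames(vapply(parts, `[`, character(1), 2), libs)
  colnames(m) <- libs
  count_table(m, grp)
}
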