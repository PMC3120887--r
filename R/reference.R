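#' Build a synthetic mature-miRNA reference with contaminant decoys
#'
#' Generates a self-consistent stand-in for a mature miRNA catalogue:
#' 19--24 nt RNA sequences organised into seed families (identical
#' nucleotides 2--8) and genomic clusters (loci within a short window on one
#' chromosome and strand), plus a set of longer mitochondrial/ribosomal-like
#' contaminant decoy sequences. All pairwise sequence constraints required by
#' downstream mismatch-tolerant alignment are enforced by construction:
#' any two mature sequences differ at more than 2 positions over their
#' aligned length, no mature sequence lies within 2 mismatches of any
#' contaminant subsequence, and no mature sequence is homopolymer-like.
#'
#' A fraction of entries are "star" (minor-arm) sequences, marked by a
#' trailing `*` in the name.
#'
#' @param n_mirnas number of mature miRNAs to generate.
#' @param n_families number of seed families; members are distributed as
#'   evenly as possible.
#' @param n_clusters number of multi-miRNA genomic clusters (size 2--4);
#'   remaining loci are singletons placed far apart.
#' @param n_contaminants number of contaminant decoy sequences (80--120 nt).
#' @param seed integer seed; the same seed reproduces the reference exactly.
#' @param star_fraction fraction of miRNAs named as star sequences.
#' @param max_tries rejection-sampling budget per sequence before the
#'   constraints are declared unsatisfiable.
#' @return an object of class `mirna_reference`: a list with `mirnas`
#'   (data.frame: name, sequence (RNA), is_star, chrom, start, end, strand,
#'   family_id, cluster_id) and `contaminants` (data.frame: name, sequence).
#' @export
build_reference <- function(n_mirnas = 150, n_families = 30, n_clusters = 10,
                            n_contaminants = 6, seed = 1,
                            star_fraction = 0.12, max_tries = 200) {
  stopifnot(n_mirnas >= 1, n_families >= 1, n_mirnas >= n_families,
            n_clusters >= 0, n_contaminants >= 0)
  if (n_families > 4^7)
    stop("impossible constraints: more families than distinct 7-nt seeds")
  if (2 * n_clusters > n_mirnas)
    stop("impossible constraints: not enough miRNAs for ", n_clusters, " clusters")
  set.seed(seed)

  ## distinct family seeds (7-mers for positions 2-8)
  seeds <- character(0)
  while (length(seeds) < n_families)
    seeds <- unique(c(seeds, random_dna(n_families - length(seeds), 7)))
  fam_sizes <- rep(n_mirnas %/% n_families, n_families) +
    c(rep(1L, n_mirnas %% n_families), rep(0L, n_families - n_mirnas %% n_families))
  family_of <- rep(seq_len(n_families), fam_sizes)

  ## contaminants first so miRNAs can be checked against them
  contaminants <- data.frame(
    name = sprintf("decoy-mt-rRNA-%02d", seq_len(n_contaminants)),
    sequence = random_dna(n_contaminants, 80:120, rng_len = TRUE),
    stringsAsFactors = FALSE)

  ok_against_contaminants <- function(dna_seq) {
    L <- nchar(dna_seq)
    s <- seq_ints(dna_seq)
    for (cs in contaminants$sequence) {
      lc <- nchar(cs)
      if (lc < L) next
      ci <- seq_ints(cs)
      for (o in seq_len(lc - L + 1L)) {
        if (sum(ci[o:(o + L - 1L)] != s) <= 2L) return(FALSE)
      }
    }
    TRUE
  }

  sequences <- character(n_mirnas)
  for (i in seq_len(n_mirnas)) {
    sd7 <- seeds[family_of[i]]
    tries <- 0L
    repeat {
      tries <- tries + 1L
      if (tries > max_tries)
        stop("impossible constraints: could not generate a distinguishable sequence")
      L <- sample(20:23, 1)
      cand <- paste0(random_dna(1, 1), sd7, random_dna(1, L - 8L))
      if (max_base_fraction(cand) > 0.6) next
      prev <- sequences[seq_len(i - 1L)]
      if (i > 1L &&
          any(vapply(prev, hamming_prefix, integer(1), b = cand) <= 2L)) next
      if (!ok_against_contaminants(cand)) next
      sequences[i] <- cand
      break
    }
  }

  ## names; a random subset are star sequences
  is_star <- rep(FALSE, n_mirnas)
  if (star_fraction > 0)
    is_star[sample(n_mirnas, round(star_fraction * n_mirnas))] <- TRUE
  name <- sprintf("mmu-miR-%04d", seq_len(n_mirnas))
  name[is_star] <- paste0(name[is_star], "*")

  ## genomic placement: n_clusters tight groups, remaining loci isolated.
  ## A per-chromosome cursor keeps unrelated loci > 50 kb apart.
  chrom <- character(n_mirnas); start <- integer(n_mirnas)
  strand <- character(n_mirnas); cluster_truth <- integer(n_mirnas)
  cursor <- stats::setNames(rep(1e5, 19), paste0("chr", 1:19))
  shuffled <- sample(n_mirnas)
  sizes <- if (n_clusters > 0) sample(2:4, n_clusters, replace = TRUE) else integer(0)
  while (sum(sizes) > n_mirnas) sizes[which.max(sizes)] <- sizes[which.max(sizes)] - 1L
  pos <- 1L
  for (k in seq_len(n_clusters)) {
    members <- shuffled[pos:(pos + sizes[k] - 1L)]; pos <- pos + sizes[k]
    ch <- sample(names(cursor), 1); st <- sample(c("+", "-"), 1)
    at <- cursor[ch]
    for (m in members) {
      chrom[m] <- ch; strand[m] <- st; start[m] <- as.integer(at)
      cluster_truth[m] <- k
      at <- at + nchar(sequences[m]) + sample(200:3000, 1)
    }
    cursor[ch] <- at + 5e4
  }
  for (m in shuffled[seq(pos, length.out = n_mirnas - pos + 1L)]) {
    ch <- sample(names(cursor), 1)
    chrom[m] <- ch; strand[m] <- sample(c("+", "-"), 1)
    start[m] <- as.integer(cursor[ch])
    cursor[ch] <- cursor[ch] + 5e4
  }

  mirnas <- data.frame(
    name = name,
    sequence = as_rna(sequences),
    is_star = is_star,
    chrom = chrom,
    start = start,
    end = start + nchar(sequences) - 1L,
    strand = strand,
    family_id = NA_character_,
    cluster_id = NA_character_,
    stringsAsFactors = FALSE)

  ref <- structure(list(mirnas = mirnas, contaminants = contaminants),
                   class = "mirna_reference")
  ref$mirnas$family_id <- assign_families(ref)
  ref$mirnas$cluster_id <- assign_clusters(ref)
  ref
}

#' @export
print.mirna_reference <- function(x, ...) {
  cat("mirna_reference:", nrow(x$mirnas), "mature miRNAs (",
      sum(x$mirnas$is_star), "star ),",
      length(unique(x$mirnas$family_id)), "families,",
      length(unique(x$mirnas$cluster_id)), "cluster ids,",
      nrow(x$contaminants), "contaminant decoys\n")
  invisible(x)
}

#' Seed-family assignment
#'
#' Two miRNAs belong to the same family iff nucleotides 2--8 (the seed) of
#' their mature sequences are identical. Star sequences are assigned by
#' their own seed.
#'
#' @param reference a `mirna_reference`.
#' @return named character vector: miRNA name -> family id (`fam-<seed>`).
#' @export
assign_families <- function(reference) {
  seqs <- reference$mirnas$sequence
  if (any(nchar(seqs) < 8))
    stop("all sequences must be at least 8 nt to define a seed")
  sd7 <- substr(seqs, 2, 8)
  stats::setNames(paste0("fam-", sd7), reference$mirnas$name)
}

#' Genomic-cluster assignment
#'
#' Single-linkage grouping of miRNA loci: two loci join the same cluster iff
#' they lie on the same chromosome and strand and the gap between them
#' (next start minus previous end) is at most `max_gap`. Singletons receive
#' their own id.
#'
#' @param reference a `mirna_reference`.
#' @param max_gap maximum inter-locus gap in bp (default 10 kb).
#' @return named character vector: miRNA name -> cluster id.
#' @export
assign_clusters <- function(reference, max_gap = 10000) {
  m <- reference$mirnas
  ord <- order(m$chrom, m$strand, m$start)
  cl <- integer(nrow(m)); cur <- 0L
  prev_key <- ""; prev_end <- -Inf
  for (i in ord) {
    key <- paste(m$chrom[i], m$strand[i])
    if (key != prev_key || m$start[i] - prev_end > max_gap) cur <- cur + 1L
    cl[i] <- cur
    prev_end <- if (key == prev_key) max(prev_end, m$end[i]) else m$end[i]
    prev_key <- key
  }
  stats::setNames(sprintf("clu-%03d", cl), m$name)
}
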