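#' Adapter and index constants
#'
#' The three 6-nt library indexes (RNA alphabet) carried at the 3' end of the
#' 5' adapter, and the 3' adapter sequence, as used in the indexed small-RNA
#' library design this package emulates. Reads begin at the index because the
#' sequencing primer covers the constant part of the 5' adapter.
#' @export
default_indexes <- function() {
  c("Index 3" = "UUAGGC", "Index 7" = "CAGAUC", "Index 11" = "GGCUAC")
}

#' @rdname default_indexes
#' @export
default_adapter3 <- function() "UCGUAUGCCGUCUUCUGCUUG"

#' Simulate group-wise relative abundance profiles
#'
#' Baseline relative abundances are drawn log-normal with a heavy top, so a
#' handful of miRNAs dominate the library, as is typical for bulk small-RNA
#' sequencing of brain tissue. The second group's abundances equal the first
#' group's multiplied by the configured fold changes, then renormalized.
#'
#' @param reference a `mirna_reference`.
#' @param de_spec named numeric vector of fold changes (group2 / group1) for
#'   differentially expressed miRNAs; empty means identical profiles.
#' @param dispersion common negative-binomial dispersion phi >= 0
#'   (variance = mu + phi * mu^2) carried along for count simulation.
#' @param seed integer seed.
#' @param sdlog log-normal shape of the baseline profile; the default gives
#'   a top-15 count share in the high-skew range seen in real libraries.
#' @param groups group labels, first is baseline.
#' @return `abundance_profile`: list with `abundance` (miRNA x 2 matrix of
#'   relative abundances summing to 1 per column), `dispersion`, `de_spec`.
#' @export
simulate_abundances <- function(reference, de_spec = numeric(0), dispersion = 0.1,
                                seed = 1, sdlog = 2.5,
                                groups = c("FCx", "HP")) {
  if (dispersion < 0) stop("dispersion must be non-negative")
  if (length(de_spec) && any(de_spec <= 0)) stop("fold changes must be > 0")
  if (length(de_spec) && !all(names(de_spec) %in% reference$mirnas$name))
    stop("de_spec names must be miRNAs of the reference")
  set.seed(seed)
  nm <- reference$mirnas$name
  base <- stats::rlnorm(length(nm), meanlog = 0, sdlog = sdlog)
  g1 <- base / sum(base)
  fc <- stats::setNames(rep(1, length(nm)), nm)
  fc[names(de_spec)] <- de_spec
  g2 <- g1 * fc
  g2 <- g2 / sum(g2)
  ab <- cbind(g1, g2)
  dimnames(ab) <- list(nm, groups)
  structure(list(abundance = ab, dispersion = dispersion, de_spec = de_spec,
                 groups = groups),
            class = "abundance_profile")
}

# Gamma-weighted multinomial counts with NB-matched marginal moments under
# exact total conservation: weights w_i ~ Gamma(shape = 1/phi,
# scale = phi * p_i) have mean p_i and variance phi * p_i^2, so
# Var(K_i) ~ mu_i + phi * mu_i^2 for small p_i. phi = 0 degenerates to a
# plain multinomial.
rmultinom_nb <- function(n_total, prob, phi) {
  if (n_total == 0L) return(integer(length(prob)))
  if (phi <= 0) return(as.integer(stats::rmultinom(1, n_total, prob)))
  # normalizing by the weight sum adds Var(sum) = phi' * sum(p^2) to every
  # relative weight; shrink the working dispersion to compensate
  phi_w <- phi / (1 + sum(prob^2))
  w <- numeric(length(prob))
  pos <- prob > 0
  w[pos] <- stats::rgamma(sum(pos), shape = 1 / phi_w, scale = phi_w * prob[pos])
  if (all(w == 0)) w <- prob
  as.integer(stats::rmultinom(1, n_total, w / sum(w)))
}

#' Simulate one indexed sequencing library
#'
#' Generates fixed-length reads of structure
#' `[6-nt index][mature miRNA insert, with substitution errors][3' adapter]`,
#' truncated (or A-padded) to `read_length`. Contaminant read classes are
#' injected at the configured fractions: adapter dimers (index directly
#' followed by adapter), mitochondrial/ribosomal-like fragments drawn from
#' the reference's decoy set, homopolymer inserts, short (<14 nt) inserts,
#' and optionally reads whose index was corrupted by one substitution
#' (`unindexed`), which drive indexing efficiency below 100%. Per-read truth
#' labels are recorded and partition the library exactly.
#'
#' Per-miRNA clean-read counts are a multinomial draw with
#' negative-binomial-matched overdispersion (common dispersion phi from the
#' profile), so replicate libraries show Var ~ mu + phi * mu^2.
#'
#' @param reference a `mirna_reference`.
#' @param profile an `abundance_profile`.
#' @param group group label (column of the profile).
#' @param index 6-nt index sequence (RNA or DNA).
#' @param n_reads total number of reads.
#' @param error_rate per-base substitution probability on the mature insert.
#' @param contaminant_fractions named fractions for classes
#'   `adapter_dimer`, `contaminant`, `homopolymer`, `short_insert`,
#'   `unindexed`; must lie in `[0,1]` and sum to at most 1.
#' @param seed integer seed.
#' @param read_length fixed read length (sequencing cycles), default 36.
#' @param adapter3 3' adapter sequence (RNA or DNA).
#' @param sample_id library identifier.
#' @return `seq_library`: list with `sample_id`, `group`, `index` (RNA),
#'   `reads` (DNA, fixed length) and `truth` (data.frame: read_id, class,
#'   source).
#' @export
simulate_library <- function(reference, profile, group, index,
                             n_reads = 50000, error_rate = 0.005,
                             contaminant_fractions = c(
                               adapter_dimer = 0.05, contaminant = 0.18,
                               homopolymer = 0.02, short_insert = 0.03,
                               unindexed = 0.08),
                             seed = 1, read_length = 36,
                             adapter3 = default_adapter3(),
                             sample_id = paste0(group, "-", index)) {
  stopifnot(nchar(index) == 6, n_reads > 0)
  known <- c("adapter_dimer", "contaminant", "homopolymer", "short_insert",
             "unindexed")
  cf <- stats::setNames(rep(0, length(known)), known)
  if (length(contaminant_fractions)) {
    if (is.null(names(contaminant_fractions)) ||
        !all(names(contaminant_fractions) %in% known))
      stop("unknown contaminant class")
    cf[names(contaminant_fractions)] <- contaminant_fractions
  }
  if (any(cf < 0) || any(cf > 1) || sum(cf) > 1)
    stop("contaminant fractions must lie in [0,1] and sum to at most 1")
  if (!group %in% colnames(profile$abundance))
    stop("unknown group: ", group)
  set.seed(seed)

  idx_dna <- as_dna(index)
  ad_dna <- as_dna(adapter3)
  phi <- profile$dispersion

  class_n <- as.integer(stats::rmultinom(1, n_reads, c(clean = 1 - sum(cf), cf)))
  names(class_n) <- c("clean", known)

  finish_read <- function(x) {
    # truncate/pad to the fixed cycle count
    x <- substr(paste0(x, strrep("A", read_length)), 1, read_length)
    x
  }

  reads <- character(0); class <- character(0); source <- character(0)

  ## clean miRNA reads
  p <- profile$abundance[, group]
  counts <- rmultinom_nb(class_n[["clean"]], p, phi)
  if (sum(counts) > 0) {
    src <- rep(rownames(profile$abundance), counts)
    ins <- as_dna(rep(reference$mirnas$sequence[
      match(rownames(profile$abundance), reference$mirnas$name)], counts))
    ins <- apply_substitutions(ins, error_rate)
    reads <- c(reads, finish_read(paste0(idx_dna, ins, ad_dna)))
    class <- c(class, rep("clean", length(ins)))
    source <- c(source, src)
  }

  add_class <- function(n, cls, make) {
    if (n == 0L) return(invisible())
    r <- make(n)
    reads <<- c(reads, finish_read(r))
    class <<- c(class, rep(cls, n))
    source <<- c(source, rep(NA_character_, n))
  }
  add_class(class_n[["adapter_dimer"]], "adapter_dimer",
            function(n) rep(paste0(idx_dna, ad_dna), n))
  add_class(class_n[["contaminant"]], "contaminant", function(n) {
    if (nrow(reference$contaminants) == 0L)
      stop("reference has no contaminants to draw from")
    cs <- sample(reference$contaminants$sequence, n, replace = TRUE)
    L <- sample(16:28, n, replace = TRUE)
    off <- floor(stats::runif(n) * (nchar(cs) - L)) + 1L
    paste0(idx_dna, substr(cs, off, off + L - 1L), ad_dna)
  })
  add_class(class_n[["homopolymer"]], "homopolymer", function(n) {
    paste0(idx_dna, strrep(sample(DNA_BASES, n, replace = TRUE),
                           sample(18:24, n, replace = TRUE)), ad_dna)
  })
  add_class(class_n[["short_insert"]], "short_insert", function(n) {
    paste0(idx_dna, random_dna(n, 12:13, rng_len = TRUE), ad_dna)
  })
  add_class(class_n[["unindexed"]], "unindexed", function(n) {
    bad <- corrupt_index(rep(idx_dna, n))
    p2 <- if (sum(p) > 0) p else rep(1, length(p))
    src <- sample(rownames(profile$abundance), n, replace = TRUE, prob = p2)
    ins <- as_dna(reference$mirnas$sequence[match(src, reference$mirnas$name)])
    paste0(bad, ins, ad_dna)
  })

  ord <- sample(length(reads))
  truth <- data.frame(read_id = sprintf("read-%06d", seq_along(ord)),
                      class = class[ord], source = source[ord],
                      stringsAsFactors = FALSE)
  structure(list(sample_id = sample_id, group = group, index = as_rna(index),
                 reads = stats::setNames(reads[ord], truth$read_id),
                 truth = truth),
            class = "seq_library")
}

#' @export
print.seq_library <- function(x, ...) {
  cat("seq_library", x$sample_id, "(group", x$group, ", index", x$index, "):",
      length(x$reads), "reads of", unique(nchar(x$reads)), "nt\n")
  print(table(x$truth$class))
  invisible(x)
}

# substitution errors: each base flips to one of the 3 others independently
apply_substitutions <- function(seqs, error_rate) {
  if (error_rate <= 0 || length(seqs) == 0L) return(seqs)
  lens <- nchar(seqs)
  n_err <- stats::rbinom(length(seqs), lens, error_rate)
  hit <- which(n_err > 0L)
  for (i in hit) {
    pos <- sample(lens[i], n_err[i])
    for (p0 in pos) {
      old <- substr(seqs[i], p0, p0)
      substr(seqs[i], p0, p0) <- sample(setdiff(DNA_BASES, old), 1)
    }
  }
  seqs
}

# one substitution somewhere in the 6-nt index
corrupt_index <- function(idx) {
  for (i in seq_along(idx)) {
    p0 <- sample(6L, 1)
    old <- substr(idx[i], p0, p0)
    substr(idx[i], p0, p0) <- sample(setdiff(DNA_BASES, old), 1)
  }
  idx
}

#' Simulate a microarray signal matrix matched to an abundance profile
#'
#' Array signal is modelled as a monotone compressive function of abundance:
#' `log2 signal = background + compression * log2(abundance / min abundance)
#' + Gaussian noise`. Compression < 1 shrinks the dynamic range relative to
#' counts, reproducing the hallmark that the top-ranked miRNAs hold a much
#' smaller share of total array signal than of sequencing counts.
#'
#' @param profile an `abundance_profile` (both groups are used).
#' @param n_replicates replicates per group.
#' @param compression slope in (0, 1].
#' @param noise_sd Gaussian noise standard deviation (log2 units).
#' @param background baseline log2 signal of an absent miRNA.
#' @param seed integer seed.
#' @return `array_matrix`: numeric miRNA x (2 * n_replicates) matrix of
#'   normalized log2 signals with attributes `groups` (column group labels),
#'   `background`, `noise_sd`.
#' @export
simulate_array <- function(profile, n_replicates = 3, compression = 0.5,
                           noise_sd = 0.5, background = 2, seed = 1) {
  stopifnot(compression > 0, compression <= 1, noise_sd >= 0, n_replicates >= 1)
  set.seed(seed)
  ab <- profile$abundance
  grp <- rep(colnames(ab), each = n_replicates)
  # one global reference point so equal abundances give equal expected signal
  mu <- background + compression * log2(ab / min(ab))
  sig <- mu[, grp] + stats::rnorm(nrow(ab) * length(grp), 0, noise_sd)
  colnames(sig) <- paste0(grp, "-rep", rep(seq_len(n_replicates), 2))
  structure(sig, groups = stats::setNames(grp, colnames(sig)),
            background = background, noise_sd = noise_sd,
            class = c("array_matrix", "matrix"))
}

#' Simulate a binding-site prediction table
#'
#' Emulates the output of several independent target-prediction programs:
#' true (planted) miRNA-gene pairs receive elevated site counts and are
#' reported by several programs; background pairs carry sites scattered at
#' the background Poisson rate and are reported by each program
#' independently with probability `q`.
#'
#' @param mirnas character vector of miRNA names to scan.
#' @param n_genes number of genes.
#' @param programs program labels.
#' @param background_rate expected binding sites per UTR nucleotide under
#'   the null.
#' @param q per-program probability of reporting a background pair that has
#'   at least one site.
#' @param planted data.frame (mirna, gene, n_sites, n_programs) of true
#'   consensus pairs, or NULL.
#' @param seed integer seed.
#' @return data.frame with columns mirna, gene, program, n_sites, utr_length.
#' @export
simulate_binding_sites <- function(mirnas, n_genes = 200,
                                   programs = paste0("P", 1:5),
                                   background_rate = 1e-4, q = 0.3,
                                   planted = NULL, seed = 1) {
  set.seed(seed)
  genes <- sprintf("gene-%04d", seq_len(n_genes))
  utr <- stats::setNames(sample(300:3000, n_genes, replace = TRUE), genes)
  rows <- list()
  for (m in mirnas) {
    k <- stats::rpois(n_genes, background_rate * utr)
    hit <- which(k > 0)
    for (g in hit) {
      rep_by <- programs[stats::runif(length(programs)) < q]
      for (pr in rep_by)
        rows[[length(rows) + 1L]] <- data.frame(
          mirna = m, gene = genes[g], program = pr, n_sites = k[g],
          utr_length = utr[[g]], stringsAsFactors = FALSE)
    }
  }
  if (!is.null(planted)) {
    for (i in seq_len(nrow(planted))) {
      g <- planted$gene[i]
      if (!g %in% genes) stop("planted gene not in gene universe")
      prs <- sample(programs, planted$n_programs[i])
      for (pr in prs)
        rows[[length(rows) + 1L]] <- data.frame(
          mirna = planted$mirna[i], gene = g, program = pr,
          n_sites = planted$n_sites[i], utr_length = utr[[g]],
          stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(mirna = character(0), gene = character(0),
                      program = character(0), n_sites = integer(0),
                      utr_length = integer(0), stringsAsFactors = FALSE)
  ## a pair may appear twice for one program (background + planted): keep max
  key <- paste(out$mirna, out$gene, out$program)
  out <- out[order(key, -out$n_sites), ]
  out <- out[!duplicated(paste(out$mirna, out$gene, out$program)), ]
  rownames(out) <- NULL
  out
}
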