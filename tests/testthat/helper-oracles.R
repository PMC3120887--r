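# Independent brute-force oracles. These deliberately share no code with the
# package internals: plain character loops, direct enumeration, definitional
# formulas.

oracle_hamming <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  L <- min(length(ca), length(cb))
  sum(ca[seq_len(L)] != cb[seq_len(L)])
}

# earliest adapter-prefix match by direct scanning, one read at a time
oracle_trim_one <- function(read, index_len, adapter, min_overlap = 7,
                            mismatch_rate = 0.1) {
  rem <- substring(read, index_len + 1)
  W <- nchar(rem); la <- nchar(adapter)
  for (p in seq_len(W)) {
    L <- min(W - p + 1, la)
    allowed <- if (L >= min_overlap) floor(L * mismatch_rate) else 0
    mm <- oracle_hamming(substring(rem, p, p + L - 1), substring(adapter, 1, L))
    if (mm <= allowed)
      return(list(insert = substring(rem, 1, p - 1),
                  status = if (p == 1) "dimer" else "trimmed"))
  }
  list(insert = rem, status = "untrimmed")
}

oracle_classify_one <- function(insert, contaminants, is_dimer,
                                max_mm = 2, hp_frac = 0.8, min_len = 14) {
  if (is_dimer || nchar(insert) == 0) return("dimer")
  L <- nchar(insert)
  for (cs in contaminants) {
    lc <- nchar(cs)
    if (lc < L) next
    for (o in seq_len(lc - L + 1))
      if (oracle_hamming(insert, substring(cs, o, o + L - 1)) <= max_mm)
        return("contaminant")
  }
  tab <- table(strsplit(insert, "")[[1]])
  if (max(tab) / L > hp_frac) return("homopolymer")
  if (L < min_len) return("short")
  "keep"
}

# all-reference Hamming scan with lexicographic tie-break
oracle_align_one <- function(insert, ref_names, ref_seqs, max_mm = 2,
                             max_overhang = 3) {
  best_mm <- Inf; best <- NA_character_
  ord <- order(ref_names)
  for (i in ord) {
    if (abs(nchar(ref_seqs[i]) - nchar(insert)) > max_overhang) next
    mm <- oracle_hamming(insert, ref_seqs[i])
    if (mm < best_mm) { best_mm <- mm; best <- ref_names[i] }
  }
  if (best_mm > max_mm) list(mirna = NA_character_, mm = NA_integer_)
  else list(mirna = best, mm = best_mm)
}

# conditional binomial enumeration via log-factorials (no dbinom)
oracle_binom_exact <- function(y1, s, p1) {
  lp <- function(a) lgamma(s + 1) - lgamma(a + 1) - lgamma(s - a + 1) +
    a * log(p1) + (s - a) * log(1 - p1)
  all_lp <- vapply(0:s, lp, numeric(1))
  sum(exp(all_lp[all_lp <= lp(y1) + 1e-10]))
}

# definitional BH step-up: q_i = min over k with p_(k) >= p_i of p_(k)*m/k
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- Inf
    for (k in seq_len(m)) if (ps[k] >= ps[i] - 1e-15)
      cand <- min(cand, ps[k] * m / k)
    q[i] <- min(1, cand)
  }
  out <- numeric(m); out[ord] <- q
  out
}

# direct Poisson pmf summation of the upper tail (numerically stable for
# deep tails, unlike 1 - lower sum)
oracle_poisson_tail <- function(k, lambda) {
  if (k == 0) return(1)
  i <- k:(k + 2000)
  sum(exp(-lambda + i * log(lambda) - lgamma(i + 1)))
}

# ordered-list score by explicit set intersections
oracle_ol_score <- function(va, vb, beta, two_sided = TRUE) {
  ids <- sort(names(va))
  oa <- ids[order(-va[ids])]; ob <- ids[order(-vb[ids])]
  N <- length(ids); sc <- 0
  for (n in seq_len(N)) {
    ov <- length(intersect(oa[1:n], ob[1:n]))
    if (two_sided)
      ov <- ov + length(intersect(rev(oa)[1:n], rev(ob)[1:n]))
    sc <- sc + exp(-beta * n) * ov
  }
  sc
}

# brute-force consensus filter
oracle_consensus <- function(pred, alpha, min_programs, rate) {
  pred <- pred[!grepl("*", pred$mirna, fixed = TRUE), , drop = FALSE]
  keys <- unique(paste(pred$mirna, pred$gene, sep = "|"))
  out <- data.frame()
  for (k in keys) {
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    rows <- pred[pred$mirna == parts[1] & pred$gene == parts[2], ]
    ks <- max(rows$n_sites)
    lam <- rate * max(rows$utr_length)
    p <- 1 - sum(exp(-lam + (0:(ks - 1)) * log(lam) - lgamma(1:ks)))
    np <- length(unique(rows$program))
    out <- rbind(out, data.frame(
      mirna = parts[1], gene = parts[2],
      pass = (p < alpha) && (np >= min_programs)))
  }
  out
}

random_reads <- function(n, len = 36) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

# small shared fixture: reference + profile
tiny_ref <- function(seed = 101, ...) build_reference(
  n_mirnas = 30, n_families = 6, n_clusters = 3, n_contaminants = 3,
  seed = seed, ...)
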