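test_that("alignment: exact hits, mismatch cap, deterministic tie-break", {
  ref <- tiny_ref()
  s <- as_dna(ref$mirnas$sequence)
  al <- align_inserts(s[3], ref)
  expect_equal(al$mirna, ref$mirnas$name[3])
  expect_equal(al$mismatches, 0L)

  # three substitutions push it beyond the cap (no other reference is near)
  bad <- s[3]
  for (p in c(3, 9, 15))
    substr(bad, p, p) <- setdiff(c("A", "C", "G", "T"),
                                 substr(bad, p, p))[1]
  expect_true(is.na(align_inserts(bad, ref)$mirna))

  # constructed equidistant tie resolves to the lexicographically first name
  ref2 <- list(mirnas = data.frame(
    name = c("mmu-miR-0002", "mmu-miR-0001"),
    sequence = c("ACGUACGUACGUACGUACGU", "ACGUACGUACGUACGUACGA"),
    stringsAsFactors = FALSE))
  probe <- "ACGTACGTACGTACGTACGC"         # 1 mismatch from both
  expect_equal(oracle_hamming(probe, "ACGTACGTACGTACGTACGT"), 1)
  expect_equal(oracle_hamming(probe, "ACGTACGTACGTACGTACGA"), 1)
  expect_equal(align_inserts(probe, ref2)$mirna, "mmu-miR-0001")

  expect_error(align_inserts("ACGT", list(mirnas = data.frame())), "empty")
})

test_that("alignment agrees with the brute-force Hamming scan", {
  set.seed(77)
  ref <- tiny_ref()
  s <- as_dna(ref$mirnas$sequence)
  inserts <- c(
    s[sample(length(s), 200, replace = TRUE)],
    vapply(s[sample(length(s), 200, replace = TRUE)], function(x) {
      k <- sample(0:4, 1)
      for (p in sample(nchar(x), k))
        substr(x, p, p) <- sample(c("A", "C", "G", "T"), 1)
      x
    }, character(1)),
    random_reads(100, len = 20))
  got <- align_inserts(inserts, ref)
  for (i in seq_along(inserts)) {
    o <- oracle_align_one(inserts[i], ref$mirnas$name, s)
    expect_identical(got$mirna[i], o$mirna)
    if (!is.na(o$mirna)) expect_equal(got$mismatches[i], o$mm)
  }
})

test_that("count table applies the single-count elimination per group", {
  hits <- list(F1 = c("miR-a", "miR-b", "miR-b"), F2 = c("miR-b"),
               H1 = c("miR-b", "miR-c", "miR-c"), H2 = character(0))
  groups <- c(F1 = "FCx", F2 = "FCx", H1 = "HP", H2 = "HP")
  ct <- build_count_table(hits, groups)
  # miR-a: single read in FCx only -> not detected anywhere, but row kept
  expect_false("miR-a" %in% ct$detected$FCx)
  expect_true("miR-a" %in% rownames(ct$counts))
  # miR-b: 3 in FCx, 1 in HP -> detected in FCx only
  expect_true("miR-b" %in% ct$detected$FCx)
  expect_false("miR-b" %in% ct$detected$HP)
  expect_true("miR-c" %in% ct$detected$HP)
  # empty input: empty table, no failure
  ct0 <- build_count_table(list(F1 = character(0)), groups["F1"])
  expect_equal(nrow(ct0$counts), 0)
})

test_that("error-free synthetic counts equal the generator truth", {
  ref <- tiny_ref()
  prof <- simulate_abundances(ref, numeric(0), 0.1, seed = 8)
  libs <- list()
  for (k in 1:2)
    libs[[paste0("L", k)]] <- simulate_library(
      ref, prof, "FCx", "UUAGGC", n_reads = 3000, error_rate = 0,
      seed = 20 + k, sample_id = paste0("L", k))
  pp <- run_preprocess(libs, ref)
  hits <- lapply(pp, function(x) align_inserts(x$inserts$insert, ref)$mirna)
  ct <- build_count_table(hits, c(L1 = "FCx", L2 = "FCx"))
  for (k in 1:2) {
    tr <- libs[[k]]$truth
    truth_counts <- table(tr$source[tr$class == "clean"])
    got <- ct$counts[, paste0("L", k)]
    expect_equal(got[names(truth_counts)], unclass(truth_counts),
                 ignore_attr = TRUE)
    expect_equal(sum(got), sum(truth_counts))
  }
})

test_that("abundance share matches a direct sort-and-sum oracle", {
  m <- matrix(c(100L, 0L, 5L, 3L, 2L, 1L), ncol = 2,
              dimnames = list(c("a", "b", "c"), c("L1", "L2")))
  ct <- count_table(m, c(L1 = "g1", L2 = "g2"))
  tot <- rowSums(m)
  expect_equal(abundance_share(ct, k = 1),
               max(tot) / sum(tot))
  expect_equal(abundance_share(ct, k = 2),
               sum(sort(tot, decreasing = TRUE)[1:2]) / sum(tot))
  expect_warning(sh <- abundance_share(ct, k = 15), "exceeds")
  expect_equal(sh, 1)
  # uniform over 30 miRNAs, k = 15 -> 0.5
  u <- matrix(1L, 30, 1, dimnames = list(sprintf("m%02d", 1:30), "L1"))
  expect_equal(abundance_share(count_table(u, c(L1 = "g")), 15), 0.5)
})

test_that("run report carries the full accounting schema and is consistent", {
  ref <- tiny_ref()
  prof <- simulate_abundances(ref, numeric(0), 0.1, seed = 9)
  libs <- list(A1 = simulate_library(ref, prof, "FCx", "UUAGGC", 2000,
                                     seed = 31, sample_id = "A1"),
               B1 = simulate_library(ref, prof, "HP", "CAGAUC", 2000,
                                     seed = 32, sample_id = "B1"))
  pp <- run_preprocess(libs, ref)
  hits <- lapply(pp, function(x) align_inserts(x$inserts$insert, ref)$mirna)
  groups <- c(A1 = "FCx", B1 = "HP")
  ct <- build_count_table(hits, groups)
  rep <- summarize_run(pp, hits, ct, groups)
  expect_true(all(c(
    "# of technical replicates",
    "# of pre-filtered reads after base calling",
    "# of sorted reads with indexes",
    "Indexing efficiency (%)",
    "# of trimmed reads without mitochondrial and ribosomal sequences",
    "# of reads aligning against the mature reference",
    "# of known miRNAs",
    "# of reads aligning against the mature reference with >=2 reads",
    "# of known miRNAs with >=2 reads") %in% rep$row_label))
  expect_equal(names(rep), c("row_label", "FCx", "HP"))
  # reads aligned equals the count-table column total
  got <- rep$FCx[rep$row_label == "# of reads aligning against the mature reference"]
  expect_equal(got, sum(ct$counts[, "A1"]))
  # zero-read input reports zeros
  pp0 <- run_preprocess(list(list(sample_id = "Z", reads = character(0))), ref)
  rep0 <- summarize_run(pp0, list(Z = character(0)),
                        build_count_table(list(Z = character(0)), c(Z = "g")),
                        c(Z = "g"))
  expect_true(all(rep0$g[rep0$row_label != "# of technical replicates"] == 0))
})
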