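test_that("demultiplexing assigns by exact index prefix", {
  reads <- c(paste0("TTAGGC", strrep("A", 30)),
             paste0("CAGATC", strrep("C", 30)),
             paste0("GGCTAC", strrep("G", 30)),
             paste0("ACGTAC", strrep("T", 30)))
  d <- demultiplex(reads)
  expect_equal(d$by_index[["Index 3"]], 1L)
  expect_equal(d$by_index[["Index 7"]], 2L)
  expect_equal(d$by_index[["Index 11"]], 3L)
  expect_equal(d$unassigned, 4L)
  expect_error(demultiplex(reads, c(a = "UUAGGC", b = "UUAGGC")), "duplicate")
  expect_error(demultiplex(reads, c(a = "UUAGG")), "6 nt")
})

test_that("trimming finds the earliest adapter prefix and handles edge cases", {
  ad <- as_dna(default_adapter3())
  insert22 <- "ACGTACGTACGTACGTACGTAC"
  read <- substr(paste0("TTAGGC", insert22, ad), 1, 36)  # 8 nt of adapter
  tr <- trim_reads(read)
  expect_equal(tr$insert, insert22)
  expect_equal(tr$status, "trimmed")

  dimer <- substr(paste0("TTAGGC", ad, strrep("A", 20)), 1, 36)
  expect_equal(trim_reads(dimer)$status, "dimer")

  noad <- paste0("TTAGGC", strrep("ACGTA", 6))           # no adapter at all
  tr <- trim_reads(noad)
  expect_equal(tr$status, "untrimmed")
  expect_equal(nchar(tr$insert), 30)

  # one mismatch in a >= 10 nt adapter overlap is tolerated
  insert20 <- substr(insert22, 1, 20)
  ad_mm <- ad
  substr(ad_mm, 3, 3) <- if (substr(ad, 3, 3) == "A") "C" else "A"
  read_mm <- substr(paste0("TTAGGC", insert20, ad_mm), 1, 36)
  expect_equal(trim_reads(read_mm)$insert, insert20)

  expect_error(trim_reads("TTAGGC"), "shorter")
})

test_that("insert classification applies the fixed discard precedence", {
  cont <- c(strrep("ACGT", 20))
  # 17 of 18 = 94% A -> homopolymer
  expect_equal(classify_inserts(paste0(strrep("A", 17), "C"), cont),
               "homopolymer")
  # exactly 80% is kept (rule is strictly greater)
  ins80 <- paste0(strrep("A", 16), "CGTC")
  expect_equal(classify_inserts(ins80, cont), "keep")
  # 13 nt non-contaminant -> short
  expect_equal(classify_inserts("TTTGGGCCCAATT", cont), "short")
  # subsequence of a contaminant with 2 mismatches -> contaminant
  sub <- substr(cont, 5, 24)
  substr(sub, 2, 2) <- "T"; substr(sub, 10, 10) <- "T"
  expect_equal(classify_inserts(sub, cont), "contaminant")
  # dimer flag wins over everything
  expect_equal(classify_inserts("", cont), "dimer")
  expect_equal(classify_inserts(sub, cont, dimer = TRUE), "dimer")
})

test_that("filter cascade agrees with the brute-force oracle on random reads", {
  set.seed(404)
  ref <- tiny_ref()
  cont <- as_dna(ref$contaminants$sequence)
  ad <- as_dna(default_adapter3())
  # a mixture of structured and fully random reads
  prof <- simulate_abundances(ref, numeric(0), 0.1, seed = 1)
  lib <- simulate_library(ref, prof, "FCx", "UUAGGC", n_reads = 600, seed = 2)
  reads <- c(unname(lib$reads), random_reads(400))
  tr <- trim_reads(reads)
  got <- classify_inserts(tr$insert, cont, dimer = tr$status == "dimer")
  for (i in seq_along(reads)) {
    otr <- oracle_trim_one(reads[i], 6, ad)
    expect_identical(tr$insert[i], otr$insert)
    expect_identical(got[i],
                     oracle_classify_one(otr$insert, cont,
                                         otr$status == "dimer"))
  }
})

test_that("preprocessing recovers the truth on synthetic libraries", {
  ref <- tiny_ref()
  prof <- simulate_abundances(ref, numeric(0), 0.1, seed = 3)
  lib <- simulate_library(ref, prof, "FCx", "UUAGGC", n_reads = 4000,
                          error_rate = 0, seed = 4)
  pp <- run_preprocess(lib, ref)[[1]]
  truth <- lib$truth
  # every retained insert comes from a clean read
  retained_class <- truth$class[match(pp$inserts$read_id, truth$read_id)]
  expect_true(all(retained_class == "clean"))
  # every clean read is retained, every dimer-truth read discarded as dimer
  expect_equal(pp$stats$retained, sum(truth$class == "clean"))
  expect_equal(pp$stats$dimer_discarded, sum(truth$class == "adapter_dimer"))
  expect_equal(pp$stats$unassigned, sum(truth$class == "unindexed"))
  validate <- mirseqpipe:::validate_preprocess_stats
  expect_silent(validate(pp$stats))
})

test_that("indexing efficiency is 100% without index-corrupting classes", {
  ref <- tiny_ref()
  prof <- simulate_abundances(ref, numeric(0), 0.1, seed = 3)
  lib <- simulate_library(ref, prof, "FCx", "UUAGGC", n_reads = 500,
                          error_rate = 0, contaminant_fractions = numeric(0),
                          seed = 5)
  pp <- run_preprocess(lib, ref)[[1]]
  expect_equal(pp$stats$indexing_efficiency, 1)
  expect_equal(pp$stats$retained, 500)
})

test_that("a pooled equal-proportion lane splits into near-equal thirds", {
  ref <- tiny_ref()
  prof <- simulate_abundances(ref, numeric(0), 0.1, seed = 6)
  idx <- default_indexes()
  libs <- lapply(seq_along(idx), function(i)
    simulate_library(ref, prof, "FCx", idx[[i]], n_reads = 10000,
                     contaminant_fractions = numeric(0), seed = 10 + i))
  pooled <- list(sample_id = "pooled",
                 reads = unname(unlist(lapply(libs, `[[`, "reads"))))
  pp <- run_preprocess(list(pooled), ref)[[1]]
  frac <- pp$stats$per_index / pp$stats$index_assigned
  expect_true(all(abs(frac - 1 / 3) < 0.02))
})

test_that("empty input yields zeroed stats without failure", {
  ref <- tiny_ref()
  pp <- run_preprocess(list(list(sample_id = "empty", reads = character(0))),
                       ref)[[1]]
  expect_equal(pp$stats$input, 0)
  expect_equal(pp$stats$retained, 0)
  expect_equal(pp$stats$indexing_efficiency, 0)
  expect_equal(nrow(pp$inserts), 0)
})
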