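grp6 <- setNames(rep(c("A", "B"), each = 3), paste0("L", 1:6))

sim_ct <- function(mu, size, n = 6, seed = 1, groups = grp6) {
  set.seed(seed)
  cnt <- vapply(seq_len(n), function(j)
    if (is.finite(size)) as.numeric(rnbinom(length(mu), mu = mu, size = size))
    else rpois(length(mu), mu), numeric(length(mu)))
  rownames(cnt) <- sprintf("m%04d", seq_along(mu))
  colnames(cnt) <- names(groups)
  count_table(cnt, groups)
}

test_that("geometric normalization: factors, concentrations, invariance", {
  m <- matrix(c(5L, 5L, 10L, 10L), 2, 2,
              dimnames = list(c("a", "b"), c("L1", "L2")))
  ct <- count_table(m, c(L1 = "A", L2 = "B"))
  nm <- normalize_geometric(ct)
  expect_equal(unname(nm$factors), c(10 / sqrt(200), 20 / sqrt(200)))
  expect_equal(unname(nm$concentration[, 1]), c(0.5, 0.5))

  # totals (1e6, 4e6) -> factors (0.5, 2.0)
  m2 <- matrix(c(1e6, 4e6), 1, 2, dimnames = list("a", c("L1", "L2")))
  nm2 <- normalize_geometric(count_table(m2, c(L1 = "A", L2 = "B")))
  expect_equal(unname(nm2$factors), c(0.5, 2.0))

  # scaling all counts by a constant leaves concentrations unchanged
  nm3 <- normalize_geometric(count_table(m * 7L, c(L1 = "A", L2 = "B")))
  expect_equal(nm3$concentration, nm$concentration)

  m4 <- cbind(m, L3 = c(0L, 0L))
  expect_warning(normalize_geometric(
    count_table(m4, c(L1 = "A", L2 = "B", L3 = "B"))), "zero-total")
})

test_that("common dispersion: Poisson near zero, NB recovered, zero residuals", {
  set.seed(11)
  mu <- rlnorm(400, log(100), 1)
  expect_lt(estimate_common_dispersion(sim_ct(mu, Inf, seed = 2))$phi, 0.02)

  phis <- vapply(1:20, function(s)
    estimate_common_dispersion(sim_ct(mu, 10, seed = 100 + s))$phi, numeric(1))
  expect_gt(mean(phis), 0.05)
  expect_lt(mean(phis), 0.2)
  expect_true(all(phis >= 0))

  # duplicated identical libraries -> zero residual variance -> phi = 0
  cnt <- matrix(rep(c(10L, 20L, 300L), 4), 3, 4,
                dimnames = list(c("a", "b", "c"), paste0("L", 1:4)))
  ctdup <- count_table(cnt, setNames(rep(c("A", "B"), each = 2),
                                     paste0("L", 1:4)))
  expect_equal(estimate_common_dispersion(ctdup)$phi, 0)
  # no replicates anywhere -> phi 0 with warning
  ct1 <- count_table(cnt[, 1:2], c(L1 = "A", L2 = "B"))
  expect_warning(d0 <- estimate_common_dispersion(ct1), "replicates")
  expect_equal(d0$phi, 0)
})

test_that("exact test: symmetric case, binomial reduction, basic contracts", {
  expect_equal(nb_exact_test(7, 7, 3, 3, 0.1), 1)
  expect_equal(nb_exact_test(0, 0, 3, 3, 0.1), 1)
  # phi = 0, equal sizes, observed (0, 10): 2 * 2^-10
  expect_equal(nb_exact_test(0, 10, 3, 3, 0), 2 * 2^-10, tolerance = 1e-12)
  # symmetry in the two groups
  for (y in list(c(3, 12), c(0, 5), c(20, 8))) {
    expect_equal(nb_exact_test(y[1], y[2], 3, 3, 0.2),
                 nb_exact_test(y[2], y[1], 3, 3, 0.2))
  }
  # p is non-increasing as the split moves away from the conditional mode
  ps <- vapply(0:10, function(a) nb_exact_test(a, 20 - a, 3, 3, 0.1),
               numeric(1))
  expect_true(all(diff(ps) >= -1e-12))
})

test_that("exact test matches the conditional binomial oracle on a grid", {
  for (s in c(1, 2, 5, 9, 17, 30)) for (a in 0:s) {
    expect_equal(nb_exact_test(a, s - a, 3, 3, 0),
                 oracle_binom_exact(a, s, 0.5), tolerance = 1e-10)
  }
  # unequal group sizes condition on n1/(n1+n2)
  for (a in 0:12)
    expect_equal(nb_exact_test(a, 12 - a, 2, 4, 0),
                 oracle_binom_exact(a, 12, 2 / 6), tolerance = 1e-10)
})

test_that("BH adjustment matches the definitional step-up oracle", {
  expect_equal(bh_adjust(0.02), 0.02)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(5)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("de_table flags planted changes and not identical counts", {
  set.seed(21)
  mu <- rep(100, 60)
  cnt <- vapply(1:6, function(j) rnbinom(60, mu = mu, size = 10) + 0, numeric(60))
  cnt[1, 4:6] <- cnt[1, 4:6] * 8L           # strong planted change
  cnt[2, ] <- 50L                           # identical in both groups
  rownames(cnt) <- sprintf("m%04d", 1:60); colnames(cnt) <- names(grp6)
  de <- de_table(count_table(cnt, grp6), phi = 0.1)
  expect_true(de$significant[de$mirna == "m0001"])
  expect_false(de$significant[de$mirna == "m0002"])
  expect_equal(de$direction[de$mirna == "m0001"], "B")
  expect_true(all(de$p_value > 0 & de$p_value <= 1))
  expect_true(all(de$bh_q >= de$p_value - 1e-12))
})

test_that("present calls require 2 of 3 replicates above background", {
  sig <- matrix(2, 3, 6, dimnames = list(c("a", "b", "c"), NULL))
  grp <- setNames(rep(c("A", "B"), each = 3), paste0("r", 1:6))
  colnames(sig) <- names(grp)
  sig["a", 1:2] <- 8   # 2 of 3 above threshold in A
  sig["b", 1] <- 8     # 1 of 3
  am <- structure(sig, groups = grp, background = 2, noise_sd = 0.5,
                  class = c("array_matrix", "matrix"))
  pc <- array_present_calls(am)
  expect_true("a" %in% pc$detected$A)
  expect_false("b" %in% pc$detected$A)
  expect_length(pc$detected$B, 0)
})

test_that("moderated t: limit identities and null calibration", {
  set.seed(31)
  n1 <- n2 <- 3
  x <- matrix(rnorm(500 * 6), 500, 6)
  m1 <- rowMeans(x[, 1:3]); m2 <- rowMeans(x[, 4:6])
  v1 <- apply(x[, 1:3], 1, var); v2 <- apply(x[, 4:6], 1, var)
  s2 <- (2 * v1 + 2 * v2) / 4
  mt <- mirseqpipe:::moderated_t_stats

  # d0 -> 0: ordinary pooled two-sample t
  got <- mt(m1, m2, s2, 3, 3, d0 = 0, s02 = 1)
  ref_t <- (m2 - m1) / sqrt(s2 * (2 / 3))
  expect_equal(got$t, ref_t, tolerance = 1e-12)
  # d0 -> Inf: all variances shrink to s0^2
  got_inf <- mt(m1, m2, s2, 3, 3, d0 = Inf, s02 = 0.7)
  expect_true(all(abs(got_inf$s2_post - 0.7) < 1e-12))

  # all-null Gaussian calibration
  grp <- setNames(rep(c("A", "B"), each = 3), paste0("r", 1:6))
  am <- structure(matrix(rnorm(1000 * 6, 5, 1), 1000, 6,
                         dimnames = list(sprintf("g%04d", 1:1000),
                                         names(grp))),
                  groups = grp, background = 0, noise_sd = 1,
                  class = c("array_matrix", "matrix"))
  de <- array_de_moderated_t(am)
  frac <- mean(de$p_value < 0.05)
  expect_gt(frac, 0.03); expect_lt(frac, 0.07)
})

test_that("moderated t agrees with the limma cross-check", {
  skip_if_not_installed("limma")
  set.seed(41)
  grp <- setNames(rep(c("A", "B"), each = 3), paste0("r", 1:6))
  sig <- matrix(rnorm(400 * 6, 6, 1.2), 400, 6,
                dimnames = list(sprintf("g%04d", 1:400), names(grp)))
  sig[1:20, 4:6] <- sig[1:20, 4:6] + 2
  am <- structure(sig, groups = grp, background = 0, noise_sd = 1,
                  class = c("array_matrix", "matrix"))
  de <- array_de_moderated_t(am)
  design <- cbind(1, grp == "B")
  fit <- limma::eBayes(limma::lmFit(sig, design))
  expect_gt(cor(-log10(de$p_value), -log10(fit$p.value[, 2])), 0.99)
  expect_equal(attr(de, "prior")$d0, fit$df.prior, tolerance = 0.2)
  expect_equal(attr(de, "prior")$s02, fit$s2.prior, tolerance = 0.1)
})

test_that("family/cluster grouping highlights co-directional groups only", {
  fam <- setNames(c("f1", "f1", "f1", "f2", "f2", "f3"),
                  c("a", "b", "c", "d", "e", "mmu-miR-9*"))
  clu <- setNames(paste0("c", 1:6), names(fam))
  mk_de <- function(mirna, logFC, p, platform, groups = c("G1", "G2")) {
    out <- data.frame(mirna = mirna, conc_g1 = 1, conc_g2 = 1,
                      logFC = logFC, p_value = p, bh_q = p,
                      significant = p < 0.05,
                      direction = ifelse(logFC >= 0, groups[2], groups[1]),
                      platform = platform, stringsAsFactors = FALSE)
    attr(out, "groups") <- groups
    class(out) <- c("de_table", "data.frame")
    out
  }
  de_seq <- mk_de(c("a", "b", "c", "d", "mmu-miR-9*"),
                  c(2, 2, -1, 1.5, 3),
                  c(0.01, 0.02, 0.01, 0.001, 0.002), "seq")
  de_arr <- mk_de(c("a", "e"), c(2, -2), c(0.03, 0.01), "array")
  rep <- group_de_by_family_cluster(de_seq, de_arr, fam, clu)
  # f1: a and b share direction -> highlighted; c opposes -> not
  expect_true(all(rep$family_highlighted[rep$mirna %in% c("a", "b")]))
  expect_false(rep$family_highlighted[rep$mirna == "c"])
  # f2: d and e in opposite directions -> no highlight
  expect_false(any(rep$family_highlighted[rep$mirna %in% c("d", "e")]))
  # platform tags
  expect_equal(rep$detected_by[rep$mirna == "a"], "MA; MS")
  expect_equal(rep$detected_by[rep$mirna == "b"], "MS")
  expect_equal(rep$detected_by[rep$mirna == "e"], "MA")
  expect_true(rep$is_star[rep$mirna == "mmu-miR-9*"])
  # empty input
  expect_equal(nrow(group_de_by_family_cluster(NULL, NULL, fam, clu)), 0)
})
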