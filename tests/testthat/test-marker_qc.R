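test_that("exact HWE test matches hand enumeration and flags monomorphs", {
  # 2 A and 2 a alleles: h in {0, 2} with P(0) = 1/3, P(2) = 2/3
  expect_equal(hwe_exact_test(1, 0, 1, "deficit")$p_value, 1 / 3)
  expect_equal(hwe_exact_test(0, 2, 0, "excess")$p_value, 2 / 3)
  mono <- hwe_exact_test(5, 0, 0, "deficit")
  expect_false(mono$testable)
  expect_true(is.na(mono$p_value))
})

test_that("exact HWE test equals independent enumeration for all n <= 16", {
  for (n in 1:16) {
    for (n_AA in 0:n) for (n_Aa in 0:(n - n_AA)) {
      n_aa <- n - n_AA - n_Aa
      nA <- 2 * n_AA + n_Aa
      if (nA == 0 || nA == 2 * n) next
      expect_equal(hwe_exact_test(n_AA, n_Aa, n_aa, "deficit")$p_value,
                   hwe_oracle_p(n_AA, n_Aa, n_aa, "deficit"),
                   tolerance = 1e-12)
      expect_equal(hwe_exact_test(n_AA, n_Aa, n_aa, "excess")$p_value,
                   hwe_oracle_p(n_AA, n_Aa, n_aa, "excess"),
                   tolerance = 1e-12)
    }
  }
})

test_that("HWE p-value pair obeys the exact-test identities", {
  set.seed(42)
  for (rep in 1:50) {
    cnt <- as.vector(stats::rmultinom(1, sample(2:16, 1), prob = runif(3)))
    if (2 * cnt[1] + cnt[2] == 0 || 2 * cnt[3] + cnt[2] == 0) next
    d <- hwe_exact_test(cnt[1], cnt[2], cnt[3], "deficit")$p_value
    e <- hwe_exact_test(cnt[1], cnt[2], cnt[3], "excess")$p_value
    expect_gte(d + e, 1)              # both tails include P(observed)
    dist <- hzclines:::hwe_het_distribution(2 * cnt[1] + cnt[2],
                                            2 * cnt[3] + cnt[2])
    expect_equal(sum(dist$p), 1)
    p_obs <- dist$p[dist$h == cnt[2]]
    expect_gte(d, p_obs); expect_gte(e, p_obs)
  }
})

test_that("corrected alpha is the per-test Bonferroni threshold", {
  expect_equal(corrected_alpha(0.05, 32), 0.0015625)
  expect_equal(corrected_alpha(0.05, 1), 0.05)
  expect_equal(corrected_alpha(0.01, 4), 0.0025)
  expect_error(corrected_alpha(1.5, 2), "alpha")
})

test_that("screen_hwe excludes a constructed repeat-deficit marker and
           keeps HWE-simulated markers", {
  set.seed(7)
  L <- 8L; n <- 16L; n_pop <- 6L
  g <- matrix(rbinom(n_pop * n * L, 2L, 0.5), n_pop * n, L,
              dimnames = list(sprintf("i%03d", 1:(n_pop * n)),
                              sprintf("m%02d", 1:L)))
  # marker m01: recode all heterozygotes to homozygotes in 4 populations ->
  # guaranteed extreme deficit there
  loc <- rep(sprintf("P%d", 1:n_pop), each = n)
  forced <- loc %in% sprintf("P%d", 1:4)
  g[forced & g[, 1] == 1L, 1] <- sample(c(0L, 2L), sum(forced & g[, 1] == 1L),
                                        replace = TRUE)
  panel <- genotype_panel(g, loc)
  dec <- screen_hwe(panel, alpha = 0.05, n_tests = 32L, min_sig_pops = 2L)
  expect_true(dec$excluded[dec$marker_id == "m01"])
  expect_gte(dec$n_significant_populations[dec$marker_id == "m01"], 4L)
  # type-I control: the honest markers survive the corrected threshold
  expect_false(any(dec$excluded[dec$marker_id != "m01"]))

  empty <- subset_panel(panel, integer(0))
  expect_equal(nrow(screen_hwe(empty)), L)
  expect_false(any(screen_hwe(empty)$excluded))
})

test_that("LD permutation test: maximal association at the floor,
           independence calibrated, seeded reproducibility", {
  set.seed(3)
  n <- 120L
  g <- cbind(m1 = rbinom(n, 2L, 0.5), m2 = rbinom(n, 2L, 0.5))
  g <- cbind(g, m3 = g[, "m1"])  # exact copy of m1
  rownames(g) <- sprintf("i%03d", 1:n)
  panel <- genotype_panel(g, rep(c("A", "B"), each = n / 2))

  dup <- ld_test(panel, "m1", "m3", n_permutations = 99L, seed = 5L)
  expect_equal(dup$p_value, 1 / 100)     # (0 + 1)/(99 + 1)

  indep <- ld_test(panel, "m1", "m2", n_permutations = 199L, seed = 5L)
  expect_gt(indep$p_value, 0.01)
  expect_identical(indep,
                   ld_test(panel, "m1", "m2", n_permutations = 199L, seed = 5L))

  # null calibration: independent markers give roughly uniform p
  ps <- vapply(1:15, function(i) {
    gg <- cbind(a = rbinom(60, 2L, 0.5), b = rbinom(60, 2L, 0.5))
    rownames(gg) <- sprintf("x%02d", 1:60)
    ld_test(genotype_panel(gg, rep("L", 60)), "a", "b",
            n_permutations = 99L, seed = i)$p_value
  }, numeric(1))
  expect_gt(mean(ps), 0.25)
  expect_lt(mean(ps), 0.85)

  mono <- cbind(m1 = rep(0L, 10), m2 = rbinom(10, 2L, 0.5))
  rownames(mono) <- sprintf("z%02d", 1:10)
  expect_false(ld_test(genotype_panel(mono, rep("L", 10)), "m1", "m2",
                       n_permutations = 99L, seed = 1L)$testable)
})

test_that("diagnosticity screen keeps exactly the fixed markers", {
  set.seed(21)
  n <- 10L
  fixed <- matrix(rep(c(0L, 2L), each = n, times = 10L), 2L * n, 10L)
  shared <- matrix(rbinom(2L * n * 3L, 2L, 0.5), 2L * n, 3L)
  g <- cbind(fixed, shared)
  dimnames(g) <- list(sprintf("i%02d", 1:(2L * n)), sprintf("m%02d", 1:13))
  panel <- genotype_panel(g, rep(c("N", "O"), each = n))
  ref <- c(N = "nesterovi", O = "ophryticus")
  expect_setequal(diagnosticity_screen(panel, ref), sprintf("m%02d", 1:10))

  # one reference heterozygote disqualifies a marker
  g2 <- g; g2[1L, 1L] <- 1L
  panel2 <- genotype_panel(g2, rep(c("N", "O"), each = n))
  expect_false("m01" %in% diagnosticity_screen(panel2, ref))
  expect_error(diagnosticity_screen(panel, c(N = "nesterovi")),
               "both species")
})
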