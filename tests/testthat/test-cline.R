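test_that("cline prediction matches closed forms", {
  m <- cline_model(center = 0, width = 2)
  expect_equal(cline_predict(m, 0), 0.5)
  expect_equal(cline_predict(m, 1), (1 + tanh(1)) / 2, tolerance = 1e-9)
  expect_equal(cline_predict(m, 1), 0.88080, tolerance = 1e-5)
  expect_equal(cline_predict(m, -1e4), 0, tolerance = 1e-12)
  expect_equal(cline_predict(m, 1e4), 1, tolerance = 1e-12)
  ms <- cline_model(0, 2, pmin = 0.1, pmax = 0.8)
  expect_equal(cline_predict(ms, -1e4), 0.1, tolerance = 1e-9)
  expect_equal(cline_predict(ms, 1e4), 0.8, tolerance = 1e-9)
})

test_that("tails join the sigmoid continuously with the stated slope ratio", {
  m <- cline_model(0, 3, tails = "both", delta_l = 2, tau_l = 0.4,
                   delta_r = 1, tau_r = 0.7)
  sig <- function(x) 1 / (1 + exp(-4 * x / 3))
  # continuity at both junctions
  expect_equal(cline_predict(m, -2 - 1e-9), cline_predict(m, -2 + 1e-9),
               tolerance = 1e-6)
  expect_equal(cline_predict(m, 1 - 1e-9), cline_predict(m, 1 + 1e-9),
               tolerance = 1e-6)
  # tail slope = tau x sigmoid slope at the junction
  num_slope <- function(x) (cline_predict(m, x + 1e-6) -
                              cline_predict(m, x - 1e-6)) / 2e-6
  sig_slope <- function(x) (4 / 3) * sig(x) * (1 - sig(x))
  expect_equal(num_slope(-2 - 1e-3), 0.4 * sig_slope(-2), tolerance = 1e-2)
  expect_equal(num_slope(1 + 1e-3), 0.7 * sig_slope(1), tolerance = 1e-2)
})

test_that("cline prediction is monotone non-decreasing for random valid
           models, tails included", {
  set.seed(8)
  xs <- seq(-30, 30, length.out = 400)
  for (i in 1:40) {
    tails <- sample(c("none", "left", "right", "mirror", "both"), 1)
    pmin <- runif(1, 0, 0.4); pmax <- runif(1, 0.6, 1)
    m <- cline_model(runif(1, -5, 5), runif(1, 0.5, 15), pmin, pmax, tails,
                     delta_l = runif(1, 0, 10), tau_l = runif(1),
                     delta_r = runif(1, 0, 10), tau_r = runif(1))
    p <- cline_predict(m, xs)
    expect_gte(min(diff(p)), -1e-12)
    expect_true(all(p >= pmin - 1e-9 & p <= pmax + 1e-9))
  }
})

test_that("binomial log-likelihood matches direct evaluation", {
  m <- cline_model(0, 2)
  # single site, p = 0.5, k = 1 of n = 2: log C(2,1) 0.5^2 = log 0.5
  expect_equal(cline_loglik(m, 0, 1, 2), log(0.5), tolerance = 1e-12)
  # brute-force dbinom oracle over a (c, w) grid
  set.seed(5)
  x <- seq(-10, 10, length.out = 12)
  n <- rep(20L, 12)
  k <- rbinom(12, n, cline_predict(cline_model(1, 4), x))
  for (cc in seq(-5, 5, length.out = 7)) for (ww in seq(0.5, 12, length.out = 7)) {
    mm <- cline_model(cc, ww)
    p <- pmin(pmax(cline_predict(mm, x), 1e-6), 1 - 1e-6)
    expect_equal(cline_loglik(mm, x, k, n),
                 sum(dbinom(k, n, p, log = TRUE)), tolerance = 1e-12)
  }
  # a saturating step model drives the step-data log-likelihood toward 0
  step_k <- c(rep(0L, 6), rep(20L, 6))
  expect_gt(cline_loglik(cline_model(0, 0.01), x, step_k, n), -0.01)
})

test_that("AICc matches its closed form and fails when undefined", {
  expect_equal(aicc(0, 2, 10), 4 + 12 / 7, tolerance = 1e-12)
  expect_equal(aicc(-10, 4, 20), 28 + 40 / 15, tolerance = 1e-12)
  expect_error(aicc(0, 9, 10), "AICc undefined")
  expect_lt(aicc(-1, 2, 10), aicc(-2, 2, 10))  # higher logL, lower AICc
})

test_that("ML fit is seeded-deterministic, respects the sampling-gap bound,
           and is symmetric under dosage flip", {
  x <- seq(-20, 20, by = 4)
  n <- rep(28L, length(x))
  k <- round(n * cline_predict(cline_model(0.5, 3), x))
  f1 <- fit_cline(x, k, n, seed = 4, mcmc = FALSE)
  f2 <- fit_cline(x, k, n, seed = 4, mcmc = FALSE)
  expect_identical(f1$theta, f2$theta)
  # step data: width is bounded by the 4 km sampling gap
  ks <- ifelse(x < 0, 0L, as.integer(n))
  fs <- fit_cline(x, ks, n, seed = 4, mcmc = FALSE)
  expect_lt(fs$model$width, 4)
  # flip k -> n - k, x -> -x: center negates, width invariant
  ff <- fit_cline(-x, n - k, n, seed = 4, mcmc = FALSE)
  expect_equal(ff$model$center, -f1$model$center, tolerance = 0.05)
  expect_equal(ff$model$width, f1$model$width, tolerance = 0.05)
  expect_error(fit_cline(x, rep(0L, length(x)), n, seed = 1),
               "monomorphic")
})

test_that("model_select fits all 15 variants, ranks by AICc and prefers
           parsimony near ties", {
  x <- seq(-15, 15, by = 3)
  n <- rep(30L, length(x))
  set.seed(77)
  k <- rbinom(length(x), n, cline_predict(cline_model(0, 4), x))
  ms <- model_select(x, k, n, seed = 9, mcmc = "none")
  expect_equal(nrow(ms$table), 15L)
  expect_equal(min(ms$table$dAICc, na.rm = TRUE), 0)
  expect_false(any(ms$table$failed))
  expect_s3_class(ms$best, "cline_fit")
  near <- ms$table[ms$table$dAICc < 2 & !ms$table$failed, ]
  expect_equal(ms$table$K[ms$table$best], min(near$K))
})

test_that("tail-free data select a no-tail variant most of the time", {
  # scaled-down replicate count to keep the default run fast
  x <- seq(-15, 15, by = 3)
  n <- rep(40L, length(x))
  wins <- 0L
  for (r in 1:8) {
    set.seed(100 + r)
    k <- rbinom(length(x), n, cline_predict(cline_model(0, 4), x))
    ms <- model_select(x, k, n, seed = 200 + r, mcmc = "none")
    if (ms$table$tails[ms$table$best] == "none") wins <- wins + 1L
  }
  expect_gte(wins, 7L)
})

test_that("strongly tailed data beat the no-tail variant by AICc", {
  # tails at delta = w/2 so they carry detectable frequency mass
  x <- seq(-30, 30, by = 2)
  n <- rep(300L, length(x))
  truth <- cline_model(0, 4, tails = "mirror", delta_l = 2, tau_l = 0.5)
  votes <- 0L
  for (r in 1:5) {
    set.seed(300 + r)
    k <- rbinom(length(x), n, cline_predict(truth, x))
    ms <- model_select(x, k, n, seed = 400 + r, mcmc = "none")
    tab <- ms$table
    best_tailed <- min(tab$AICc[tab$tails != "none"], na.rm = TRUE)
    best_plain <- min(tab$AICc[tab$tails == "none"], na.rm = TRUE)
    if (best_plain - best_tailed > 2) votes <- votes + 1L
  }
  expect_gte(votes, 3L)
})

test_that("MCMC support limits contain the ML point and flag convergence", {
  x <- seq(-12, 12, by = 3)
  n <- rep(30L, length(x))
  set.seed(6)
  k <- rbinom(length(x), n, cline_predict(cline_model(0, 4), x))
  f <- fit_cline(x, k, n, seed = 11, mcmc = TRUE, chains = 2L, steps = 8000L)
  expect_true(all(f$support$lower <= f$support$mle + 1e-9))
  expect_true(all(f$support$upper >= f$support$mle - 1e-9))
  expect_true(f$converged)
  expect_true(all(f$mcmc$acceptance > 0.05 & f$mcmc$acceptance < 0.8))
})

test_that("concordance report flags displaced markers only", {
  x <- seq(-12, 12, by = 3)
  n <- rep(40L, length(x))
  set.seed(13)
  k <- rbinom(length(x), n, cline_predict(cline_model(0, 4), x))
  ref <- fit_cline(x, k, n, seed = 21, chains = 2L, steps = 6000L)
  same <- fit_cline(x, k, n, seed = 22, chains = 2L, steps = 6000L)
  k_disp <- rbinom(length(x), n, cline_predict(cline_model(12, 4), x))
  disp <- fit_cline(x, k_disp, n, seed = 23, chains = 2L, steps = 6000L)
  rep <- concordance_report(list(same = same, displaced = disp), ref)
  expect_true(rep$center_overlap[rep$fit == "same"])
  expect_true(rep$width_overlap[rep$fit == "same"])
  expect_false(rep$center_overlap[rep$fit == "displaced"])
})
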