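test_that("D-prime inversion from hybrid-index variance is exact", {
  L <- 31
  # independent loci: Var(HI) = pq/(2L) -> D' = 0
  hi0 <- c(0.4, 0.6)  # p_bar = 0.5, var chosen via p_bar argument
  v0 <- 0.5 * 0.5 / (2 * L)
  hi <- c(0.5 - sqrt(v0 / 2), 0.5 + sqrt(v0 / 2))  # sample var = v0
  expect_equal(suppressWarnings(dprime_from_hi_variance(hi, L, p_bar = 0.5)),
               0, tolerance = 1e-9)  # float noise may dip a hair below 0
  # maximal between-locus association: Var(HI) = pq/2 -> D' = 1
  hi1 <- c(0.25, 0.75)  # sample variance = 0.125 = pq/2 at p_bar = 0.5
  expect_equal(dprime_from_hi_variance(hi1, L, p_bar = 0.5), 1,
               tolerance = 1e-9)
  # the algebraic case consistent with a 0.62 km/gen dispersal estimate
  hi2 <- c(0.5 - sqrt(0.01222 / 2), 0.5 + sqrt(0.01222 / 2))
  expect_equal(dprime_from_hi_variance(hi2, L, p_bar = 0.5), 0.0677,
               tolerance = 1e-3)
  expect_error(dprime_from_hi_variance(c(0, 0), L), "no polymorphism")
  expect_warning(d <- dprime_from_hi_variance(c(0.5, 0.5), L, p_bar = 0.5),
                 "floored")
  expect_equal(d, 0)
})

test_that("variance-based and pairwise-covariance D-prime agree on
           simulated center samples", {
  set.seed(19)
  L <- 31L; n <- 200L
  d_true <- 0.15
  v <- d_true * 0.25 * (L - 1) / (2 * L - 1)
  kk <- 0.25 / v - 1
  q <- rbeta(n, 0.5 * kk, 0.5 * kk)
  g <- matrix(rbinom(n * L, 2L, rep(q, each = L)), n, L, byrow = TRUE,
              dimnames = list(sprintf("i%03d", 1:n), sprintf("m%02d", 1:L)))
  hi <- rowSums(g) / (2 * L)
  d_var <- dprime_from_hi_variance(hi, L)
  d_pair <- hzclines:::dprime_pairwise(g)
  expect_equal(d_var, d_pair, tolerance = 0.1)
})

test_that("dispersal, neutral width, selection and crossing time match
           their closed forms", {
  expect_equal(sigma_from_ld(0.0677, 0.5, 3.37), 0.620, tolerance = 1e-3)
  expect_equal(sigma_from_ld(1, 0.5, 1), sqrt(0.5), tolerance = 1e-12)
  # round trip sigma -> D' -> sigma
  s <- sigma_from_ld(0.2, 0.5, 5)
  expect_equal(sigma_from_ld(s^2 / (0.5 * 25), 0.5, 5), s, tolerance = 1e-12)

  expect_equal(neutral_width(1, 1), sqrt(2 * pi), tolerance = 1e-12)
  expect_equal(neutral_width(0.62, 2400), 75.81, tolerance = 0.01)
  expect_equal(neutral_width(0.45, 2400), 55.01, tolerance = 0.01)
  expect_equal(neutral_width(0.83, 2400), 102.04, tolerance = 0.01)

  expect_equal(as.numeric(effective_selection(1, sqrt(8))), 1,
               tolerance = 1e-12)
  expect_equal(as.numeric(effective_selection(0.62, 3.37)), 0.271,
               tolerance = 1e-3)
  # the mean-marker-width convention reproduces the printed s* scale
  expect_equal(as.numeric(effective_selection(0.62, 4.69,
                                              "mean_marker_width")),
               0.140, tolerance = 1e-2)

  expect_lt(generations_to_cross(3.37, 0.62), 6)
  expect_equal(generations_to_cross(3.37, 0.62), 3.37 / 0.62)
  expect_equal(generations_to_cross(1, 1), 1)
  expect_equal(generations_to_cross(33.7, 6.2),
               generations_to_cross(3.37, 0.62))
})

test_that("neutral width scales linearly in sigma and as sqrt(T)", {
  sig <- seq(0.1, 2, length.out = 10)
  w1 <- vapply(sig, neutral_width, numeric(1), T_gen = 500)
  expect_equal(w1 / sig, rep(w1[1] / sig[1], 10), tolerance = 1e-12)
  Ts <- c(100, 400, 1600)
  ws <- vapply(Ts, function(tt) neutral_width(0.5, tt), numeric(1))
  expect_equal(ws[2] / ws[1], 2, tolerance = 1e-12)
  expect_equal(ws[3] / ws[2], 2, tolerance = 1e-12)
})

test_that("dispersal pipeline enforces the life-stage policy and chains the
           estimators", {
  cfg <- zone_sim_config(localities = data.frame(
    code = sprintf("S%02d", 1:9), distance_km = seq(-12, 12, by = 3)),
    n_per_locality = 40L, d_prime = 0.1, width = 4,
    post_metamorphic_fraction = 1, seed = 31L)
  sim <- simulate_zone(cfg)
  tr <- data.frame(code = cfg$localities$code,
                   distance_km = cfg$localities$distance_km)
  fit <- fit_cline(tr$distance_km,
                   round(sim$localities$hybrid_index * 2 * sim$localities$n_kasp),
                   2L * sim$localities$n_kasp, seed = 5, mcmc = FALSE)
  est <- dispersal_pipeline(sim$panel, tr, fit)
  expect_gt(est$sigma, 0)
  expect_equal(est$w_neutral, neutral_width(est$sigma, 2400))
  expect_equal(est$s_star_hybrid_index,
               8 * est$sigma^2 / fit$model$width^2, tolerance = 1e-12)
  expect_equal(est$inputs$T_gen, 2400)   # 12 ka / 5-year generations

  # all pre-metamorphic individuals -> no dispersal information
  pre <- sim$panel
  pre$life_stage[] <- "pre_metamorphic"
  expect_error(dispersal_pipeline(pre, tr, fit), "dispersal-informative")
  expect_error(dispersal_pipeline(sim$panel,
                                  transform(tr, distance_km = distance_km + 500),
                                  fit),
               "no center localities")
})

test_that("stronger zone-center LD increases the dispersal estimate
           monotonically", {
  sig_hat <- vapply(seq_along(lv <- c(0.02, 0.08, 0.2, 0.4, 0.6)), function(i) {
    cfg <- zone_sim_config(localities = data.frame(
      code = c("W", "C", "E"), distance_km = c(-8, 0, 8)),
      n_per_locality = c(30L, 300L, 30L), width = 4, d_prime = lv[i],
      post_metamorphic_fraction = 1, seed = 600L + i)
    sim <- simulate_zone(cfg)
    hi <- individual_hybrid_index(subset_panel(sim$panel,
      which(sim$panel$locality_code == "C")))$hybrid_index
    sigma_from_ld(max(dprime_from_hi_variance(hi, 31L), 1e-6), 0.5, 4)
  }, numeric(1))
  expect_true(all(diff(sig_hat) > 0))
})
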