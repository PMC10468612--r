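# Small helper: a niche_grid built directly from a z vector, for exact
# hand computations of Schoener's D.
manual_grid <- function(z, x = seq_len(nrow(z)), y = seq_len(ncol(z))) {
  structure(list(x = x, y = y, z = z / sum(z)), class = "niche_grid")
}

test_that("variable selection drops exactly the inter-correlated layers", {
  set.seed(2)
  base <- matrix(rnorm(400), 20, 20)
  st <- raster_stack(list(v1 = base,
                          v2 = base + matrix(rnorm(400, sd = 0.1), 20, 20),
                          v3 = matrix(rnorm(400), 20, 20)),
                    0, 1, 0, 1)
  kept <- select_variables(st, 0.7)
  expect_length(kept, 2L)
  expect_true("v3" %in% kept)
  expect_length(intersect(kept, c("v1", "v2")), 1L)
  # identical layers: one survives
  st2 <- raster_stack(list(a = base, b = base), 0, 1, 0, 1)
  expect_length(select_variables(st2, 0.7), 1L)
  # no pair above threshold: everything survives
  st3 <- raster_stack(list(a = matrix(rnorm(400), 20),
                           b = matrix(rnorm(400), 20)), 0, 1, 0, 1)
  expect_length(select_variables(st3, 0.99), 2L)
})

test_that("background PCA has the stated geometry", {
  set.seed(4)
  b <- matrix(rnorm(600), 30, 20)
  st <- raster_stack(list(v1 = b, v2 = 2 * b + 5), 0, 1, 0, 1)
  p <- pca_env(st)
  expect_equal(p$var_explained[1], 1)          # perfectly correlated pair
  # centering: the background centroid projects to the origin
  expect_equal(colMeans(p$scores), c(PC1 = 0, PC2 = 0), tolerance = 1e-12)
  # isotropic cloud splits variance evenly
  st2 <- raster_stack(list(v1 = matrix(rnorm(10000), 100),
                           v2 = matrix(rnorm(10000), 100)), 0, 1, 0, 1)
  p2 <- pca_env(st2)
  expect_equal(p2$var_explained[1], 0.5, tolerance = 0.05)
  stc <- raster_stack(list(v1 = b, v2 = matrix(1, 30, 20)), 0, 1, 0, 1)
  expect_error(pca_env(stc), "constant variable.*v2")
})

test_that("schoeners_d matches hand computations exactly", {
  z1 <- manual_grid(matrix(c(0.5, 0.5, 0), 3, 1))
  z2 <- manual_grid(matrix(c(0, 0.5, 0.5), 3, 1))
  expect_equal(schoeners_d(z1, z1), 1)
  expect_equal(schoeners_d(z1, z2), 0.5)
  z3 <- manual_grid(matrix(c(1, 0, 0), 3, 1))
  z4 <- manual_grid(matrix(c(0, 0, 1), 3, 1))
  expect_equal(schoeners_d(z3, z4), 0)
  # symmetric and invariant under a common relabeling of cells
  set.seed(6)
  a <- manual_grid(matrix(runif(9), 3, 3))
  b <- manual_grid(matrix(runif(9), 3, 3))
  expect_identical(schoeners_d(a, b), schoeners_d(b, a))
  perm <- sample(9)
  ap <- manual_grid(matrix(a$z[perm], 3, 3))
  bp <- manual_grid(matrix(b$z[perm], 3, 3))
  expect_equal(schoeners_d(ap, bp), schoeners_d(a, b), tolerance = 1e-12)
  z5 <- manual_grid(matrix(1, 4, 4), x = 1:4 + 0.5)
  expect_error(schoeners_d(a, z5), "misaligned")
})

test_that("occupancy grids are normalized, peaked where occurrences are,
           and resolution-robust", {
  set.seed(8)
  bkg <- cbind(rnorm(3000), rnorm(3000))
  occ1 <- cbind(rnorm(60, -0.5, 0.4), rnorm(60, 0, 0.4))
  g1 <- occupancy_grid(occ1, bkg, R = 100)
  expect_equal(sum(g1$z), 1, tolerance = 1e-9)
  # a point mass peaks at its own cell
  pt <- cbind(rep(0.7, 6), rep(-0.3, 6))
  gp <- occupancy_grid(pt, bkg, R = 60)
  peak <- which(gp$z == max(gp$z), arr.ind = TRUE)
  expect_lt(abs(gp$x[peak[1]] - 0.7), 0.15)
  expect_lt(abs(gp$y[peak[2]] - (-0.3)), 0.15)
  # identical occurrences give identical grids
  g1b <- occupancy_grid(occ1, bkg, R = 100)
  expect_identical(g1$z, g1b$z)
  # doubling R leaves D between two fixed species stable
  occ2 <- cbind(rnorm(60, 0.5, 0.4), rnorm(60, 0, 0.4))
  d100 <- schoeners_d(occupancy_grid(occ1, bkg, R = 100),
                      occupancy_grid(occ2, bkg, R = 100))
  d200 <- schoeners_d(occupancy_grid(occ1, bkg, R = 200),
                      occupancy_grid(occ2, bkg, R = 200))
  expect_equal(d100, d200, tolerance = 0.02 / max(d100, 0.1))
  expect_error(occupancy_grid(occ1[1:3, ], bkg), "at least 5")
})

test_that("similarity test: identical species sit at the p floor and the
           result is seed-reproducible", {
  set.seed(12)
  bkg <- cbind(runif(2000, -3, 3), runif(2000, -3, 3))
  occ <- cbind(rnorm(50, 0, 0.3), rnorm(50, 0, 0.3))
  ga <- occupancy_grid(occ, bkg, R = 60)
  st1 <- similarity_test(ga, occ, bkg, n_reps = 99, seed = 7, R = 60)
  expect_equal(st1$D, 1)
  expect_lte(st1$p_value, 0.02)          # at/near the 1/(n+1) floor
  st2 <- similarity_test(ga, occ, bkg, n_reps = 99, seed = 7, R = 60)
  expect_identical(st1$p_value, st2$p_value)
  expect_identical(st1$null_D, st2$null_D)
  expect_true(st1$p_value > 0 && st1$p_value <= 1)
})

test_that("shared-suitability projection classifies the constructed
           landscape correctly", {
  sim <- simulate_climate_landscape(n_variables = 3, seed = 5,
                                    n_occurrences = 80)
  st <- sim$stack
  p <- pca_env(st)
  occ <- sim$occurrences
  pa <- project_env(p, st, occ$latitude[occ$species == "a"],
                    occ$longitude[occ$species == "a"])
  pb <- project_env(p, st, occ$latitude[occ$species == "b"],
                    occ$longitude[occ$species == "b"])
  ga <- occupancy_grid(pa, p$scores, R = 60)
  gb <- occupancy_grid(pb, p$scores, R = 60)
  proj_same <- project_shared_suitability(p, ga, ga, st)
  expect_true(all(proj_same$layers$category %in% c(0, 3)))  # both or neither
  # disjoint niches: no cell suits both
  d1 <- manual_grid(rbind(diag(0, 2), c(0, 0)) + cbind(c(1, 1, 1), 0),
                    x = c(-2, 0, 2), y = c(-2, 2))
  d2 <- manual_grid(cbind(0, c(1, 1, 1)), x = c(-2, 0, 2), y = c(-2, 2))
  pd <- project_shared_suitability(p, d1, d2, st)
  expect_false(any(pd$layers$category == 3, na.rm = TRUE))
})
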