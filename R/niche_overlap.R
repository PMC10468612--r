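#' Drop inter-correlated environmental variables
#'
#' Greedy elimination over background cells: while any pair of retained
#' layers has `|Pearson r| >=` the threshold, the member of the worst pair
#' with the larger mean absolute correlation to all other retained layers
#' is dropped (ties: the later layer in stack order). Deterministic.
#'
#' @param stack a [raster_stack()].
#' @param r_threshold correlation threshold (default 0.7).
#' @return character vector of retained layer names.
#' @export
select_variables <- function(stack, r_threshold = 0.7) {
  vals <- sapply(stack$layers, as.vector)
  vals <- vals[complete.cases(vals), , drop = FALSE]
  if (nrow(vals) == 0L) stop("no valid (unmasked) cells shared by all layers")
  keep <- colnames(vals)
  repeat {
    if (length(keep) < 2L) break
    cm <- abs(cor(vals[, keep, drop = FALSE]))
    diag(cm) <- 0
    if (max(cm) < r_threshold) break
    worst <- which(cm == max(cm), arr.ind = TRUE)[1L, ]
    pair <- keep[worst]
    mean_r <- colMeans(cm)[pair]
    drop <- pair[which.max(mean_r + c(0, 1e-12))]  # tie -> later in order
    keep <- setdiff(keep, drop)
  }
  keep
}

#' Principal component analysis of the environmental background (PCA-env)
#'
#' Ordination of the full background cloud (every valid cell of the study
#' extent x the selected variables, standardized to zero mean and unit
#' variance), within which species occurrence densities are later compared.
#'
#' @param stack a [raster_stack()].
#' @param variables layer subset (default all layers).
#' @return object of class `pca_env`: the `prcomp` fit, background scores
#'   (`scores`, first two axes), `var_explained`, background cell
#'   coordinates, and the variable list.
#' @export
pca_env <- function(stack, variables = NULL) {
  variables <- variables %||% names(stack$layers)
  vals <- sapply(stack$layers[variables], as.vector)
  nr <- nrow(stack$layers[[1L]])
  cell_lat <- rep(stack$lat, times = ncol(stack$layers[[1L]]))
  cell_lon <- rep(stack$lon, each = nr)
  ok <- complete.cases(vals)
  vals <- vals[ok, , drop = FALSE]
  if (nrow(vals) < 3L) stop("need at least 3 background cells")
  sds <- apply(vals, 2L, sd)
  if (any(sds == 0))
    stop("constant variable after masking: ", variables[which(sds == 0)[1L]])
  fit <- prcomp(vals, center = TRUE, scale. = TRUE)
  ve <- fit$sdev^2 / sum(fit$sdev^2)
  structure(list(fit = fit, scores = fit$x[, 1:2, drop = FALSE],
                 var_explained = ve, variables = variables,
                 cell_latitude = cell_lat[ok], cell_longitude = cell_lon[ok]),
            class = "pca_env")
}

#' Project points into the fitted environmental ordination
#'
#' @param pca a [pca_env()].
#' @param stack the same [raster_stack()] the PCA was calibrated on.
#' @param latitude,longitude point coordinates.
#' @return matrix of PC1/PC2 scores (rows with `NA` where points fall on
#'   masked or off-grid cells).
#' @export
project_env <- function(pca, stack, latitude, longitude) {
  env <- extract_cells(stack, latitude, longitude)[, pca$variables, drop = FALSE]
  predict(pca$fit, newdata = as.data.frame(env))[, 1:2, drop = FALSE]
}

# Gaussian product-kernel density of points evaluated on a grid.
kde_grid <- function(px, py, gx, gy, hx, hy) {
  kx <- dnorm(outer(gx, px, "-"), sd = hx)
  ky <- dnorm(outer(gy, py, "-"), sd = hy)
  (kx %*% t(ky)) / length(px)
}

silverman_bw <- function(v) {
  n <- length(v)
  bw <- 1.06 * sd(v) * n^(-1 / 5)
  if (!is.finite(bw) || bw <= 0) bw <- diff(range(v)) / 10 + 1e-8
  bw
}

#' Kernel occupancy grid of a species niche in ordination space
#'
#' Gaussian kernel density of the occurrence scores on an `R x R` grid
#' spanning the background's PC1-PC2 range, corrected for environmental
#' availability by dividing by the background kernel density (floored at
#' its 1st percentile so rare environments do not blow up), zeroed where
#' the background is absent, and renormalized to sum to one.
#'
#' @param occ_scores matrix of occurrence PC1/PC2 scores (>= 5 rows).
#' @param bkg_scores matrix of background PC1/PC2 scores.
#' @param R grid resolution per axis (default 100).
#' @param bandwidth length-2 kernel SDs; default Silverman's rule per axis
#'   on the occurrence scores.
#' @param species optional label.
#' @return object of class `niche_grid`: grid vectors `x`, `y`, occupancy
#'   `z` (sums to 1), `occ_density`, `bkg_density`, `mask`, `bandwidth`.
#' @export
occupancy_grid <- function(occ_scores, bkg_scores, R = 100L,
                           bandwidth = NULL, species = NULL) {
  occ_scores <- occ_scores[complete.cases(occ_scores), , drop = FALSE]
  if (nrow(occ_scores) < 5L) stop("need at least 5 occurrences")
  gx <- seq(min(bkg_scores[, 1L]), max(bkg_scores[, 1L]), length.out = R)
  gy <- seq(min(bkg_scores[, 2L]), max(bkg_scores[, 2L]), length.out = R)
  bandwidth <- bandwidth %||% c(silverman_bw(occ_scores[, 1L]),
                                silverman_bw(occ_scores[, 2L]))
  # degenerate occurrence clouds (zero spread) fall back to one grid cell
  bandwidth <- pmax(bandwidth, c(diff(range(gx)), diff(range(gy))) / R)
  occ_d <- kde_grid(occ_scores[, 1L], occ_scores[, 2L], gx, gy,
                    bandwidth[1L], bandwidth[2L])
  bkg_bw <- c(silverman_bw(bkg_scores[, 1L]), silverman_bw(bkg_scores[, 2L]))
  bkg_d <- kde_grid(bkg_scores[, 1L], bkg_scores[, 2L], gx, gy,
                    bkg_bw[1L], bkg_bw[2L])
  # background "present" = smallest cell set carrying 99% of its density
  # mass; outside it both densities are numerical tails and their ratio is
  # meaningless noise
  ord <- order(bkg_d, decreasing = TRUE)
  cum <- cumsum(bkg_d[ord]) / sum(bkg_d)
  mask <- bkg_d >= bkg_d[ord][which(cum >= 0.99)[1L]]
  floor_d <- quantile(bkg_d[mask], 0.01)
  occu <- ifelse(mask, occ_d / pmax(bkg_d, floor_d), 0)
  tot <- sum(occu)
  if (tot <= 0)
    stop("all occurrences outside background extent: empty occupancy")
  structure(list(x = gx, y = gy, z = occu / tot,
                 occ_density = occ_d, bkg_density = bkg_d, mask = mask,
                 bandwidth = bandwidth, species = species %||% ""),
            class = "niche_grid")
}

#' Schoener's D niche overlap statistic
#'
#' \eqn{D = 1 - \frac{1}{2} \sum_{cells} |z_1 - z_2|} between two occupancy
#' grids on identical grids; 1 = identical niches, 0 = disjoint.
#'
#' @param z1,z2 [occupancy_grid()] objects on the same grid.
#' @return D in `[0, 1]`.
#' @export
schoeners_d <- function(z1, z2) {
  stopifnot(inherits(z1, "niche_grid"), inherits(z2, "niche_grid"))
  if (!isTRUE(all.equal(z1$x, z2$x)) || !isTRUE(all.equal(z1$y, z2$y)))
    stop("misaligned grids: extents/resolutions differ")
  1 - 0.5 * sum(abs(z1$z - z2$z))
}

#' Niche similarity permutation test
#'
#' Tests whether the observed overlap between a fixed species' niche and a
#' second species is larger (more similar) than expected if the second
#' species occupied its available environment at random: the second
#' species' occurrence scores are randomly translated (with wraparound)
#' within its background's PC1-PC2 extent, the occupancy grid is rebuilt,
#' and Schoener's D recomputed. `p = (#{D_null >= D_obs} + 1)/(n_reps + 1)`
#' for `direction = "more_similar"` (reversed for `"more_dissimilar"`).
#'
#' @param grid_fixed [occupancy_grid()] of the fixed species.
#' @param occ_scores,bkg_scores scores of the species being randomized.
#' @param n_reps permutation count (>= 99; default 100).
#' @param seed RNG seed (required).
#' @param direction `"more_similar"` or `"more_dissimilar"`.
#' @param R grid resolution (must match `grid_fixed`).
#' @return list of class `overlap_result`: `D`, `p_value`, `n_reps`,
#'   `seed`, `direction`, `null_D`.
#' @export
similarity_test <- function(grid_fixed, occ_scores, bkg_scores,
                            n_reps = 100L, seed,
                            direction = c("more_similar", "more_dissimilar"),
                            R = length(grid_fixed$x)) {
  direction <- match.arg(direction)
  if (missing(seed)) stop("'seed' is required")
  if (n_reps < 99L) stop("need at least 99 repetitions")
  rngx <- range(bkg_scores[, 1L]); rngy <- range(bkg_scores[, 2L])
  if (diff(rngx) <= 0 || diff(rngy) <= 0)
    stop("background too small for relocation")
  obs_grid <- occupancy_grid(occ_scores, bkg_scores, R = R)
  d_obs <- schoeners_d(grid_fixed, obs_grid)
  wrap <- function(v, rng, shift) {
    rng[1L] + (v - rng[1L] + shift) %% diff(rng)
  }
  null_d <- with_seed(seed, vapply(seq_len(n_reps), function(i) {
    sx <- runif(1L, 0, diff(rngx)); sy <- runif(1L, 0, diff(rngy))
    shifted <- cbind(wrap(occ_scores[, 1L], rngx, sx),
                     wrap(occ_scores[, 2L], rngy, sy))
    g <- occupancy_grid(shifted, bkg_scores, R = R,
                        bandwidth = obs_grid$bandwidth)
    schoeners_d(grid_fixed, g)
  }, numeric(1L)))
  cnt <- if (direction == "more_similar") sum(null_d >= d_obs - 1e-12)
         else sum(null_d <= d_obs + 1e-12)
  structure(list(D = d_obs, p_value = (cnt + 1) / (n_reps + 1),
                 n_reps = n_reps, seed = seed, direction = direction,
                 null_D = null_d),
            class = "overlap_result")
}

#' Map shared climatic suitability back to geography
#'
#' Classifies every valid geographic cell by whether its environmental
#' position falls inside each species' occupied niche, where "occupied"
#' means occupancy above the density threshold that excludes the lowest
#' `mass_threshold` of each species' occupancy mass (default 5%).
#'
#' @param pca a [pca_env()].
#' @param grid_a,grid_b [occupancy_grid()] objects for the two species.
#' @param stack the calibration [raster_stack()].
#' @param mass_threshold excluded tail mass (default 0.05).
#' @return a [raster_stack()] with one layer `category` coded 0 = neither,
#'   1 = A only, 2 = B only, 3 = both; the coding is recorded in attribute
#'   `legend`.
#' @export
project_shared_suitability <- function(pca, grid_a, grid_b, stack,
                                       mass_threshold = 0.05) {
  occ_thr <- function(g) {
    zs <- sort(as.vector(g$z))
    cs <- cumsum(zs)
    i <- which(cs > mass_threshold)[1L]
    zs[max(i, 1L)]
  }
  ta <- occ_thr(grid_a); tb <- occ_thr(grid_b)
  template <- stack$layers[[1L]]
  nr <- nrow(template); nc <- ncol(template)
  lat <- rep(stack$lat, times = nc); lon <- rep(stack$lon, each = nr)
  sc <- project_env(pca, stack, lat, lon)
  cell_of <- function(v, gv) {
    i <- findInterval(v, gv, all.inside = TRUE)
    # nearest of the two bracketing grid points
    ifelse(abs(v - gv[i]) <= abs(v - gv[pmin(i + 1L, length(gv))]), i, i + 1L)
  }
  occupied <- function(g, thr) {
    ix <- cell_of(sc[, 1L], g$x); iy <- cell_of(sc[, 2L], g$y)
    out <- g$z[cbind(ix, iy)] >= thr
    out[is.na(sc[, 1L]) | sc[, 1L] < min(g$x) | sc[, 1L] > max(g$x) |
          sc[, 2L] < min(g$y) | sc[, 2L] > max(g$y)] <- FALSE
    out
  }
  in_a <- occupied(grid_a, ta); in_b <- occupied(grid_b, tb)
  cat_v <- ifelse(in_a & in_b, 3, ifelse(in_a, 1, ifelse(in_b, 2, 0)))
  cat_v[is.na(as.vector(template))] <- NA
  m <- matrix(cat_v, nr, nc)
  out <- raster_stack(list(category = m),
                      xmin = stack$extent["xmin"], xmax = stack$extent["xmax"],
                      ymin = stack$extent["ymin"], ymax = stack$extent["ymax"])
  attr(out, "legend") <- c("0" = "neither", "1" = "A only",
                           "2" = "B only", "3" = "both")
  out
}
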