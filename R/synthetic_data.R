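#' Configuration for a simulated hybrid zone
#'
#' States the world a simulated zone is drawn from. Defaults mirror the
#' banded newt survey: 31 diagnostic markers, 12 individuals per locality,
#' a 3.37 km wide nuclear cline centered on the contact, a much steeper
#' mtDNA cline (0.17 km), and zone-center admixture LD at the level implied
#' by a dispersal of ~0.6 km/generation.
#'
#' Each individual draws a latent ancestry proportion `q` from a Beta
#' distribution with mean `p(x)` (the true cline at its locality) and
#' variance tuned so the zone-center standardized LD equals `d_prime`;
#' genotypes are then conditionally independent `Binomial(2, q)` per locus.
#' `d_prime = 0` collapses to independent loci.
#'
#' @param L marker count.
#' @param localities data frame with `code` and either `distance_km` (1D
#'   transect positions) or `latitude`/`longitude`; default 21 localities
#'   every 5 km from -50 to 50.
#' @param n_per_locality individuals per locality (recycled).
#' @param center,width,pmin,pmax,tails true nuclear cline (see
#'   [cline_model()]).
#' @param d_prime target zone-center admixture LD in `[0, 1)`.
#' @param mtdna_center,mtdna_width true mtDNA cline.
#' @param n_mtdna_per_locality mtDNA sample size per locality (recycled).
#' @param post_metamorphic_fraction fraction of individuals assigned the
#'   post-metamorphic stage (default 0.8).
#' @param seed RNG seed (mandatory).
#' @return list of class `zone_sim_config`.
#' @export
zone_sim_config <- function(L = 31L,
                            localities = data.frame(
                              code = sprintf("S%02d", 1:21),
                              distance_km = seq(-50, 50, by = 5)),
                            n_per_locality = 12L,
                            center = 0, width = 3.37, pmin = 0, pmax = 1,
                            tails = "none",
                            d_prime = 0.068,
                            mtdna_center = 0, mtdna_width = 0.17,
                            n_mtdna_per_locality = 3L,
                            post_metamorphic_fraction = 0.8,
                            seed) {
  if (missing(seed)) stop("'seed' is mandatory")
  if (L < 1L || any(n_per_locality < 1L)) stop("counts must be >= 1")
  if (d_prime < 0 || d_prime >= 1) stop("d_prime must be in [0, 1)")
  structure(as.list(environment()), class = "zone_sim_config")
}

#' Simulate a hybrid-zone survey (genotypes, localities, mtDNA)
#'
#' See [zone_sim_config()] for the generative model. The Beta variance at a
#' locality with expected frequency p is
#' `v = d_prime * p(1-p) * (L-1) / (2L-1)`, the value that makes the
#' hybrid-index variance decomposition return `d_prime` exactly in
#' expectation; infeasible combinations (`v >= p(1-p)`) are an error.
#'
#' @param config a [zone_sim_config()].
#' @return list of class `zone_sim`: `panel` ([genotype_panel()]),
#'   `localities` ([locality_frame()] with realized hybrid indices),
#'   `mtdna` (per-locality haploid counts), `truth` (the generating
#'   parameters).
#' @export
simulate_zone <- function(config) {
  stopifnot(inherits(config, "zone_sim_config"))
  loc <- config$localities
  if (is.null(loc$distance_km)) {
    if (is.null(loc$latitude)) stop("localities need distance_km or lat/long")
    stop("geographic simulation requires precomputed distance_km; ",
         "run build_transect() on a seed map or supply distance_km")
  }
  nl <- nrow(loc)
  n_ind <- rep_len(config$n_per_locality, nl)
  n_mt <- rep_len(config$n_mtdna_per_locality, nl)
  true_cline <- cline_model(config$center, config$width, config$pmin,
                            config$pmax, config$tails)
  mt_cline <- cline_model(config$mtdna_center, config$mtdna_width)
  L <- config$L
  with_seed(config$seed, {
    p <- cline_predict(true_cline, loc$distance_km)
    panels <- vector("list", nl)
    mt_k <- integer(nl)
    for (i in seq_len(nl)) {
      v <- config$d_prime * p[i] * (1 - p[i]) * (L - 1) / (2 * L - 1)
      if (p[i] > 0 && p[i] < 1 && v >= p[i] * (1 - p[i]))
        stop("Beta parameterization infeasible: v >= p(1-p)")
      q <- if (v <= 0 || p[i] <= 0 || p[i] >= 1) rep(p[i], n_ind[i])
      else {
        kk <- p[i] * (1 - p[i]) / v - 1
        rbeta(n_ind[i], p[i] * kk, (1 - p[i]) * kk)
      }
      g <- matrix(rbinom(n_ind[i] * L, 2L, rep(q, each = L)),
                  nrow = n_ind[i], ncol = L, byrow = TRUE)
      rownames(g) <- sprintf("%s_i%03d", loc$code[i], seq_len(n_ind[i]))
      colnames(g) <- sprintf("m%03d", seq_len(L))
      panels[[i]] <- g
      mt_k[i] <- sum(runif(n_mt[i]) < cline_predict(mt_cline, loc$distance_km[i]))
    }
    g_all <- do.call(rbind, panels)
    stage <- ifelse(runif(nrow(g_all)) < config$post_metamorphic_fraction,
                    "post_metamorphic", "pre_metamorphic")
    panel <- genotype_panel(g_all,
                            locality_code = rep(loc$code, n_ind),
                            life_stage = stage)
    lhi <- locality_hybrid_index(panel)
    lf <- data.frame(code = loc$code,
                     latitude = loc$latitude %||% rep(41, nl),
                     longitude = loc$longitude %||%
                       (37.17 + loc$distance_km / (111.195 * cos(41 * pi / 180))),
                     species = ifelse(p < 0.1, "nesterovi",
                                      ifelse(p > 0.9, "ophryticus", "admixed")),
                     n_kasp = n_ind,
                     hybrid_index = lhi$hybrid_index[match(loc$code, lhi$locality_code)],
                     n_mtdna = n_mt,
                     mtdna_freq = mt_k / pmax(n_mt, 1L))
    structure(list(panel = panel, localities = locality_frame(lf),
                   mtdna = data.frame(code = loc$code, k = mt_k, n = n_mt),
                   truth = list(cline = true_cline, mtdna_cline = mt_cline,
                                d_prime = config$d_prime, L = L,
                                p = p, distance_km = loc$distance_km)),
              class = "zone_sim")
  })
}

#' Simulate a genetically admixed swarm from the triangle model
#'
#' Genotypes are drawn per locus from the ancestry/heterozygosity model
#' `P(2) = S - H/2`, `P(1) = H`, `P(0) = 1 - S - H/2` -- the generative
#' counterpart of [triangle_ml()]. Emulates an introduced hybrid-swarm
#' population where all hybrid classes mix freely.
#'
#' @param n individuals.
#' @param S,H ancestry and interclass heterozygosity (scalars or length-n
#'   vectors); each pair must satisfy `H <= 2 min(S, 1-S)`.
#' @param L markers (default 31).
#' @param seed RNG seed.
#' @return a [genotype_panel()] (single locality `"swarm"`).
#' @export
simulate_admixed_swarm <- function(n, S, H, L = 31L, seed) {
  if (missing(seed)) stop("'seed' is mandatory")
  S <- rep_len(S, n); H <- rep_len(H, n)
  bad <- H > 2 * pmin(S, 1 - S) + 1e-12
  if (any(bad))
    stop(sprintf("infeasible (S, H) pair: (%.3f, %.3f) outside the triangle",
                 S[which(bad)[1L]], H[which(bad)[1L]]))
  with_seed(seed, {
    g <- t(vapply(seq_len(n), function(i) {
      sample(0:2, L, replace = TRUE,
             prob = c(1 - S[i] - H[i] / 2, H[i], S[i] - H[i] / 2))
    }, integer(L)))
    dimnames(g) <- list(sprintf("sw_i%03d", seq_len(n)),
                        sprintf("m%03d", seq_len(L)))
    genotype_panel(g, locality_code = rep("swarm", n),
                   life_stage = "post_metamorphic")
  })
}

# Separable Gaussian blur of a matrix (reflecting edges via renormalisation).
gaussian_blur <- function(m, sd_cells) {
  if (sd_cells <= 0) return(m)
  k <- function(n) {
    d <- dnorm(outer(seq_len(n), seq_len(n), "-"), sd = sd_cells)
    d / rowSums(d)
  }
  k(nrow(m)) %*% m %*% t(k(ncol(m)))
}

#' Simulate a climate landscape with two species' occurrences
#'
#' Climate layers are smooth correlated random fields (a random low-order
#' spatial trend plus Gaussian-filtered noise), standardized per layer.
#' Each species' suitability is a Gaussian function of the first two
#' environmental variables around its own niche center; occurrences are
#' sampled from valid cells with probability proportional to suitability,
#' jittered within the cell. The analytic niche parameters are recorded as
#' ground truth.
#'
#' @param extent `c(xmin, xmax, ymin, ymax)` degrees.
#' @param resolution cell size, degrees.
#' @param n_variables number of climate layers (default 7).
#' @param smoothness Gaussian filter SD in cells (default 5).
#' @param niche_centers 2-row matrix: each species' niche center on the
#'   first two (standardized) variables.
#' @param niche_sd suitability SD (scalar or per-species vector).
#' @param n_occurrences occurrences per species (recycled).
#' @param seed RNG seed.
#' @return list of class `climate_sim`: `stack` ([raster_stack()]),
#'   `occurrences` ([occurrence_set()]), `truth`.
#' @export
simulate_climate_landscape <- function(extent = c(27, 45, 39, 43),
                                       resolution = 0.1,
                                       n_variables = 7L, smoothness = 5,
                                       niche_centers = rbind(a = c(-0.5, 0),
                                                             b = c(0.5, 0)),
                                       niche_sd = 0.8,
                                       n_occurrences = 100L,
                                       seed) {
  if (missing(seed)) stop("'seed' is mandatory")
  nc <- round((extent[2L] - extent[1L]) / resolution)
  nr <- round((extent[4L] - extent[3L]) / resolution)
  if (nr < 2L || nc < 2L) stop("extent/resolution give a degenerate grid")
  with_seed(seed, {
    rr <- row(matrix(0, nr, nc)) / nr; cc <- col(matrix(0, nr, nc)) / nc
    layers <- lapply(seq_len(n_variables), function(i) {
      trend <- rnorm(1L) * rr + rnorm(1L) * cc + rnorm(1L) * rr * cc
      noise <- gaussian_blur(matrix(rnorm(nr * nc), nr, nc), smoothness)
      f <- trend + noise * 2
      (f - mean(f)) / sd(f)
    })
    names(layers) <- sprintf("bio%02d", seq_len(n_variables))
    stack <- raster_stack(layers, extent[1L], extent[2L], extent[3L], extent[4L])
    sdv <- rep_len(niche_sd, nrow(niche_centers))
    species <- rownames(niche_centers) %||% c("a", "b")
    n_occ <- rep_len(n_occurrences, nrow(niche_centers))
    occs <- lapply(seq_len(nrow(niche_centers)), function(s) {
      suit <- exp(-0.5 * ((layers[[1L]] - niche_centers[s, 1L])^2 +
                          (layers[[2L]] - niche_centers[s, 2L])^2) / sdv[s]^2)
      idx <- sample(length(suit), n_occ[s], replace = TRUE,
                    prob = as.vector(suit))
      ri <- (idx - 1L) %% nr + 1L; ci <- (idx - 1L) %/% nr + 1L
      data.frame(species = species[s],
                 latitude = stack$lat[ri] + runif(n_occ[s], -0.5, 0.5) * resolution,
                 longitude = stack$lon[ci] + runif(n_occ[s], -0.5, 0.5) * resolution)
    })
    occ <- do.call(rbind, occs)
    structure(list(stack = stack,
                   occurrences = occurrence_set(occ$species, occ$latitude,
                                                occ$longitude),
                   truth = list(niche_centers = niche_centers,
                                niche_sd = sdv, seed = seed)),
              class = "climate_sim")
  })
}
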