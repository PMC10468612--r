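#' Admixture linkage disequilibrium from hybrid-index variance
#'
#' At a hybrid-zone center, association among ancestry states at different
#' loci inflates the variance of the individual hybrid index above the
#' binomial expectation. With L diagnostic loci and mean allele frequency
#' \eqn{\bar p} among the sampled individuals,
#' \deqn{Var(HI) = \bar p \bar q \left[\frac{1}{2L} +
#'       \frac{L-1}{2L} D'\right]}
#' (assuming no within-locus excess, i.e. F_IS = 0, which the upstream HWE
#' screening supports), so the standardized admixture LD is recovered as
#' \deqn{D' = \frac{2L\,Var(HI)/(\bar p \bar q) - 1}{L - 1}.}
#' Sampling noise can push the estimate below 0 or above 1; it is clamped
#' to `[0, 1]` with a warning.
#'
#' @param hi individual hybrid indices of zone-center individuals.
#' @param L number of diagnostic loci.
#' @param p_bar mean *ophryticus* allele frequency; default `mean(hi)`.
#' @return D-prime in `[0, 1]`.
#' @export
dprime_from_hi_variance <- function(hi, L, p_bar = NULL) {
  hi <- hi[!is.na(hi)]
  if (length(hi) < 2L) stop("need at least 2 individuals")
  if (L < 2L) stop("need at least 2 loci")
  p_bar <- p_bar %||% mean(hi)
  if (p_bar <= 0 || p_bar >= 1)
    stop("no polymorphism at center (p_bar is 0 or 1)")
  v <- var(hi)
  d <- (2 * L * v / (p_bar * (1 - p_bar)) - 1) / (L - 1)
  if (d < 0) {
    warning("negative D' estimate floored at 0")
    d <- 0
  } else if (d > 1) {
    warning("D' estimate above 1 capped at 1")
    d <- 1
  }
  d
}

# Direct pairwise estimator: mean standardized covariance of allele dosages
# across locus pairs. Used as an internal cross-check of the variance route.
dprime_pairwise <- function(dosage, p_bar = NULL) {
  a <- dosage / 2
  p_bar <- p_bar %||% mean(a, na.rm = TRUE)
  cv <- cov(a, use = "pairwise.complete.obs")
  off <- cv[upper.tri(cv)]
  mean(off, na.rm = TRUE) / (p_bar * (1 - p_bar) / 2)
}

#' Lifetime dispersal from admixture LD (dispersal-recombination balance)
#'
#' At equilibrium in a tension zone, \eqn{D' = \sigma^2 / (r w^2)}, so
#' \eqn{\sigma = w \sqrt{r D'}}.
#'
#' @param d_prime standardized admixture LD.
#' @param r mean recombination rate between marker pairs (0.5 for unlinked
#'   markers).
#' @param w cline width, km.
#' @return lifetime dispersal, km per generation.
#' @export
sigma_from_ld <- function(d_prime, r, w) {
  if (any(c(d_prime, r, w) <= 0)) stop("all inputs must be > 0")
  w * sqrt(r * d_prime)
}

#' Expected cline width under neutral diffusion
#'
#' After T generations of secondary contact with no selection the cline
#' spreads to \eqn{w = \sigma \sqrt{2 \pi T}}.
#'
#' @param sigma lifetime dispersal, km/generation.
#' @param T_gen generations since contact.
#' @return expected neutral width, km.
#' @examples
#' neutral_width(0.62, 2400) # ~76 km: vastly wider than an observed 3.4 km
#' @export
neutral_width <- function(sigma, T_gen) {
  if (sigma <= 0) stop("sigma must be > 0")
  if (T_gen < 1) stop("T_gen must be >= 1")
  sigma * sqrt(2 * pi * T_gen)
}

#' Average effective selection maintaining a tension zone
#'
#' \eqn{s^* = 8 \sigma^2 / w^2}: the aggregate selection pressure against
#' hybrids needed to hold a cline of width w against dispersal sigma. The
#' width may be taken from the hybrid-index cline (`mode =
#' "hybrid_index_width"`) or from the mean single-marker cline width
#' (`"mean_marker_width"`); the two conventions differ and both are
#' reported by [dispersal_pipeline()].
#'
#' @param sigma lifetime dispersal, km/generation.
#' @param w cline width, km.
#' @param mode label recording which width convention `w` follows.
#' @return s-star (dimensionless).
#' @export
effective_selection <- function(sigma, w,
                                mode = c("hybrid_index_width",
                                         "mean_marker_width")) {
  mode <- match.arg(mode)
  if (sigma <= 0 || w <= 0) stop("inputs must be > 0")
  structure(8 * sigma^2 / w^2, mode = mode)
}

#' Generations needed to disperse across the zone
#'
#' `w / sigma`: how many generations of average dispersal it takes to cross
#' the cline width.
#'
#' @param w cline width, km.
#' @param sigma lifetime dispersal, km/generation.
#' @return generations.
#' @export
generations_to_cross <- function(w, sigma) {
  if (sigma <= 0 || w <= 0) stop("inputs must be > 0")
  w / sigma
}

#' Full tension-zone estimation chain
#'
#' Chains the estimators: select zone-center localities (within
#' `center_radius` of the transect origin, default half the fitted cline
#' width), restrict to dispersal-informative individuals (post-metamorphic
#' by default -- larvae have not yet had the opportunity to disperse;
#' individuals of unknown stage are kept), then
#' D' ([dprime_from_hi_variance()]) -> sigma ([sigma_from_ld()]) ->
#' neutral width ([neutral_width()]) -> effective selection
#' ([effective_selection()]) and generations to cross, with
#' `T = contact_age_years / generation_time`.
#'
#' @param panel a [genotype_panel()].
#' @param transect an `isoline_transect` from [signed_distances()] (or any
#'   data frame `code`, `distance_km`).
#' @param fit a `cline_fit` for the hybrid index (provides the width).
#' @param r mean recombination rate (default 0.5, unlinked markers).
#' @param generation_time years per generation (default 5, typical of
#'   *Ommatotriton* newts).
#' @param contact_age_years years since secondary contact (default 12000,
#'   onset of the Holocene).
#' @param center_radius km; localities with `|distance| <= center_radius`
#'   are zone-center (default fitted width / 2).
#' @param life_stage_policy `"post_metamorphic"` (default; excludes
#'   pre-metamorphic individuals) or `"all"`.
#' @param mean_marker_width optional mean width of per-marker clines, for
#'   the second s-star convention.
#' @return list of class `tension_zone_estimates` with every estimate and
#'   the inputs it was derived from.
#' @export
dispersal_pipeline <- function(panel, transect, fit, r = 0.5,
                               generation_time = 5, contact_age_years = 12000,
                               center_radius = NULL,
                               life_stage_policy = c("post_metamorphic", "all"),
                               mean_marker_width = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  life_stage_policy <- match.arg(life_stage_policy)
  w <- fit$model$width
  center_radius <- center_radius %||% (w / 2)
  center_locs <- transect$code[abs(transect$distance_km) <= center_radius]
  if (length(center_locs) == 0L)
    stop("no center localities within ", signif(center_radius, 3), " km of the isoline")
  in_center <- panel$locality_code %in% center_locs
  keep <- in_center
  if (life_stage_policy == "post_metamorphic")
    keep <- keep & panel$life_stage != "pre_metamorphic"
  if (!any(keep))
    stop("no dispersal-informative individuals (all pre-metamorphic?)")
  hi <- individual_hybrid_index(subset_panel(panel, which(keep)))$hybrid_index
  L <- length(panel$marker_id)
  d_prime <- dprime_from_hi_variance(hi, L)
  T_gen <- contact_age_years / generation_time
  sigma <- if (d_prime > 0) sigma_from_ld(d_prime, r, w) else 0
  out <- list(
    d_prime = d_prime,
    sigma = sigma,
    w_neutral = if (sigma > 0) neutral_width(sigma, T_gen) else 0,
    s_star_hybrid_index = if (sigma > 0)
      as.numeric(effective_selection(sigma, w)) else 0,
    s_star_mean_marker = if (sigma > 0 && !is.null(mean_marker_width))
      as.numeric(effective_selection(sigma, mean_marker_width,
                                     "mean_marker_width")) else NA_real_,
    generations_to_cross = if (sigma > 0) generations_to_cross(w, sigma)
      else NA_real_,
    inputs = list(width_km = w, r = r, generation_time = generation_time,
                  contact_age_years = contact_age_years, T_gen = T_gen,
                  center_radius_km = center_radius,
                  center_localities = center_locs,
                  n_individuals = sum(keep), L = L,
                  life_stage_policy = life_stage_policy,
                  mean_marker_width = mean_marker_width))
  class(out) <- "tension_zone_estimates"
  out
}

#' @export
print.tension_zone_estimates <- function(x, ...) {
  cat(sprintf("<tension_zone_estimates> D'=%.4f, sigma=%.3f km/gen, neutral width=%.2f km, s*=%.3f, %.1f generations to cross\n",
              x$d_prime, x$sigma, x$w_neutral, x$s_star_hybrid_index,
              x$generations_to_cross))
  invisible(x)
}
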