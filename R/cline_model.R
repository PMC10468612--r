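#' Geographic cline model (sigmoid center, optional exponential tails)
#'
#' The classical hybrid-zone cline: a central sigmoid
#' \deqn{S(x) = \frac{1 + \tanh(2 (x - c) / w)}{2}}
#' with center `c` (km along the transect) and width `w` (inverse of the
#' maximum slope, km), optionally replaced beyond a distance `delta` from
#' the center by an exponential tail whose slope at the junction is a
#' fraction `tau` of the sigmoid slope, matched continuously in value (the
#' Szymura-Barton / HZAR tail parameterisation). The unit cline is then
#' rescaled to the asymptotic frequencies `[pmin, pmax]`.
#'
#' Tail variants: `"none"`, `"left"`, `"right"`, `"mirror"` (both tails,
#' shared `delta`/`tau`), `"both"` (independent tails). Together with the
#' three frequency-scaling variants (fixed 0/1, observed extremes, free)
#' these form the 15-model family fitted by [model_select()].
#'
#' @param center cline center c, km.
#' @param width cline width w > 0, km.
#' @param pmin,pmax asymptotic allele frequencies, `pmin <= pmax`.
#' @param tails tail variant (see above).
#' @param delta_l,tau_l left-tail junction distance (km, >= 0) and relative
#'   slope (0..1); used for `tails` in `"left"`, `"mirror"`, `"both"`.
#' @param delta_r,tau_r right-tail parameters; for `"mirror"` the left
#'   values are reused.
#' @return list of class `cline_model`.
#' @examples
#' m <- cline_model(center = 0, width = 2)
#' cline_predict(m, c(-1, 0, 1))
#' @export
cline_model <- function(center, width, pmin = 0, pmax = 1,
                        tails = c("none", "left", "right", "mirror", "both"),
                        delta_l = 0, tau_l = 1, delta_r = 0, tau_r = 1) {
  tails <- match.arg(tails)
  if (width <= 0) stop("width must be > 0")
  if (pmin > pmax) stop("pmin must not exceed pmax")
  if (pmin < 0 || pmax > 1) stop("pmin/pmax must be in [0, 1]")
  if (any(c(delta_l, delta_r) < 0)) stop("tail delta must be >= 0")
  if (any(c(tau_l, tau_r) < 0 | c(tau_l, tau_r) > 1))
    stop("tail tau must be in [0, 1]")
  if (tails == "mirror") { delta_r <- delta_l; tau_r <- tau_l }
  structure(list(center = center, width = width, pmin = pmin, pmax = pmax,
                 tails = tails, delta_l = delta_l, tau_l = tau_l,
                 delta_r = delta_r, tau_r = tau_r),
            class = "cline_model")
}

#' Predicted allele frequency along the transect
#'
#' @param model a [cline_model()].
#' @param x transect positions, km (negative = *nesterovi* side).
#' @return expected frequencies in `[pmin, pmax]` (unclamped; the
#'   likelihood applies its own floor).
#' @export
cline_predict <- function(model, x) {
  stopifnot(inherits(model, "cline_model"))
  c0 <- model$center; w <- model$width
  sig <- function(u) 1 / (1 + exp(-4 * (u - c0) / w)) # = (1+tanh(2(u-c0)/w))/2
  p <- sig(x)
  if (model$tails %in% c("left", "mirror", "both")) {
    xl <- c0 - model$delta_l
    i <- x < xl
    if (any(i)) {
      sl <- sig(xl)
      p[i] <- sl * exp(4 * model$tau_l * (1 - sl) * (x[i] - xl) / w)
    }
  }
  if (model$tails %in% c("right", "mirror", "both")) {
    xr <- c0 + model$delta_r
    i <- x > xr
    if (any(i)) {
      sr <- sig(xr)
      p[i] <- 1 - (1 - sr) * exp(-4 * model$tau_r * sr * (x[i] - xr) / w)
    }
  }
  model$pmin + (model$pmax - model$pmin) * p
}

#' Binomial cline log-likelihood
#'
#' The full binomial log-likelihood
#' \eqn{\sum_i \log\binom{n_i}{k_i} + k_i \log p(x_i) +
#' (n_i - k_i) \log(1 - p(x_i))} (the coefficient term is a data-only
#' constant, so every model comparison is unaffected by it; it is kept so
#' printed log-likelihoods match `dbinom`). Predicted frequencies are
#' clamped to `[1e-6, 1 - 1e-6]` so fixed localities never produce
#' infinite terms.
#'
#' @param model a [cline_model()].
#' @param x transect positions (km).
#' @param k counts of the *ophryticus* allele per locality.
#' @param n total allele counts per locality (haploid markers: haplotype
#'   sample sizes).
#' @return log-likelihood (<= 0 up to the omitted constant).
#' @export
cline_loglik <- function(model, x, k, n) {
  if (any(n < 1) || any(k > n) || any(k < 0)) stop("invalid counts")
  eps <- 1e-6
  p <- pmin(pmax(cline_predict(model, x), eps), 1 - eps)
  sum(lchoose(n, k) + k * log(p) + (n - k) * log(1 - p))
}

#' Akaike information criterion corrected for small samples
#'
#' `AICc = -2 logL + 2K + 2K(K+1)/(n - K - 1)`.
#'
#' @param logL model log-likelihood.
#' @param K number of free parameters.
#' @param n number of data points (localities).
#' @return AICc value; error when `n <= K + 1` (correction undefined).
#' @export
aicc <- function(logL, K, n) {
  if (n <= K + 1) stop("AICc undefined: need n > K + 1")
  -2 * logL + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

# Free-parameter count of a tail/scaling variant.
cline_n_params <- function(tails, scaling) {
  2L + switch(tails, none = 0L, left = 2L, right = 2L, mirror = 2L, both = 4L) +
    if (scaling == "free") 2L else 0L
}

# The 15-variant family.
cline_variants <- function() {
  expand.grid(tails = c("none", "left", "right", "mirror", "both"),
              scaling = c("fixed", "observed", "free"),
              stringsAsFactors = FALSE)
}
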