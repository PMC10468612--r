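#' Individual hybrid index
#'
#' Proportion of diagnostic *ophryticus* alleles carried by each individual:
#' sum of dosages over called markers divided by twice the number of called
#' markers. Missing markers are excluded from numerator and denominator; an
#' individual with no called markers gets `NA` (and is excluded from
#' locality means downstream).
#'
#' @param panel a [genotype_panel()].
#' @param individual_id optional: restrict to one or more individuals.
#' @return data frame `individual_id`, `locality_code`, `hybrid_index`,
#'   `n_called_alleles`.
#' @export
individual_hybrid_index <- function(panel, individual_id = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (!is.null(individual_id)) panel <- subset_panel(panel, individual_id)
  called <- rowSums(!is.na(panel$dosage))
  hi <- rowSums(panel$dosage, na.rm = TRUE) / (2 * called)
  hi[called == 0L] <- NA_real_
  data.frame(individual_id = panel$individual_id,
             locality_code = panel$locality_code,
             hybrid_index = as.vector(hi),
             n_called_alleles = as.integer(2L * called),
             row.names = NULL)
}

#' Locality hybrid index (pooled over alleles)
#'
#' The locality index pools all called alleles at the locality (so
#' individuals with more complete genotypes carry proportionally more
#' weight), rather than averaging individual indices; the pooled count is
#' what the binomial cline likelihood consumes.
#'
#' @param panel a [genotype_panel()].
#' @param locality_code optional: restrict to one or more localities.
#' @return data frame `locality_code`, `hybrid_index`, `n_called_alleles`,
#'   `n_individuals`.
#' @export
locality_hybrid_index <- function(panel, locality_code = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  locs <- locality_code %||% unique(panel$locality_code)
  miss <- setdiff(locs, panel$locality_code)
  if (length(miss)) stop("empty locality: ", miss[1L])
  rows <- lapply(locs, function(l) {
    g <- panel$dosage[panel$locality_code == l, , drop = FALSE]
    called <- sum(!is.na(g))
    if (called == 0L) stop("locality '", l, "' has no called genotypes")
    data.frame(locality_code = l,
               hybrid_index = sum(g, na.rm = TRUE) / (2 * called),
               n_called_alleles = 2L * called,
               n_individuals = nrow(g))
  })
  do.call(rbind, rows)
}

# Per-locus genotype probabilities of the ancestry/heterozygosity model:
# P(g=2) = S - H/2, P(g=1) = H, P(g=0) = 1 - S - H/2, feasible on the
# triangle 0 <= H <= 2 min(S, 1 - S).
triangle_loglik <- function(S, H, n0, n1, n2, eps = 1e-9) {
  p2 <- pmax(S - H / 2, eps)
  p1 <- pmax(H, eps)
  p0 <- pmax(1 - S - H / 2, eps)
  n2 * log(p2) + n1 * log(p1) + n0 * log(p0)
}

#' Maximum-likelihood ancestry and interclass heterozygosity
#'
#' Places one individual on the ancestry (S) versus interclass
#' heterozygosity (H) "triangle": S is the fraction of its diagnostic
#' alleles inherited from *O. ophryticus*, H the fraction of markers
#' heterozygous for alleles of both species. The per-locus genotype model is
#' `P(2) = S - H/2`, `P(1) = H`, `P(0) = 1 - S - H/2`, maximised over the
#' feasible triangle `0 <= H <= 2 min(S, 1-S)` by a coarse grid search with
#' local refinement (probabilities floored at 1e-9 before logs so boundary
#' optima never yield -Inf; exact ties broken toward smaller H). Missing
#' loci are skipped. Pure parentals land in the bottom corners (0,0) and
#' (1,0); F1 hybrids at (0.5, 1).
#'
#' @param panel a [genotype_panel()].
#' @param individual_id one individual id.
#' @param grid_step coarse grid step on S and H (default 0.005).
#' @return list of class `triangle_estimate`: `individual_id`, `S`, `H`,
#'   `logL`, `n_loci`.
#' @export
triangle_ml <- function(panel, individual_id, grid_step = 0.005) {
  stopifnot(inherits(panel, "genotype_panel"))
  g <- panel$dosage[match(individual_id, panel$individual_id), ]
  g <- g[!is.na(g)]
  if (length(g) == 0L) stop("individual has no called markers")
  n0 <- sum(g == 0L); n1 <- sum(g == 1L); n2 <- sum(g == 2L)
  opt <- triangle_opt(n0, n1, n2, grid_step)
  structure(list(individual_id = individual_id, S = opt$S, H = opt$H,
                 logL = opt$logL, n_loci = length(g)),
            class = "triangle_estimate")
}

triangle_opt <- function(n0, n1, n2, grid_step = 0.005) {
  search <- function(Sv, Hv) {
    grid <- expand.grid(S = Sv, H = Hv)
    grid <- grid[grid$H <= 2 * pmin(grid$S, 1 - grid$S) + 1e-12, , drop = FALSE]
    ll <- triangle_loglik(grid$S, grid$H, n0, n1, n2)
    top <- which(ll > max(ll) - 1e-12)
    best <- top[which.min(grid$H[top])]    # ties toward smaller H
    list(S = grid$S[best], H = grid$H[best], logL = ll[best])
  }
  co <- search(seq(0, 1, by = grid_step), seq(0, 1, by = grid_step))
  fine <- grid_step / 10
  res <- search(seq(max(0, co$S - grid_step), min(1, co$S + grid_step), by = fine),
                seq(max(0, co$H - grid_step), min(1, co$H + grid_step), by = fine))
  res
}

#' Triangle estimates for every individual, with corner occupancy
#'
#' @param panel a [genotype_panel()].
#' @param grid_step passed to [triangle_ml()].
#' @param corner_radius individuals with `S` within this distance of 0 or 1
#'   and `H` at or below it count as occupying a pure-parental corner
#'   (reporting convention, default 0.05).
#' @return data frame of per-individual estimates; attribute `corners`
#'   holds counts `nesterovi_corner`, `ophryticus_corner`, `other`.
#' @export
triangle_batch <- function(panel, grid_step = 0.005, corner_radius = 0.05) {
  stopifnot(inherits(panel, "genotype_panel"))
  ests <- lapply(panel$individual_id, function(id) {
    e <- triangle_ml(panel, id, grid_step)
    data.frame(individual_id = id, locality_code =
                 panel$locality_code[panel$individual_id == id],
               S = e$S, H = e$H, logL = e$logL, n_loci = e$n_loci)
  })
  out <- do.call(rbind, ests)
  nest <- out$S <= corner_radius & out$H <= corner_radius
  ophr <- out$S >= 1 - corner_radius & out$H <= corner_radius
  attr(out, "corners") <- c(nesterovi_corner = sum(nest),
                            ophryticus_corner = sum(ophr),
                            other = sum(!nest & !ophr))
  out
}
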