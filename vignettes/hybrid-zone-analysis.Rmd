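---
title: "Hybrid-zone cline analysis with hzclines: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid-zone cline analysis with hzclines: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hzclines)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the tunable parameters and why their
defaults are what they are, what the synthetic-data generators do and do
not emulate, the numerical choices, and the known limitations. It states
no empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The system and the data model

Two banded newt species, *Ommatotriton nesterovi* and *O. ophryticus*,
meet in a narrow contact zone on the southern Black Sea coast. Individuals
are genotyped at a panel of species-diagnostic SNP markers — loci fixed
for alternative alleles in the two parental species — so ancestry can be
read directly from genotypes. A `genotype_panel` stores, per individual
and marker, the dosage (0/1/2) of the *O. ophryticus* allele; a hybrid
index of 1 therefore means pure *ophryticus*, matching the convention of
the packaged locality table (`ommatotriton_localities()`: 42 natural-range
localities plus one introduced, admixed Spanish population; 523 genotyped
individuals in total). Missing genotypes are `NA` throughout and are
excluded from both numerators and denominators, never imputed.

Coordinates are always WGS84 decimal degrees and all distances are
great-circle (haversine, Earth radius 6371 km); no projected CRS is used
anywhere.

## Marker quality control

**Hardy–Weinberg.** `hwe_exact_test()` enumerates the exact conditional
(Levene/Haldane) distribution of the heterozygote count given the observed
allele counts, so no asymptotic approximation enters at the per-locality
sample sizes typical of hybrid-zone surveys (here 3–16 individuals).
One-sided deficit and excess p-values are the tail sums including the
observed configuration; monomorphic samples are flagged "not testable"
rather than given a numeric p.

**Multiple testing.** The correction is a per-test threshold
`alpha / n_tests` (`corrected_alpha()`), with `n_tests` defaulting to the
number of markers (32 in the motivating panel, so 0.05/32 = 0.0015625).
Whether such a correction should run across markers, across populations,
or both is genuinely ambiguous in common practice; both are available via
the `n_tests` argument, and the default corrects across markers within
each population's batch, the reading that keeps a marker's tests mutually
comparable across populations.

**Exclusion rule.** `screen_hwe()` counts, per marker, the populations
with a corrected-significant heterozygote *deficit* (the signature of a
null allele or mis-clustering assay) and excludes markers at or above
`min_sig_pops`. The motivating study excluded a marker significant in
four populations but stated no threshold; the default is 2, because a
deficit repeated in independent populations indicates a marker-level
artifact while a single population can be chance or local structure. It
is a tuning parameter, not a law.

**Linkage disequilibrium.** `ld_test()` uses a log-likelihood-ratio G
statistic on the per-locality 3×3 genotype tables, summed over localities,
with the null distribution from permuting one marker's genotypes *within*
localities — stratification that prevents Wahlund-driven spurious LD when
allele frequencies differ among localities. p-values use the add-one rule
`(b + 1)/(m + 1)`, so the floor at m permutations is 1/(m+1). 1000
permutations by default; the seed is a required argument.

**Diagnosticity.** `diagnosticity_screen()` retains markers where
reference localities of one species carry only dosage 0 and the other only
dosage 2, missing calls ignored — the operational definition of a
diagnostic marker.

## Hybrid indices

The individual hybrid index is the proportion of called alleles that are
*ophryticus*: `sum(dosage) / (2 × called markers)`. The locality index is
*pooled over alleles* rather than averaged over individuals: individuals
with more complete genotypes carry proportionally more weight, and the
pooled numerator/denominator pair is exactly the `(k, n)` the binomial
cline likelihood consumes. For panels with little missing data the two
definitions agree to rounding.

## Ancestry–heterozygosity triangle

`triangle_ml()` places an individual at maximum-likelihood ancestry `S`
(fraction of alleles from *ophryticus*) and interclass heterozygosity `H`
(fraction of markers with one allele from each species), under the
per-locus model `P(2) = S − H/2`, `P(1) = H`, `P(0) = 1 − S − H/2` on the
feasible triangle `0 ≤ H ≤ 2·min(S, 1−S)`. Parentals sit at the bottom
corners, F1s at the apex (0.5, 1), F2s around (0.5, 0.5), backcrosses at
(0.25/0.75, 0.5). The optimum is found by a coarse grid (step 0.005)
plus a 10× finer local refinement; the likelihood floor is 1e-9 before
logs so boundary optima never produce −Inf, and exact ties break toward
smaller `H` (the less admixed interpretation). For complete data the MLE
has a closed form (the multinomial proportions projected onto the
triangle), which the test suite uses as the oracle the grid search must
match.

## From map to transect

Cline models are one-dimensional, so the 2-D locality map must become a
signed axis. Three steps, `build_transect()`:

1. `interpolate_hi_surface()` interpolates locality hybrid indices
   *linearly on a Delaunay triangulation* (package `interp`), node-exact
   by construction, evaluated on a regular grid (default 0.01°) over the
   locality bounding box and masked outside the convex hull.
2. `extract_isoline()` takes the 0.5 contour — the theoretical zone
   center — as the *exact level set* of the piecewise-linear surface: each
   crossed triangle contributes one straight segment, segments are chained
   into polylines, and the longest component (great-circle length) is
   kept. Computing the level set exactly, rather than by marching squares
   on the resampled grid, makes the isoline independent of grid
   resolution; on the packaged table the distances are bit-identical
   between 0.02° and 0.005° grids. An optional clipping polygon can trim
   the isoline to a species-range mask.
3. `signed_distances()` assigns each locality the minimum great-circle
   distance to the isoline (segments densified to ≤ 0.1 km), negative on
   the *nesterovi* side (hybrid index < 0.5), positive on the
   *ophryticus* side.

**Why linear interpolation and not a smoothing spline?** Akima-type
splines (which the original GIS workflow used) are not shape-preserving on
highly irregular layouts: on the packaged table they overshoot badly near
the contact (values of ~0.4 within 200 m of a 0.06 node) and fragment the
0.5 contour into dozens of spurious pieces. Linear interpolation is
monotone along every triangle edge and cannot invent crossings. The cost
is geometric: with long, thin triangles the level set can pass close to a
locality whose index is near, but not at, 0.5. On the packaged table the
isoline passes ~0.3 km from the easternmost *nesterovi* locality (index
0.06), which compresses near-center distances relative to a hand-smoothed
isoline — see Limitations.

## The geographic cline family

`cline_predict()` implements the standard hybrid-zone cline: a central
sigmoid

> p(x) = (1 + tanh(2(x − c)/w)) / 2,

with center `c` (km) and width `w` (km; the inverse of the maximum slope),
optionally replaced beyond a distance δ from the center by an exponential
tail matched continuously in value whose log-slope is a fraction τ of the
sigmoid's at the junction — for the left tail, with S the unit sigmoid and
x_L = c − δ:

> p(x) = S(x_L) · exp( 4τ (1 − S(x_L)) (x − x_L) / w ),  x < x_L,

and mirrored on the right. The unit cline is rescaled to asymptotes
`[pmin, pmax]`. Five tail variants (none / left / right / mirror / both)
crossed with three scalings (fixed 0/1, observed locality extremes, free)
give the classical 15-variant family; parameter counts run from K = 2
(none/fixed) to K = 8 (both/free). The prediction is monotone
non-decreasing for every valid parameter set, a property the test suite
checks across random models.

**Likelihood.** Per-locality allele counts `k` of `n` are binomial at
`p(x)` clamped to `[1e-6, 1 − 1e-6]`, so localities fixed for one allele
contribute finitely. The full `dbinom` log-likelihood (coefficient
included) is reported; the coefficient is a data-only constant and cancels
in every comparison. Haploid data (mtDNA) enter with `n` = haplotype
sample size.

**Fitting.** `fit_cline()` finds the ML point by multi-start bounded
L-BFGS-B (deterministic starts at empirical 0.5-crossings plus seeded
random starts; free scaling is parameterised as `pmin` and
`pmax = pmin + (1 − pmin)·u` so `pmin ≤ pmax` holds throughout). Bounds:
`c` within the transect span ± span/2, `w ∈ [0.01, 2·span]`,
`δ ∈ [0, span]`, `τ ∈ [0, 1]`, uniform. A Metropolis MCMC stage (default
3 chains × 100,000 steps, 10% burn-in, proposal scales auto-tuned to
20–40% acceptance during burn-in, seed required) then yields
*two-log-likelihood-unit support limits*: the per-parameter range of all
samples within 2 log-units of the maximum. Following the field's
convention these are labelled "95% CI" in outputs. If a chain stumbles on
a better mode than the optimizer, the better point is reported. Chains
whose maxima disagree by more than 2 log-units flag the fit as
non-converged.

**Selection.** `model_select()` fits all 15 variants, ranks by
`AICc = −2logL + 2K + 2K(K+1)/(n−K−1)` (n = number of localities), and
breaks ties (ΔAICc < 2) toward fewer parameters. Per-variant failures are
flagged rows, never aborting the family. By default MCMC support limits
are computed for the selected model only (`mcmc = "best"`); `"all"`
reproduces the exhaustive behaviour of the classical software at 15× the
cost.

## Tension-zone estimators

At a dispersal–selection equilibrium the zone-center admixture linkage
disequilibrium, dispersal, and width are linked. With L diagnostic loci
and mean frequency p̄ among zone-center individuals, assuming no
within-locus excess (F_IS = 0, which the upstream HWE screen supports),

> Var(HI) = p̄q̄ [ 1/(2L) + (L−1)/(2L) · D′ ],

which `dprime_from_hi_variance()` inverts for D′ (estimates outside
[0, 1] are clamped with a warning — sampling noise does that at small n).
Then `sigma_from_ld()` gives lifetime dispersal σ = w√(r·D′) (r = mean
recombination rate, 0.5 for unlinked markers), `neutral_width()` the
expected width σ√(2πT) after T generations of neutral contact,
`effective_selection()` the aggregate selection s\* = 8σ²/w², and
`generations_to_cross()` the ratio w/σ.

`dispersal_pipeline()` chains these: zone-center localities are those
within `center_radius` of the isoline (default: half the fitted width —
the region where admixture LD is generated), and only
dispersal-informative individuals enter the variance (post-metamorphic by
default, since larvae have not yet dispersed; individuals of unknown stage
are kept, as adults dominate field sampling). Defaults T = 12,000 years /
5 years per generation = 2,400 generations (onset-of-Holocene contact,
newt generation time) and r = 0.5.

**Which width enters s\*?** The literature is not explicit about whether
w is the hybrid-index cline width or the mean single-marker width (which
is systematically wider, since single-marker clines add noise). Both
conventions are computed (`s_star_hybrid_index`, `s_star_mean_marker`);
neither is presented as canonical.

## Climatic niche overlap

`select_variables()` greedily drops layers until no background pair has
|Pearson r| at or above the threshold (default 0.7), removing the member
of the worst pair with the larger mean absolute correlation.
`pca_env()` ordinates the *entire background* (every valid cell of the
calibration extent, standardized), and occurrences are projected into that
space — so the ordination describes available environments, not the
occurrences. `occupancy_grid()` lays a Gaussian kernel density of the
occurrence scores on an R×R grid (default 100) spanning the background's
PC1–PC2 range (Silverman bandwidth per axis, floored at one grid cell),
divides by the background kernel density to correct for availability —
restricted to the cells carrying 99% of background mass, with the divisor
floored at its 1st percentile so rare environments cannot blow up the
ratio — and renormalizes to sum 1. Schoener's
`D = 1 − ½Σ|z₁ − z₂|` then measures overlap; `similarity_test()` builds
the null by randomly translating (with wraparound) one species' occurrence
scores within its own background and recomputing D, add-one p-values, 100
repetitions by default, seed required, run in either direction.
`project_shared_suitability()` maps each geographic cell to its ordination
position and classifies it by whether it falls inside each species'
occupied niche (cells above the density threshold that excludes the lowest
5% of occupancy mass).

## Synthetic data: what it emulates, what it does not

`simulate_zone()` draws, per individual, a latent ancestry
`q ~ Beta(mean = p(x), var = v)` and then genotypes `Binomial(2, q)`
independently per locus. The Beta variance is set from the LD dial as
`v = D′·p(1−p)·(L−1)/(2L−1)`, the value that makes the hybrid-index
variance decomposition return `D′` exactly in expectation — so the
generator hits a *prescribed* cline shape and zone-center LD directly,
which is what the estimators consume. Defaults mirror the motivating
survey: L = 31 markers, 12 individuals per locality, a 3.37 km nuclear
cline, a 0.17 km mtDNA cline, zone-center D′ = 0.068 (the level implied by
a ~0.6 km/generation dispersal), and an 80% post-metamorphic fraction (a
typical adult-biased field sample; the original study does not print its
larval fraction).

It does **not** emulate: forward-time dynamics (selection, zone movement),
within-locus departures from Hardy–Weinberg (F_IS is 0 by construction),
locus-specific introgression (all loci share one q), missing data, or
genotyping error. A green recovery test therefore establishes that the
estimators invert the model they assume — not that the model captures
every feature of real zones.

`simulate_admixed_swarm()` draws genotypes from the triangle model at
fixed (S, H) — the generative counterpart of `triangle_ml()`, emulating an
introduced hybrid swarm. `simulate_climate_landscape()` builds smooth
correlated fields (random low-order trend + Gaussian-filtered noise,
standardized) and samples occurrences proportional to a Gaussian
suitability in the space of the first two variables; identical niche
parameters for two species give pipeline D → 1 as occurrence sampling
densifies (measured ≈0.81 at 150 records, ≈0.87 at 600 — kernel sampling
noise accounts for the gap), and well-separated niches give D ≈ 0.

## Numerical choices

* Probability floors: 1e-6 in the cline likelihood, 1e-9 in the triangle
  likelihood; both only matter at saturated boundaries.
* AICc ties (ΔAICc < 2) break toward fewer parameters; triangle ties
  toward smaller H; variable-selection ties toward the later layer.
* All stochastic functions take a mandatory seed and restore the caller's
  RNG state; identical seeds are bit-reproducible, which the suite checks.
* The mtDNA cline on step-like frequency data rails at the 0.01 km width
  bound: the binomial likelihood is flat in width below the inter-locality
  gap, so any "point estimate" there is a bound artifact in whatever
  software computes it; the support interval is the meaningful quantity.
* AICc requires n > K + 1; with fewer localities the richer tail variants
  are reported as flagged failures rather than fitted.

## Known limitations

* **Isoline geometry.** The exact linear-interpolation level set can run
  close to near-center localities when the locality layout creates thin
  triangles (it does here), compressing near-center transect distances.
  On the packaged table the resulting hybrid-index cline width (~2.2 km,
  support ≈ 1.6–3.1) sits inside the published 95% CI (0.21–5.33 km) but
  below the published 3.37 km point estimate, which was derived from a
  spline-smoothed, hand-trimmed isoline that cannot be reproduced
  algorithmically. The qualitative conclusion — a zone two orders of
  magnitude narrower than neutral expectation — is unchanged.
* The D′-from-variance estimator assumes all zone-center individuals share
  one expected frequency; mixing localities from different parts of a wide
  zone inflates it. The default half-width center window keeps that bias
  small for narrow zones but is a convention.
* Niche overlap from ~100 occurrence records carries kernel sampling noise
  of order 0.2 in D; comparisons of D across studies should match sample
  sizes or rely on the similarity tests.
* The Genepop export is a convenience for interoperability; the package
  does not re-implement Genepop's test batteries beyond the exact HWE and
  permutation LD tests described above.
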