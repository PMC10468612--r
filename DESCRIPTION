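Package: hzclines
Title: Hybrid Zone Cline Analysis and Tension-Zone Inference for
    Diagnostic SNP Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing narrow hybrid zones between parapatric
    (cryptic) species genotyped at species-diagnostic SNP markers. Covers
    marker quality control (exact Hardy-Weinberg deficit/excess tests,
    permutation tests of pairwise linkage disequilibrium, diagnosticity
    screening), individual and locality hybrid indices, maximum-likelihood
    ancestry and interclass-heterozygosity estimation ("triangle" plots),
    construction of a one-dimensional transect from the 0.5 hybrid-index
    isoline on a map, likelihood fitting of the classical fifteen-variant
    sigmoid/exponential-tail geographic cline family with MCMC support
    limits and AICc model selection, tension-zone estimators of dispersal
    and effective selection from admixture linkage disequilibrium, and
    ordination-based climatic niche overlap (Schoener's D with similarity
    permutation tests). Includes seeded synthetic-data generators for
    hybrid-zone genotype panels and climate landscapes so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    interp,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
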