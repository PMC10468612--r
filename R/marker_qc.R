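#' Exact Hardy-Weinberg heterozygote deficit / excess test
#'
#' Conditional exact test (Levene/Haldane): given the observed allele counts,
#' the number of heterozygotes under Hardy-Weinberg equilibrium follows the
#' distribution
#' \deqn{P(h) = \frac{n!\, n_A!\, n_a!\, 2^h}{(2n)!\, n_{AA}!\, h!\, n_{aa}!}}
#' over heterozygote counts h of the parity fixed by the allele counts. The
#' deficit p-value is \eqn{P(h \le h_{obs})}, the excess p-value
#' \eqn{P(h \ge h_{obs})}, by full enumeration (cheap at the per-locality
#' sample sizes of a hybrid-zone survey).
#'
#' @param n_AA,n_Aa,n_aa genotype counts.
#' @param alternative `"deficit"` (too few heterozygotes) or `"excess"`.
#' @return list with `p_value`, `testable` (FALSE and `p_value = NA` when
#'   the sample is monomorphic), the counts and the alternative.
#' @examples
#' hwe_exact_test(1, 0, 1, "deficit")$p_value # 1/3
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa,
                           alternative = c("deficit", "excess")) {
  alternative <- match.arg(alternative)
  n <- n_AA + n_Aa + n_aa
  if (n < 1L) stop("need at least one individual")
  nA <- 2L * n_AA + n_Aa
  na <- 2L * n_aa + n_Aa
  if (nA == 0L || na == 0L) {
    return(list(p_value = NA_real_, testable = FALSE,
                n_AA = n_AA, n_Aa = n_Aa, n_aa = n_aa,
                alternative = alternative,
                reason = "monomorphic sample: HWE not testable"))
  }
  d <- hwe_het_distribution(nA, na)
  obs <- n_Aa
  p <- if (alternative == "deficit") sum(d$p[d$h <= obs]) else sum(d$p[d$h >= obs])
  list(p_value = min(p, 1), testable = TRUE,
       n_AA = n_AA, n_Aa = n_Aa, n_aa = n_aa, alternative = alternative)
}

# Exact conditional distribution of the heterozygote count given allele
# counts nA, na; h runs over values of matching parity.
hwe_het_distribution <- function(nA, na) {
  n2 <- nA + na            # 2n alleles
  n <- n2 / 2
  h <- seq.int(nA %% 2L, min(nA, na), by = 2L)
  logp <- lfactorial(n) + lfactorial(nA) + lfactorial(na) + h * log(2) -
    lfactorial((nA - h) / 2) - lfactorial(h) - lfactorial((na - h) / 2) -
    lfactorial(n2)
  p <- exp(logp - max(logp))
  data.frame(h = h, p = p / sum(p))
}

#' Bonferroni-style per-test significance threshold
#'
#' @param alpha nominal significance level.
#' @param n_tests number of tests corrected for.
#' @return `alpha / n_tests`.
#' @examples
#' corrected_alpha(0.05, 32) # 0.0015625
#' @export
corrected_alpha <- function(alpha, n_tests) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (n_tests < 1L) stop("n_tests must be >= 1")
  alpha / n_tests
}

#' Per-marker x per-locality Hardy-Weinberg test table
#'
#' @param panel a [genotype_panel()].
#' @return data frame with genotype counts and deficit/excess p-values per
#'   marker and locality (`NA` where not testable).
#' @export
hwe_table <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  locs <- unique(panel$locality_code)
  out <- expand.grid(marker_id = panel$marker_id, locality_code = locs,
                     stringsAsFactors = FALSE)
  if (nrow(out) == 0L) {
    for (cc in c("n_AA", "n_Aa", "n_aa", "p_deficit", "p_excess"))
      out[[cc]] <- numeric(0)
    out$testable <- logical(0)
    return(out)
  }
  res <- t(mapply(function(m, l) {
    g <- panel$dosage[panel$locality_code == l, m]
    g <- g[!is.na(g)]
    cnt <- c(sum(g == 0L), sum(g == 1L), sum(g == 2L))
    if (sum(cnt) == 0L) return(c(cnt, NA_real_, NA_real_))
    c(cnt,
      hwe_exact_test(cnt[1L], cnt[2L], cnt[3L], "deficit")$p_value,
      hwe_exact_test(cnt[1L], cnt[2L], cnt[3L], "excess")$p_value)
  }, out$marker_id, out$locality_code))
  out$n_AA <- res[, 1L]; out$n_Aa <- res[, 2L]; out$n_aa <- res[, 3L]
  out$p_deficit <- res[, 4L]; out$p_excess <- res[, 5L]
  out$testable <- !is.na(out$p_deficit)
  out
}

#' Screen markers for repeated Hardy-Weinberg heterozygote deficit
#'
#' Applies [hwe_exact_test()] per marker and locality, counts localities with
#' a deficit significant at the corrected threshold, and flags markers for
#' exclusion when the count reaches `min_sig_pops`. Correction defaults to a
#' per-test threshold of `alpha / n_markers` (the "corrected for N markers"
#' convention); pass `n_tests` to correct over a different batch size.
#'
#' @param panel a [genotype_panel()].
#' @param alpha nominal level before correction.
#' @param n_tests number of tests the threshold is corrected for; default
#'   the number of markers in the panel.
#' @param min_sig_pops localities with a significant deficit needed to
#'   exclude a marker (default 2: a deficit repeated across populations is
#'   evidence of a systematic assay artifact, one population may be chance).
#' @return data frame of class `qc_decision` with `marker_id`,
#'   `n_significant_populations`, `excluded`; the full test table is
#'   attached as attribute `hwe_table`.
#' @export
screen_hwe <- function(panel, alpha = 0.05, n_tests = NULL, min_sig_pops = 2L) {
  stopifnot(inherits(panel, "genotype_panel"))
  tab <- hwe_table(panel)
  thr <- corrected_alpha(alpha, n_tests %||% length(panel$marker_id))
  sig <- tab$testable & tab$p_deficit < thr
  n_sig <- tapply(sig, tab$marker_id, sum)
  ns <- as.integer(n_sig[panel$marker_id])
  ns[is.na(ns)] <- 0L
  out <- data.frame(marker_id = panel$marker_id,
                    n_significant_populations = ns,
                    excluded = ns >= min_sig_pops)
  attr(out, "hwe_table") <- tab
  attr(out, "threshold") <- thr
  class(out) <- c("qc_decision", "data.frame")
  out
}

#' Permutation test of genotypic linkage disequilibrium between two markers
#'
#' Log-likelihood-ratio (G) statistic on the per-locality 3x3 genotype
#' contingency tables, summed across localities; the null distribution is
#' obtained by permuting one marker's genotypes within localities (so
#' population structure alone cannot create association). One-sided p-value
#' with the add-one rule `p = (#null >= observed + 1) / (n_permutations + 1)`.
#'
#' @param panel a [genotype_panel()].
#' @param marker_a,marker_b marker ids.
#' @param n_permutations at least 99; default 1000.
#' @param seed RNG seed (mandatory for reproducibility).
#' @return list with `p_value`, `G`, `testable`, `n_permutations`, `seed`.
#' @export
ld_test <- function(panel, marker_a, marker_b, n_permutations = 1000L, seed) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (missing(seed)) stop("'seed' is required")
  if (n_permutations < 99L) stop("need at least 99 permutations")
  if (!all(c(marker_a, marker_b) %in% panel$marker_id))
    stop("unknown marker id")
  ga <- panel$dosage[, marker_a]
  gb <- panel$dosage[, marker_b]
  keep <- !is.na(ga) & !is.na(gb)
  ga <- ga[keep]; gb <- gb[keep]; loc <- panel$locality_code[keep]
  if (length(unique(ga)) < 2L || length(unique(gb)) < 2L) {
    return(list(p_value = NA_real_, G = NA_real_, testable = FALSE,
                reason = "a marker is monomorphic everywhere",
                n_permutations = n_permutations, seed = seed))
  }
  g_stat <- function(a, b, loc) {
    tot <- 0
    for (l in unique(loc)) {
      i <- loc == l
      o <- table(factor(a[i], 0:2), factor(b[i], 0:2))
      e <- outer(rowSums(o), colSums(o)) / sum(o)
      nz <- o > 0
      tot <- tot + 2 * sum(o[nz] * log(o[nz] / e[nz]))
    }
    tot
  }
  obs <- g_stat(ga, gb, loc)
  with_seed(seed, {
    null <- vapply(seq_len(n_permutations), function(i) {
      bp <- gb
      for (l in unique(loc)) {
        j <- which(loc == l)
        bp[j] <- bp[sample(j)]
      }
      g_stat(ga, bp, loc)
    }, numeric(1L))
    list(p_value = (sum(null >= obs - 1e-12) + 1) / (n_permutations + 1),
         G = obs, testable = TRUE,
         n_permutations = n_permutations, seed = seed)
  })
}

#' Screen markers for species diagnosticity against reference localities
#'
#' A marker is diagnostic when reference *nesterovi* localities carry only
#' dosage 0 and reference *ophryticus* localities only dosage 2 (missing
#' calls ignored).
#'
#' @param panel a [genotype_panel()].
#' @param reference_labels named character vector mapping locality codes to
#'   `"nesterovi"` or `"ophryticus"`; both species must be represented.
#' @return character vector of retained (diagnostic) marker ids.
#' @export
diagnosticity_screen <- function(panel, reference_labels) {
  stopifnot(inherits(panel, "genotype_panel"))
  nest <- names(reference_labels)[reference_labels == "nesterovi"]
  ophr <- names(reference_labels)[reference_labels == "ophryticus"]
  if (length(nest) == 0L || length(ophr) == 0L)
    stop("need reference localities for both species")
  in_nest <- panel$locality_code %in% nest
  in_ophr <- panel$locality_code %in% ophr
  keep <- vapply(panel$marker_id, function(m) {
    gn <- panel$dosage[in_nest, m]; go <- panel$dosage[in_ophr, m]
    all(gn[!is.na(gn)] == 0L) && all(go[!is.na(go)] == 2L)
  }, logical(1L))
  panel$marker_id[keep]
}
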