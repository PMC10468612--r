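# Small in-code fixtures shared across test files.

# Panel of 3 individuals x 2 markers with one missing call.
tiny_panel <- function() {
  g <- matrix(c(0L, 1L, 2L,
                NA, 0L, 2L), nrow = 3,
              dimnames = list(c("a", "b", "c"), c("m1", "m2")))
  genotype_panel(g, locality_code = c("L1", "L1", "L2"))
}

# Panel with pure reference localities on both sides and a contact locality.
reference_panel <- function(L = 6L, n = 8L, seed = 11L) {
  set.seed(seed)
  mk <- sprintf("m%02d", seq_len(L))
  g <- rbind(
    matrix(0L, n, L), # pure nesterovi
    matrix(2L, n, L), # pure ophryticus
    matrix(sample(0:2, n * L, replace = TRUE), n, L))
  dimnames(g) <- list(sprintf("i%02d", seq_len(3L * n)), mk)
  genotype_panel(g, locality_code = rep(c("N", "O", "C"), each = n))
}

# Independent enumeration oracle for the conditional HWE distribution:
# counts genotype assignments with integer combinatorics (choose()), not
# the lgamma route the package uses.
hwe_oracle_p <- function(n_AA, n_Aa, n_aa, alternative) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2L * n_AA + n_Aa
  hs <- seq.int(nA %% 2L, min(nA, 2L * n - nA), by = 2L)
  weight <- vapply(hs, function(h) {
    aa <- (nA - h) / 2
    choose(n, aa) * choose(n - aa, h) * 2^h
  }, numeric(1L))
  p <- weight / sum(weight)
  if (alternative == "deficit") sum(p[hs <= n_Aa]) else sum(p[hs >= n_Aa])
}

# Straight-line synthetic map: localities on a lon gradient with HI linear
# in longitude, crossing 0.5 at lon = mid.
gradient_localities <- function(nx = 5L, ny = 5L,
                                lon = seq(36, 38, length.out = nx),
                                lat = seq(40.9, 41.3, length.out = ny)) {
  gr <- expand.grid(longitude = lon, latitude = lat)
  hi <- (gr$longitude - min(lon)) / diff(range(lon))
  locality_frame(data.frame(
    code = sprintf("G%02d", seq_len(nrow(gr))),
    latitude = gr$latitude, longitude = gr$longitude,
    species = ifelse(hi < 0.5, "nesterovi", "ophryticus"),
    n_kasp = 10L, hybrid_index = hi, n_mtdna = 3L,
    mtdna_freq = round(hi)))
}
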