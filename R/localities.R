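#' Locality summary frame
#'
#' Validates a per-locality summary table: WGS84 decimal-degree coordinates,
#' a species label, KASP sample size, pooled hybrid index, mtDNA sample size
#' and frequency of the *ophryticus* mtDNA haplogroup.
#'
#' @param df data frame with columns `code`, `latitude`, `longitude`,
#'   `species` (one of `nesterovi`, `ophryticus`, `admixed`), `n_kasp`,
#'   `hybrid_index`, `n_mtdna`, `mtdna_freq`. Extra columns are kept.
#' @return `df` with class `locality_frame` prepended.
#' @export
locality_frame <- function(df) {
  need <- c("code", "latitude", "longitude", "species", "n_kasp",
            "hybrid_index", "n_mtdna", "mtdna_freq")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing locality columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$code)) stop("duplicate locality code")
  chk <- function(v, lo, hi, what) {
    bad <- which(!is.na(v) & (v < lo | v > hi))
    if (length(bad))
      stop(sprintf("%s out of range [%g, %g] at locality '%s' (value %g)",
                   what, lo, hi, df$code[bad[1L]], v[bad[1L]]))
  }
  chk(df$latitude, -90, 90, "latitude")
  chk(df$longitude, -180, 180, "longitude")
  chk(df$hybrid_index, 0, 1, "hybrid_index")
  chk(df$mtdna_freq, 0, 1, "mtdna_freq")
  chk(df$n_kasp, 0, Inf, "n_kasp")
  chk(df$n_mtdna, 0, Inf, "n_mtdna")
  sp <- c("nesterovi", "ophryticus", "admixed")
  if (!all(df$species %in% sp))
    stop("species label must be one of: ", paste(sp, collapse = ", "))
  class(df) <- c("locality_frame", class(df))
  df
}

#' Read a locality table from delimited text
#'
#' @param path CSV/TSV path with the columns described in [locality_frame()].
#' @return a [locality_frame()].
#' @export
read_locality_table <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  locality_frame(read.csv(path, sep = sep, check.names = FALSE))
}

#' Sampled banded newt populations (packaged fixture)
#'
#' The published locality summaries for the *Ommatotriton nesterovi* /
#' *O. ophryticus* contact-zone survey: 42 localities across the natural
#' range in Turkiye and Georgia plus one introduced, admixed population in
#' Spain. Columns: locality code, coordinates, species assignment, number of
#' KASP-genotyped individuals, pooled nuclear hybrid index (proportion of
#' *ophryticus* alleles over 31 diagnostic SNPs), mtDNA sample size and
#' *ophryticus* mtDNA frequency.
#'
#' @param natural_only drop the introduced Spanish population (default keeps
#'   all 43 rows).
#' @return a [locality_frame()] with 43 (or 42) rows.
#' @examples
#' loc <- ommatotriton_localities()
#' sum(loc$n_kasp) # 523 genotyped individuals
#' @export
ommatotriton_localities <- function(natural_only = FALSE) {
  path <- system.file("extdata", "ommatotriton_localities.csv",
                      package = "hzclines", mustWork = TRUE)
  df <- locality_frame(read.csv(path, check.names = FALSE,
                                colClasses = c(code = "character")))
  if (natural_only) df <- df[df$code != "I", , drop = FALSE]
  df
}

#' Per-individual mtDNA species calls
#'
#' Haplotype-to-species assignment is taken as given input (e.g. from a CO1
#' phylogeny); this container only validates it against a panel.
#'
#' @param individual_id character vector.
#' @param species_call `"nesterovi"` or `"ophryticus"` per individual.
#' @param panel optional [genotype_panel()]; if given, every call must
#'   belong to a panel individual.
#' @return data frame of class `mtdna_calls`.
#' @export
mtdna_calls <- function(individual_id, species_call, panel = NULL) {
  if (length(individual_id) != length(species_call))
    stop("id and call vectors must have equal length")
  if (!all(species_call %in% c("nesterovi", "ophryticus")))
    stop("species_call must be 'nesterovi' or 'ophryticus'")
  if (!is.null(panel)) {
    orphan <- setdiff(individual_id, panel$individual_id)
    if (length(orphan))
      stop("mtDNA call for unknown individual: ", orphan[1L])
  }
  structure(data.frame(individual_id = individual_id,
                       species_call = species_call),
            class = c("mtdna_calls", "data.frame"))
}

#' Species occurrence records
#'
#' @param species character vector of species labels.
#' @param latitude,longitude WGS84 decimal degrees.
#' @return data frame of class `occurrence_set`.
#' @export
occurrence_set <- function(species, latitude, longitude) {
  if (any(abs(latitude) > 90) || any(abs(longitude) > 180))
    stop("invalid coordinates")
  if (length(unique(species)) < 1L || any(table(species) < 1L))
    stop("need at least one record per species")
  structure(data.frame(species = species, latitude = latitude,
                       longitude = longitude),
            class = c("occurrence_set", "data.frame"))
}
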