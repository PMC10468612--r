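#' Genotype panel of species-diagnostic SNP dosages
#'
#' A `genotype_panel` holds per-individual genotypes at L diagnostic markers,
#' coded as the dosage (0, 1 or 2) of one focal species' allele; here the
#' convention is that dosage counts *O. ophryticus* alleles, so a hybrid
#' index of 1 means pure *ophryticus*. Missing genotypes are `NA`.
#'
#' @param dosage integer matrix, individuals x markers, values 0/1/2 or `NA`.
#'   Row names are individual ids, column names marker ids.
#' @param locality_code character vector, one locality per individual.
#' @param life_stage optional character vector per individual, one of
#'   `"pre_metamorphic"`, `"post_metamorphic"`, `"unknown"` (default).
#' @return an object of class `genotype_panel`: a list with elements
#'   `dosage`, `individual_id`, `locality_code`, `marker_id`, `life_stage`.
#' @examples
#' g <- matrix(c(0L, 1L, 2L, NA, 0L, 2L), nrow = 3,
#'             dimnames = list(c("a", "b", "c"), c("m1", "m2")))
#' genotype_panel(g, locality_code = c("L1", "L1", "L2"))
#' @export
genotype_panel <- function(dosage, locality_code,
                           life_stage = NULL) {
  if (!is.matrix(dosage)) stop("'dosage' must be a matrix")
  if ((nrow(dosage) > 0L && is.null(rownames(dosage))) || is.null(colnames(dosage)))
    stop("'dosage' needs individual row names and marker column names")
  if (is.null(rownames(dosage))) rownames(dosage) <- character(0)
  storage.mode(dosage) <- "integer"
  bad <- !(dosage %in% c(0L, 1L, 2L, NA))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("invalid dosage %s for individual '%s', marker '%s' (must be 0/1/2/NA)",
                 dosage[idx[1L], idx[2L]],
                 rownames(dosage)[idx[1L]], colnames(dosage)[idx[2L]]))
  }
  if (anyDuplicated(rownames(dosage)))
    stop("duplicate individual id: ",
         rownames(dosage)[anyDuplicated(rownames(dosage))])
  if (anyDuplicated(colnames(dosage)))
    stop("duplicate marker id: ",
         colnames(dosage)[anyDuplicated(colnames(dosage))])
  if (ncol(dosage) < 1L) stop("need at least one marker")
  if (length(locality_code) != nrow(dosage))
    stop("'locality_code' must have one entry per individual")
  if (is.null(life_stage)) life_stage <- rep("unknown", nrow(dosage))
  if (length(life_stage) == 1L) life_stage <- rep(life_stage, nrow(dosage))
  stages <- c("unknown", "pre_metamorphic", "post_metamorphic")
  if (!all(life_stage %in% stages))
    stop("life_stage values must be one of: ", paste(stages, collapse = ", "))
  if (length(life_stage) != nrow(dosage))
    stop("'life_stage' must have one entry per individual")
  structure(list(dosage = dosage,
                 individual_id = rownames(dosage),
                 locality_code = as.character(locality_code),
                 marker_id = colnames(dosage),
                 life_stage = life_stage),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("<genotype_panel> %d individuals x %d markers, %d localities, %d missing calls\n",
              nrow(x$dosage), ncol(x$dosage),
              length(unique(x$locality_code)), sum(is.na(x$dosage))))
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$dosage)

#' Subset a genotype panel by individuals and/or markers
#'
#' @param x a [genotype_panel()].
#' @param individuals,markers character or logical/integer index vectors;
#'   `NULL` keeps all.
#' @return a `genotype_panel`.
#' @export
subset_panel <- function(x, individuals = NULL, markers = NULL) {
  stopifnot(inherits(x, "genotype_panel"))
  i <- if (is.null(individuals)) seq_len(nrow(x$dosage)) else individuals
  if (is.character(i)) i <- match(i, x$individual_id)
  j <- if (is.null(markers)) seq_len(ncol(x$dosage)) else markers
  if (is.character(j)) j <- match(j, x$marker_id)
  genotype_panel(x$dosage[i, j, drop = FALSE],
                 locality_code = x$locality_code[i],
                 life_stage = x$life_stage[i])
}

#' Read a genotype table from delimited text
#'
#' Expects columns `individual`, `locality`, optionally `life_stage`, and one
#' column per marker containing 0/1/2 or empty/NA. Comma or tab delimited
#' (sniffed from the header line).
#'
#' @param path file path.
#' @return a [genotype_panel()].
#' @export
read_genotype_table <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- read.csv(path, sep = sep, check.names = FALSE,
                 colClasses = "character", na.strings = c("NA", ""))
  need <- c("individual", "locality")
  if (!all(need %in% names(df)))
    stop("genotype table must have 'individual' and 'locality' columns")
  ls_col <- if ("life_stage" %in% names(df)) df$life_stage else NULL
  marker_cols <- setdiff(names(df), c("individual", "locality", "life_stage"))
  if (length(marker_cols) < 1L) stop("no marker columns found")
  if (anyDuplicated(df$individual))
    stop("duplicate individual id: ", df$individual[anyDuplicated(df$individual)])
  g <- matrix(NA_integer_, nrow(df), length(marker_cols),
              dimnames = list(df$individual, marker_cols))
  for (m in marker_cols) {
    v <- df[[m]]
    ok <- is.na(v) | v %in% c("0", "1", "2")
    if (!all(ok)) {
      r <- which(!ok)[1L]
      stop(sprintf("non-integer or out-of-range dosage '%s' at row %d (individual '%s'), column '%s'",
                   v[r], r, df$individual[r], m))
    }
    g[, m] <- as.integer(v)
  }
  panel <- genotype_panel(g, locality_code = df$locality,
                          life_stage = ls_col %||% rep("unknown", nrow(df)))
  message(sprintf("read %d individuals x %d markers (%d missing calls)",
                  nrow(g), ncol(g), sum(is.na(g))))
  panel
}

#' Write a genotype panel back to delimited text
#'
#' Inverse of [read_genotype_table()]; a write-read round trip reproduces the
#' panel exactly.
#'
#' @param panel a [genotype_panel()].
#' @param path output file path (`.csv` comma-separated).
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(panel, path) {
  stopifnot(inherits(panel, "genotype_panel"))
  df <- data.frame(individual = panel$individual_id,
                   locality = panel$locality_code,
                   life_stage = panel$life_stage,
                   check.names = FALSE)
  df <- cbind(df, as.data.frame(panel$dosage, check.names = FALSE))
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Export a genotype panel in Genepop format
#'
#' Writes the standard Genepop file: a title line, one marker name per line,
#' then one `Pop` block per locality with two-digit-per-allele diploid codes.
#' Allele 1 is the *nesterovi* allele and allele 2 the *ophryticus* allele,
#' so dosage 0 becomes `0101`, 1 becomes `0102`, 2 becomes `0202`; missing is
#' `0000`.
#'
#' @param panel a [genotype_panel()].
#' @param path output file path.
#' @param title title line content.
#' @return `path`, invisibly.
#' @export
export_genepop <- function(panel, path, title = "hzclines export") {
  stopifnot(inherits(panel, "genotype_panel"))
  if (nrow(panel$dosage) == 0L) stop("panel is empty")
  code <- c("0101", "0102", "0202")
  lines <- c(title, panel$marker_id)
  for (loc in unique(panel$locality_code)) {
    lines <- c(lines, "Pop")
    idx <- which(panel$locality_code == loc)
    for (i in idx) {
      g <- panel$dosage[i, ]
      gc <- ifelse(is.na(g), "0000", code[g + 1L])
      lines <- c(lines, paste0(loc, "_", panel$individual_id[i], " ,  ",
                               paste(gc, collapse = " ")))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Parse a Genepop file written by [export_genepop()]
#'
#' Minimal reader used to verify the export round-trips; recovers dosages
#' from the two-digit allele codes.
#'
#' @param path Genepop file path.
#' @return a [genotype_panel()].
#' @export
read_genepop <- function(path) {
  lines <- readLines(path)
  pop_at <- which(trimws(tolower(lines)) == "pop")
  if (length(pop_at) == 0L) stop("no 'Pop' line found: not a Genepop file")
  markers <- trimws(lines[2:(pop_at[1L] - 1L)])
  rows <- list(); locs <- character(); ids <- character()
  blocks <- c(pop_at, length(lines) + 1L)
  for (b in seq_along(pop_at)) {
    for (li in seq(blocks[b] + 1L, blocks[b + 1L] - 1L)) {
      if (li > length(lines) || !nzchar(trimws(lines[li]))) next
      parts <- strsplit(lines[li], ",")[[1L]]
      label <- trimws(parts[1L])
      codes <- strsplit(trimws(parts[2L]), "[[:space:]]+")[[1L]]
      dos <- vapply(codes, function(cc) {
        if (cc == "0000") return(NA_integer_)
        a <- c(substr(cc, 1, 2), substr(cc, 3, 4))
        sum(a == "02")
      }, integer(1L))
      ids <- c(ids, sub("^[^_]*_", "", label))
      locs <- c(locs, sub("_.*$", "", label))
      rows[[length(rows) + 1L]] <- dos
    }
  }
  g <- do.call(rbind, rows)
  dimnames(g) <- list(ids, markers)
  genotype_panel(g, locality_code = locs)
}
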