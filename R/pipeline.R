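#' Pipeline configuration
#'
#' Collects every stage toggle and tuning parameter in one echoable list.
#' Seeds are mandatory for all stochastic stages.
#'
#' @param localities a [locality_frame()] (required).
#' @param panel optional [genotype_panel()]; when absent the pipeline runs
#'   in summary ("table") mode, reconstructing per-locality allele counts
#'   from the locality hybrid indices: `k_i = round(HI_i * 2 n_i)`,
#'   `n_i = 2 N_KASP_i` (mtDNA: `k_i = round(freq_i * N_mtDNA_i)`), and
#'   skipping individual-level stages (HWE, LD, triangle, D') with notices.
#' @param stages character vector from `c("qc", "hybrid_index", "transect",
#'   "cline", "tension", "triangle")`.
#' @param seed master seed; stage seeds are derived as small offsets.
#' @param alpha,min_sig_pops HWE screening settings ([screen_hwe()]).
#' @param resolution,level transect settings ([build_transect()]).
#' @param mcmc,chains,steps,burnin cline MCMC settings ([fit_cline()]).
#' @param r,generation_time,contact_age_years,sigma tension-zone settings;
#'   `sigma` (km/gen) substitutes for the LD-based estimate in summary mode,
#'   where individual genotypes to estimate D' from are unavailable.
#' @param out_dir optional directory: per-stage tables, the verbatim config
#'   and a JSON summary are written there.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(localities, panel = NULL,
                            stages = c("hybrid_index", "transect", "cline",
                                       "tension"),
                            seed = 1L, alpha = 0.05, min_sig_pops = 2L,
                            resolution = 0.01, level = 0.5,
                            mcmc = "best", chains = 3L, steps = 1e5L,
                            burnin = 0.1,
                            r = 0.5, generation_time = 5,
                            contact_age_years = 12000, sigma = NULL,
                            out_dir = NULL) {
  known <- c("qc", "hybrid_index", "transect", "cline", "tension", "triangle")
  if (length(stages) == 0L) stop("nothing to do: no stages enabled")
  if (!all(stages %in% known))
    stop("unknown stage: ", setdiff(stages, known)[1L])
  structure(as.list(environment())[
    c("localities", "panel", "stages", "seed", "alpha", "min_sig_pops",
      "resolution", "level", "mcmc", "chains", "steps", "burnin", "r",
      "generation_time", "contact_age_years", "sigma", "out_dir")],
    class = "pipeline_config")
}

#' Run the hybrid-zone analysis pipeline
#'
#' Executes the enabled stages in order: marker QC, hybrid indices,
#' isoline transect, cline fitting with AICc model selection (hybrid index
#' and mtDNA), and the tension-zone estimator chain. With only locality
#' summaries available (no genotype panel) the pipeline runs in summary
#' mode (see [pipeline_config()]). Missing upstream requirements for an
#' enabled stage raise an error before any computation.
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_result` with one element per executed
#'   stage plus `notices` and the echoed `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  st <- config$stages
  table_mode <- is.null(config$panel)
  # validate stage prerequisites up front
  if (table_mode && any(st %in% c("qc", "triangle")))
    stop("stages qc/triangle need a genotype panel; none supplied")
  if ("cline" %in% st && !("transect" %in% st))
    stop("cline stage needs the transect stage enabled")
  if ("tension" %in% st && !("cline" %in% st))
    stop("tension stage needs the cline stage enabled")
  res <- list(notices = character())
  note <- function(msg) res$notices <<- c(res$notices, msg)
  if (table_mode)
    note("summary mode: no genotype panel; HWE, LD, triangle and D' skipped; allele counts reconstructed from locality hybrid indices")
  loc <- config$localities

  if ("qc" %in% st) {
    res$qc <- screen_hwe(config$panel, alpha = config$alpha,
                         min_sig_pops = config$min_sig_pops)
    if (any(res$qc$excluded)) {
      keep <- setdiff(config$panel$marker_id,
                      res$qc$marker_id[res$qc$excluded])
      note(paste("excluded markers:",
                 paste(res$qc$marker_id[res$qc$excluded], collapse = ", ")))
      config$panel <- subset_panel(config$panel, markers = keep)
    }
  }
  if ("hybrid_index" %in% st) {
    if (table_mode) {
      res$hybrid_index <- data.frame(locality_code = loc$code,
                                     hybrid_index = loc$hybrid_index,
                                     n_called_alleles = 2L * loc$n_kasp)
    } else {
      res$hybrid_index <- locality_hybrid_index(config$panel)
      res$individual_hi <- individual_hybrid_index(config$panel)
      loc$hybrid_index <- res$hybrid_index$hybrid_index[
        match(loc$code, res$hybrid_index$locality_code)]
    }
  }
  if ("transect" %in% st) {
    res$transect <- build_transect(loc, resolution = config$resolution,
                                   level = config$level)
  }
  if ("cline" %in% st) {
    x <- res$transect$distances$distance_km
    if (table_mode) {
      n_al <- 2L * loc$n_kasp
      k <- round(loc$hybrid_index * n_al)
    } else {
      lhi <- res$hybrid_index[match(loc$code, res$hybrid_index$locality_code), ]
      n_al <- lhi$n_called_alleles
      k <- round(lhi$hybrid_index * n_al)
    }
    ok <- n_al > 0 & !is.na(x)
    res$cline_hi <- model_select(x[ok], k[ok], n_al[ok], seed = config$seed,
                                 mcmc = config$mcmc, chains = config$chains,
                                 steps = config$steps, burnin = config$burnin)
    if (!is.null(loc$n_mtdna) && any(loc$n_mtdna > 0)) {
      mk <- round(loc$mtdna_freq * loc$n_mtdna)
      mok <- loc$n_mtdna > 0 & !is.na(x)
      res$cline_mtdna <- model_select(x[mok], mk[mok], loc$n_mtdna[mok],
                                      seed = config$seed + 50L,
                                      mcmc = config$mcmc,
                                      chains = config$chains,
                                      steps = config$steps,
                                      burnin = config$burnin)
    }
  }
  if ("tension" %in% st) {
    fit <- res$cline_hi$best
    T_gen <- config$contact_age_years / config$generation_time
    if (table_mode) {
      if (is.null(config$sigma))
        stop("tension stage in summary mode needs config$sigma")
      note("summary mode: sigma supplied by config, not estimated from LD")
      s <- config$sigma
      res$tension <- list(
        sigma = s, T_gen = T_gen,
        w_neutral = neutral_width(s, T_gen),
        s_star_hybrid_index = as.numeric(effective_selection(s, fit$model$width)),
        generations_to_cross = generations_to_cross(fit$model$width, s))
    } else {
      res$tension <- dispersal_pipeline(
        config$panel, res$transect$distances, fit, r = config$r,
        generation_time = config$generation_time,
        contact_age_years = config$contact_age_years)
    }
  }
  if ("triangle" %in% st) res$triangle <- triangle_batch(config$panel)
  res$config <- config
  class(res) <- "pipeline_result"
  if (!is.null(config$out_dir)) write_pipeline_outputs(res, config$out_dir)
  res
}

# Per-stage tables + JSON summary + verbatim config echo.
write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- res$config
  cfg$localities <- NULL; cfg$panel <- NULL
  jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  if (!is.null(res$hybrid_index))
    write.csv(res$hybrid_index, file.path(out_dir, "hybrid_index.csv"),
              row.names = FALSE)
  if (!is.null(res$transect))
    write.csv(res$transect$distances, file.path(out_dir, "transect.csv"),
              row.names = FALSE)
  summary <- list(notices = res$notices)
  for (nm in c("cline_hi", "cline_mtdna")) {
    if (is.null(res[[nm]])) next
    write.csv(res[[nm]]$table, file.path(out_dir, paste0(nm, "_models.csv")),
              row.names = FALSE)
    b <- res[[nm]]$best
    summary[[nm]] <- list(tails = b$tails, scaling = b$scaling,
                          center = b$model$center, width = b$model$width,
                          logL = b$logL, AICc = b$AICc,
                          support = b$support)
  }
  if (!is.null(res$tension))
    summary$tension <- res$tension[setdiff(names(res$tension), "inputs")]
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE,
                       digits = NA)
  invisible(out_dir)
}
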