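#' @name pipeline
#' @title End-to-end gap-filling pipeline
#' @description
#' Drives the full chain: (optional) 8-day compositing and conservative
#' regridding, Step I optimal interpolation, per-cell PDF fitting, Step
#' II Monte-Carlo multiple imputation, and ensemble bloom phenology.
#' Each stage logs the basin-mean percent of missing ocean pixels before
#' and after, and all randomness derives from a single master seed.
NULL

#' Default pipeline configuration
#'
#' Returns the full configuration list with defaults; any element can be
#' overridden via `...` or by loading a YAML file with [load_config()].
#'
#' Keys: `input_path` (netCDF to read; `NULL` simulates synthetic data
#' from `simulate`), `output_dir` (`NULL` = no files written),
#' `target_resolution_deg` (`NULL` = no regridding), `n_ensembles`
#' (ensemble size N, default 10000), `seed`, `threshold_factor` (5%
#' above the annual median = 1.05), `summer_months` (peak search window,
#' June-September), `phenology_year` / `phenology_cell` (`NULL` picks
#' the middle year and an interior ocean cell), `kde` (cross-validation
#' settings), `ensemble_storage` (`"lazy"`, `"single"` or
#' `"per_member"`), `write_members` (how many members to store when
#' writing), and `simulate` (synthetic truth and gap parameters).
#'
#' @param ... configuration overrides.
#' @return Named configuration list.
#' @export
default_config <- function(...) {
  cfg <- list(
    input_path = NULL,
    output_dir = NULL,
    target_resolution_deg = NULL,
    n_ensembles = 10000L,
    seed = 1L,
    threshold_factor = 1.05,
    summer_months = 6:9,
    phenology_year = NULL,
    phenology_cell = NULL,
    kde = list(n_folds = 5L, n_bandwidths = 20L),
    ensemble_storage = "lazy",
    write_members = 10L,
    simulate = list(summer_gap = 0.4, offseason_gap = 0.1,
                    persistence = 0.95, smooth_sd = 2.5))
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Load a YAML configuration file
#'
#' @param path YAML file; keys override [default_config()].
#' @return Configuration list.
#' @export
load_config <- function(path) {
  do.call(default_config, yaml::read_yaml(path))
}

pct_missing <- function(field) 100 * gap_fraction(field)$summary

#' Run the two-step gap-filling pipeline
#'
#' Executes composite -> regrid -> Step I -> Step II -> phenology on the
#' configured input (a netCDF file, or a seeded synthetic field when
#' `input_path` is `NULL`), logging the percent of missing ocean pixels
#' after every stage. Deterministic given `config$seed`.
#'
#' @param config list from [default_config()] / [load_config()].
#' @return List with `input` (the field the two-step algorithm saw),
#'   `step1` (Step-I output), `fits` (per-cell fit table and list),
#'   `ensembles` (`ensemble_set`), `gap_reports` (per stage),
#'   `phenology` (`phenology_summary`), and `truth` (the
#'   `synthetic_truth` when simulating, else `NULL`).
#' @export
run_pipeline <- function(config = default_config()) {
  cfg <- do.call(default_config, config)
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE))
  }

  truth <- NULL
  if (is.null(cfg$input_path)) {
    sim <- cfg$simulate
    truth <- run_stage("simulate",
      simulate_chl_field(do.call(synth_params, sim$params %||% list()),
                         seed = cfg$seed))
    field <- run_stage("simulate",
      apply_cloud_gaps(truth,
                       summer_gap = sim$summer_gap %||% 0.4,
                       offseason_gap = sim$offseason_gap %||% 0.1,
                       persistence = sim$persistence %||% 0.95,
                       smooth_sd = sim$smooth_sd %||% 2.5,
                       seed = substream_seed(cfg$seed, 7L)))
  } else {
    field <- run_stage("read", read_chl_nc(cfg$input_path))
  }
  reports <- list(input = gap_fraction(field))

  daily <- length(field$time) > 1 && all(diff(as.numeric(field$time)) == 1)
  if (daily) {
    before <- pct_missing(field)
    field <- run_stage("composite", compose_8day(field))
    reports$composite <- gap_fraction(field)
    stage_log("composite_8day", before, 100 * reports$composite$summary)
  }
  if (!is.null(cfg$target_resolution_deg)) {
    before <- pct_missing(field)
    field <- run_stage("regrid",
                       regrid_conservative(field, cfg$target_resolution_deg))
    reports$regrid <- gap_fraction(field)
    stage_log("regrid_conservative", before, 100 * reports$regrid$summary)
  }
  input_field <- field

  before <- pct_missing(field)
  step1 <- run_stage("step1_interpolation", optimal_interpolate(field))
  reports$step1 <- gap_fraction(step1)
  stage_log("step1_interpolation", before, 100 * reports$step1$summary)

  fits <- run_stage("distribution_fitting",
                    fit_field(step1, fold_seed = substream_seed(cfg$seed, 11L)))
  ens <- run_stage("step2_monte_carlo",
    generate_ensembles(step1, fits$fits,
                       n_members = cfg$n_ensembles,
                       seed = substream_seed(cfg$seed, 13L),
                       materialize = identical(cfg$ensemble_storage,
                                               "materialize")))
  reports$step2 <- gap_fraction(ensemble_member(ens, 1L))
  stage_log("step2_monte_carlo", 100 * reports$step1$summary,
            100 * reports$step2$summary)

  phen <- run_stage("phenology", {
    yrs <- as.integer(unique(format(step1$time, "%Y")))
    year <- cfg$phenology_year %||% yrs[ceiling(length(yrs) / 2)]
    cell <- cfg$phenology_cell %||% {
      oc <- which(!step1$land, arr.ind = TRUE)
      ctr <- colMeans(oc)
      oc[which.min((oc[, 1] - ctr[1])^2 + (oc[, 2] - ctr[2])^2), ]
    }
    ensemble_phenology(ens, year, cell = as.integer(cell),
                       threshold_factor = cfg$threshold_factor,
                       summer_months = cfg$summer_months)
  })

  if (!is.null(cfg$output_dir)) run_stage("write_outputs", {
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    out <- function(f) file.path(cfg$output_dir, f)
    write_chl_nc(step1, out("step1_filled.nc"))
    write_summary_nc(ensemble_summary(ens), step1, out("ensemble_summary.nc"))
    if (identical(cfg$ensemble_storage, "per_member")) {
      write_ensemble_nc(ens, out("members"),
                        members = seq_len(min(cfg$write_members,
                                              ens$n_members)),
                        mode = "per_member")
    } else if (!identical(cfg$ensemble_storage, "lazy")) {
      write_ensemble_nc(ens, out("ensemble.nc"),
                        members = seq_len(min(cfg$write_members,
                                              ens$n_members)))
    }
    for (nm in names(reports))
      write_gap_report(reports[[nm]], out(sprintf("gaps_%s.csv", nm)),
                       out(sprintf("gaps_%s.json", nm)))
    utils::write.csv(fits$table, out("cell_fits.csv"), row.names = FALSE)
    write_phenology_csv(phen, out("phenology_members.csv"),
                        out("phenology_summary.csv"))
  })

  list(input = input_field, step1 = step1, fits = fits, ensembles = ens,
       gap_reports = reports, phenology = phen, truth = truth)
}
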