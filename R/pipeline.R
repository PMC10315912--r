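#' Run configuration for the end-to-end pipeline
#'
#' @param output_dir directory for result files (created if absent)
#' @param targets_csv path of the calibration-targets CSV (written by
#'   [generate_targets_file()], read back by [run_pipeline()]); NULL to
#'   generate in memory
#' @param scenario_yaml scenario-library YAML file (default: the packaged
#'   library)
#' @param horizon `c(start, end)` calendar years
#' @param baseline a [baseline_config()]
#' @param fit a [fit_spec()]
#' @param sim_control solver control for scenario runs
#' @param seed integer seed forwarded to the generator and the fit
#' @return object of class `run_config`
#' @export
run_config <- function(output_dir = "results",
                       targets_csv = NULL,
                       scenario_yaml = NULL,
                       horizon = c(2021, 2050),
                       baseline = baseline_config(),
                       fit = fit_spec(),
                       sim_control = list(),
                       seed = 1L) {
  if (horizon[1] < 1900 || horizon[2] > 2200 || horizon[1] >= horizon[2])
    stop_field("horizon", "must be an increasing pair within [1900, 2200]")
  structure(list(output_dir = output_dir, targets_csv = targets_csv,
                 scenario_yaml = scenario_yaml, horizon = horizon,
                 baseline = baseline, fit = fit,
                 sim_control = sim_control, seed = as.integer(seed)),
            class = "run_config")
}

#' Generate the synthetic targets and write them to CSV
#'
#' @param config a [run_config()]
#' @return the path written, invisibly
#' @export
generate_targets_file <- function(config = run_config()) {
  cfg <- config$baseline
  cfg$seed <- config$seed
  targets <- generate_baseline(cfg)
  path <- config$targets_csv %||% file.path(config$output_dir, "targets.csv")
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  write_targets(targets, path)
  invisible(path)
}

#' Calibrate the model for a run configuration
#'
#' Reads the targets CSV if present, otherwise generates the synthetic
#' baseline in memory, and fits the free parameters.
#'
#' @param config a [run_config()]
#' @return list with `targets` and the `fit_result`
#' @export
calibrate_pipeline <- function(config = run_config()) {
  targets <- if (!is.null(config$targets_csv) && file.exists(config$targets_csv))
    read_targets(config$targets_csv)
  else {
    cfg <- config$baseline
    cfg$seed <- config$seed
    generate_baseline(cfg)
  }
  spec <- config$fit
  spec$seed <- config$seed
  list(targets = targets, fit = fit_parameters(targets, spec))
}

#' Write / read natural-history parameters as JSON
#'
#' Plain-text serialization of an `nh_params` so a calibration can be
#' reused across analysis scripts.
#'
#' @param params `nh_params`
#' @param path JSON file path
#' @return `write_params` returns `path` invisibly; `read_params` returns
#'   the reconstructed `nh_params`
#' @export
write_params <- function(params, path) {
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$lambda_a <- unlist(raw$lambda_a)
  raw$lambda_b <- unlist(raw$lambda_b)
  raw$lambda_c <- unlist(raw$lambda_c)
  do.call(natural_history_params, raw)
}

#' Run scenarios end to end and write result files
#'
#' Auto-calibrates (or reuses a supplied calibration), runs the requested
#' scenarios and packages, and writes one year-indexed CSV plus one JSON
#' summary (2050 values) per scenario, and a combined summary table of the
#' 2050 outcome set across scenarios.
#'
#' @param scenarios character vector of scenario/package ids, or `"all"`
#'   for the twelve scenarios plus both packages
#' @param config a [run_config()]
#' @param calibration optional result of [calibrate_pipeline()] to reuse
#' @return named list of `scenario_result`, invisibly; the combined summary
#'   is attached as attribute `summary`
#' @export
run_pipeline <- function(scenarios = "all", config = run_config(),
                         calibration = NULL) {
  lib <- if (is.null(config$scenario_yaml)) scenario_library()
         else scenario_library(config$scenario_yaml)
  ids <- if (identical(scenarios, "all"))
    c(names(lib), names(attr(lib, "packages")))
  else scenarios
  cal <- calibration %||% calibrate_pipeline(config)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  summary_rows <- list()
  for (id in ids) {
    res <- run_scenario(id, cal$fit$params, cal$targets, lib,
                        horizon = config$horizon,
                        control = config$sim_control)
    results[[id]] <- res
    write.csv(as.data.frame(res),
              file.path(config$output_dir, paste0(id, ".csv")),
              row.names = FALSE)
    f <- res[nrow(res), ]
    summ <- list(
      scenario = id,
      year = f$year,
      prevalence_baseline_pct = 100 * f$prevalence_baseline,
      prevalence_intervention_pct = 100 * f$prevalence_intervention,
      prevalence_reduction_pp = f$prevalence_reduction_pp,
      new_cases_reduction_pct = 100 *
        (1 - f$new_cases_intervention / f$new_cases_baseline),
      cum_averted = f$cum_averted,
      prop_averted_pct = 100 * f$prop_averted)
    jsonlite::write_json(summ,
                         file.path(config$output_dir, paste0(id, ".json")),
                         auto_unbox = TRUE, digits = NA)
    summary_rows[[id]] <- as.data.frame(summ, stringsAsFactors = FALSE)
  }
  summary <- do.call(rbind, summary_rows)
  rownames(summary) <- NULL
  write.csv(summary, file.path(config$output_dir, "summary.csv"),
            row.names = FALSE)
  attr(results, "summary") <- summary
  invisible(results)
}
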