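#' Generate synthetic calibration targets
#'
#' Builds a self-consistent, Qatar-like baseline dataset — population counts
#' and prevalence surfaces of T2DM, obesity, physical inactivity and smoking
#' by sex, 3-year age band and calendar year — that reproduces the aggregate
#' anchors in the configuration exactly. It stands in for the national
#' calibration data the model was originally fitted to, which are not
#' machine-readable here.
#'
#' Construction: the start-year cross-section comes from
#' [consistent_structure()] (a young exponential pyramid; a monotone-in-age
#' T2DM profile whose level matches the start-year anchors exactly; the
#' configured risk-factor marginals). [solve_baseline_params()] then finds
#' the natural-history parameters whose no-intervention model run from that
#' cross-section reproduces the remaining anchors (end-year prevalence and
#' population, first/last-year and cumulative new cases, the obesity
#' anchor), and the emitted surfaces are that run's annual snapshots. The
#' targets are therefore literally a model trajectory — "shape from the
#' model, scale from the published anchors".
#'
#' @param config a [baseline_config()]
#' @return a `calibration_targets` data frame with columns
#'   `sex, age_band, year, population, t2dm_prev, obesity_prev,
#'   inactivity_prev, smoking_prev` (one row per sex x band x year); the
#'   generating parameters are attached as attribute `true_params`
#' @export
generate_baseline <- function(config = baseline_config()) {
  validate_baseline_config(config)
  key <- paste(vapply(config, function(v) paste(format(v, digits = 15),
                                                collapse = ","), ""),
               collapse = "|")
  cached <- .generator_cache[[key]]
  if (!is.null(cached)) return(cached)
  sol <- solve_baseline_params(config)
  out <- trajectory_targets(sol$trajectory,
                            years = config$start_year:config$end_year)
  if (config$noise_sd > 0) {
    set.seed(config$seed)
    jitter <- function(x) clip01(x * exp(stats::rnorm(length(x), 0, config$noise_sd)))
    for (col in c("t2dm_prev", "obesity_prev", "inactivity_prev", "smoking_prev"))
      out[[col]] <- jitter(out[[col]])
  }
  out <- out[order(out$year, out$sex, out$age_band), ]
  rownames(out) <- NULL
  class(out) <- c("calibration_targets", "data.frame")
  attr(out, "config") <- config
  attr(out, "true_params") <- sol$params
  validate_targets(out)
  .generator_cache[[key]] <- out
  out
}

# memoisation of the anchor solve (deterministic in the configuration)
.generator_cache <- new.env(parent = emptyenv())

TARGET_COLUMNS <- c("sex", "age_band", "year", "population", "t2dm_prev",
                    "obesity_prev", "inactivity_prev", "smoking_prev")

validate_targets <- function(targets) {
  missing <- setdiff(TARGET_COLUMNS, names(targets))
  if (length(missing))
    stop(sprintf("targets table is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  for (col in setdiff(TARGET_COLUMNS, "sex")) {
    bad <- which(!is.finite(targets[[col]]))
    if (length(bad))
      stop(sprintf("non-numeric or missing value in column '%s', row %d",
                   col, bad[1]), call. = FALSE)
  }
  prev_cols <- grep("_prev$", TARGET_COLUMNS, value = TRUE)
  for (col in prev_cols)
    if (any(targets[[col]] < 0 | targets[[col]] > 1))
      stop(sprintf("column '%s' outside [0, 1]", col), call. = FALSE)
  if (any(targets$population < 0)) stop("negative population count", call. = FALSE)
  cnt <- table(targets$year)
  if (length(unique(cnt)) != 1L || unique(cnt) != 2L * N_BANDS)
    stop("every (sex, age_band) pair must be present for every year", call. = FALSE)
  invisible(targets)
}

#' Aggregate a targets table over sex and age
#'
#' @param targets a `calibration_targets` data frame
#' @return data frame per year with total population and population-weighted
#'   aggregate prevalences
#' @export
aggregate_targets <- function(targets) {
  sp <- split(targets, targets$year)
  out <- do.call(rbind, lapply(sp, function(d) {
    w <- d$population
    data.frame(year = d$year[1],
               population = sum(w),
               t2dm_prev = sum(w * d$t2dm_prev) / sum(w),
               obesity_prev = sum(w * d$obesity_prev) / sum(w),
               inactivity_prev = sum(w * d$inactivity_prev) / sum(w),
               smoking_prev = sum(w * d$smoking_prev) / sum(w))
  }))
  rownames(out) <- NULL
  out
}

#' Write / read calibration targets as CSV
#'
#' Plain UTF-8 CSV with a single header row and '.' decimal separator;
#' the round trip is lossless to full double precision (values are written
#' with 15 significant digits).
#'
#' @param targets a `calibration_targets` data frame
#' @param path file path
#' @return `write_targets` returns `path` invisibly; `read_targets` returns
#'   a validated `calibration_targets` data frame
#' @export
write_targets <- function(targets, path) {
  validate_targets(targets)
  out <- targets[, TARGET_COLUMNS]
  for (col in c("population", "t2dm_prev", "obesity_prev",
                "inactivity_prev", "smoking_prev"))
    out[[col]] <- formatC(out[[col]], format = "g", digits = 15)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_targets
#' @export
read_targets <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (file.size(path) == 0) stop("empty targets file: ", path, call. = FALSE)
  raw <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                  error = function(e) stop("malformed targets CSV: ",
                                           conditionMessage(e), call. = FALSE))
  missing <- setdiff(TARGET_COLUMNS, names(raw))
  if (length(missing))
    stop(sprintf("targets CSV is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  for (col in setdiff(TARGET_COLUMNS, "sex")) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]))
    if (length(bad))
      stop(sprintf("non-numeric cell in column '%s', row %d", col, bad[1]),
           call. = FALSE)
    raw[[col]] <- v
  }
  raw$age_band <- as.integer(raw$age_band)
  raw$year <- as.integer(raw$year)
  class(raw) <- c("calibration_targets", "data.frame")
  validate_targets(raw)
  raw
}
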