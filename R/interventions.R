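#' Intervention scenario specification
#'
#' One intervention scenario: who is eligible, how coverage scales up, and
#' what the intervention does (a multiplicative reduction of the T2DM onset
#' hazard, a population- or covered-scope obesity-prevalence endpoint to be
#' reached by the end of scale-up, and/or normalization of physical
#' inactivity among the covered).
#'
#' @param id unique scenario identifier
#' @param uptake,adherence fractions in `[0, 1]`; effective coverage is
#'   their product
#' @param ramp_start,ramp_end calendar years of the linear scale-up window
#' @param horizon_end last maintained year (default 2050)
#' @param min_age,max_age eligible age range in years; converted to the
#'   3-year bands fully contained in the range
#' @param require_obese restrict eligibility to obese profiles
#' @param incidence_multiplier IRR/RR applied to the onset hazard of covered
#'   persons matching the filter, in `(0, 1]` (1 = no direct effect)
#' @param obesity_prev_target obesity prevalence (fraction) to reach by
#'   `ramp_end`, or NULL
#' @param obesity_scope `"total"` (whole population) or `"covered"`
#'   (covered subgroup) — where the obesity target is measured
#' @param normalize_inactivity move covered inactive persons to active over
#'   the scale-up window
#' @param bmi_shift_info assumed population BMI reduction (kg/m^2),
#'   informational only (endpoints, not BMI shifts, drive the simulation)
#' @param evidence_irr effect sizes the `incidence_multiplier` was derived
#'   from, informational
#' @param label human-readable description
#' @return object of class `intervention_spec`
#' @export
intervention_spec <- function(id, uptake, adherence,
                              ramp_start, ramp_end, horizon_end = 2050,
                              min_age = 20, max_age = 79,
                              require_obese = FALSE,
                              incidence_multiplier = 1,
                              obesity_prev_target = NULL,
                              obesity_scope = c("total", "covered"),
                              normalize_inactivity = FALSE,
                              bmi_shift_info = NA_real_,
                              evidence_irr = NULL,
                              label = id) {
  obesity_scope <- match.arg(obesity_scope)
  check_fraction(uptake, "uptake")
  check_fraction(adherence, "adherence")
  if (ramp_start >= ramp_end) stop_field("ramp_start", "must be before ramp_end")
  if (ramp_end > horizon_end) stop_field("ramp_end", "must be <= horizon_end")
  if (incidence_multiplier <= 0 || incidence_multiplier > 1)
    stop_field("incidence_multiplier", "must be in (0, 1]")
  if (!is.null(obesity_prev_target)) check_fraction(obesity_prev_target,
                                                    "obesity_prev_target")
  min_band <- band_at_or_above(min_age)
  if (is.na(min_band)) stop_field("min_age", "above the modeled range")
  ub <- band_lower() + BAND_WIDTH - 1
  max_band <- max(which(ub <= max_age), 0L)
  if (max_band < min_band) stop_field("max_age", "age window contains no band")
  sp <- list(id = id, label = label, uptake = uptake, adherence = adherence,
             ramp_start = ramp_start, ramp_end = ramp_end,
             horizon_end = horizon_end,
             filter = list(min_age = min_age, max_age = max_age,
                           min_band = min_band, max_band = max_band,
                           require_obese = isTRUE(require_obese)),
             incidence_multiplier = incidence_multiplier,
             obesity_prev_target = obesity_prev_target,
             obesity_scope = obesity_scope,
             normalize_inactivity = isTRUE(normalize_inactivity),
             bmi_shift_info = bmi_shift_info,
             evidence_irr = evidence_irr)
  class(sp) <- "intervention_spec"
  sp
}

#' @export
print.intervention_spec <- function(x, ...) {
  cat(sprintf("<intervention_spec> %s\n  coverage %.0f%% x %.0f%%, ramp %d-%d\n",
              x$id, 100 * x$uptake, 100 * x$adherence,
              x$ramp_start, x$ramp_end))
  if (x$incidence_multiplier < 1)
    cat(sprintf("  incidence multiplier %.2f\n", x$incidence_multiplier))
  if (!is.null(x$obesity_prev_target))
    cat(sprintf("  obesity target %.1f%% by %d (%s scope)\n",
                100 * x$obesity_prev_target, x$ramp_end, x$obesity_scope))
  invisible(x)
}

#' Effective coverage: uptake times adherence
#' @param spec `intervention_spec`
#' @return fraction
#' @export
effective_coverage <- function(spec) spec$uptake * spec$adherence

#' Coverage scale-up ramp
#'
#' Linear increase from 0 at `ramp_start` to the effective coverage at
#' `ramp_end`, held constant thereafter.
#'
#' @param t calendar year (vectorized)
#' @param spec `intervention_spec`
#' @return targeted covered fraction of the eligible population at `t`
#' @export
coverage_ramp <- function(t, spec) {
  effective_coverage(spec) *
    clip01((t - spec$ramp_start) / (spec$ramp_end - spec$ramp_start))
}

#' Recruitment rate tracking the coverage ramp
#'
#' Per-capita rate at which eligible uncovered persons are recruited so that
#' the covered fraction tracks [coverage_ramp()]: a feed-forward term equal
#' to the ramp slope plus a proportional correction that also offsets
#' dilution by new entrants during maintenance. The rate is zero before
#' `ramp_start` and zero whenever the covered fraction is at (or above) its
#' target — in particular after `ramp_end` once the target is held.
#'
#' @param t calendar year
#' @param spec `intervention_spec`
#' @param current_covered_fraction covered fraction of the eligible
#'   population in `[0, 1)`
#' @param gain proportional-correction gain (per year)
#' @return per-year rate applied to eligible uncovered persons
#' @export
recruitment_rate <- function(t, spec, current_covered_fraction, gain = 2) {
  f <- current_covered_fraction
  if (f >= 1) {
    warning("covered fraction at or above 1; recruitment suspended")
    return(0)
  }
  target <- coverage_ramp(t, spec)
  slope <- if (t >= spec$ramp_start && t < spec$ramp_end)
    effective_coverage(spec) / (spec$ramp_end - spec$ramp_start) else 0
  max(0, slope + gain * (target - f)) / max(1 - f, 1e-9)
}

#' Intervention effects acting on one compartment
#'
#' Composes the effects of the active scenarios for a compartment key:
#' incidence multipliers of all scenarios that cover the compartment and
#' whose target filter it matches compose multiplicatively; inactivity
#' normalization and obesity forcing are flagged where applicable.
#'
#' @param sex `"female"` or `"male"`
#' @param age_band band index 1-20
#' @param profile profile index 1-8 or named 0/1 vector
#' @param status `"susceptible"` or `"diabetic"`
#' @param specs list of `intervention_spec`
#' @param covered logical vector: which of `specs` cover the compartment
#' @return list with `incidence_multiplier`, `normalize_inactivity`,
#'   `obesity_forcing` (ids of scenarios whose obesity endpoint applies)
#' @export
apply_effects <- function(sex, age_band, profile, status, specs,
                          covered = rep(TRUE, length(specs))) {
  ids <- vapply(specs, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop("duplicate scenario id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  if (length(profile) == 1L) profile <- PROFILE_FLAGS[profile, ]
  mult <- 1
  norm <- FALSE
  forced <- character()
  for (i in seq_along(specs)) {
    if (!covered[i]) next
    sp <- specs[[i]]
    in_band <- age_band >= sp$filter$min_band && age_band <= sp$filter$max_band
    ok_prof <- !sp$filter$require_obese || profile[["obese"]] == 1
    if (!in_band || !ok_prof) next
    mult <- mult * sp$incidence_multiplier
    if (sp$normalize_inactivity) norm <- TRUE
    if (!is.null(sp$obesity_prev_target)) forced <- c(forced, sp$id)
  }
  list(incidence_multiplier = mult, normalize_inactivity = norm,
       obesity_forcing = forced)
}

spec_from_yaml <- function(node) {
  eff <- node$effects %||% list()
  intervention_spec(
    id = node$id,
    label = node$label %||% node$id,
    uptake = node$uptake, adherence = node$adherence,
    ramp_start = node$ramp[[1]], ramp_end = node$ramp[[2]],
    horizon_end = node$horizon_end %||% 2050,
    min_age = node$filter$min_age %||% 20,
    max_age = node$filter$max_age %||% 79,
    require_obese = node$filter$require_obese %||% FALSE,
    incidence_multiplier = eff$irr %||% 1,
    obesity_prev_target = eff$obesity_prev_target,
    obesity_scope = eff$scope %||% "total",
    normalize_inactivity = eff$normalize_inactivity %||% FALSE,
    bmi_shift_info = node$bmi_shift %||% NA_real_,
    evidence_irr = unlist(eff$evidence_irr)
  )
}

#' Load the packaged scenario library
#'
#' Reads the twelve intervention scenarios (five intervention approaches)
#' and the two combination packages shipped with the package, mirroring the
#' published study design: three lifestyle-management scenarios, two active
#' commuting scenarios, four dietary scenarios, three subsidy/legislation
#' scenarios, and the most/least optimistic packages.
#'
#' @param path YAML file (default: the packaged `table1_scenarios.yaml`)
#' @return named list of `intervention_spec` with a `packages` attribute
#'   mapping package names to scenario ids; class `scenario_library`
#' @export
scenario_library <- function(path = system.file("extdata",
                                                "table1_scenarios.yaml",
                                                package = "t2dmsim")) {
  doc <- yaml::read_yaml(path)
  specs <- lapply(doc$scenarios, spec_from_yaml)
  ids <- vapply(specs, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop("duplicate scenario id(s) in library", call. = FALSE)
  names(specs) <- ids
  for (pkg in doc$packages) {
    missing <- setdiff(unlist(pkg), ids)
    if (length(missing))
      stop("package references unknown scenario(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
  }
  structure(specs, packages = doc$packages, class = "scenario_library")
}

#' @export
print.scenario_library <- function(x, ...) {
  cat(sprintf("<scenario_library> %d scenarios, %d packages\n",
              length(x), length(attr(x, "packages"))))
  for (id in names(x)) cat("  -", id, "\n")
  invisible(x)
}

#' Combination intervention packages
#'
#' The most optimistic package combines the most impactful scenario of each
#' of the four intervention approaches; the least optimistic combines the
#' least impactful scenario of each.
#'
#' @param kind `"most_optimistic"` or `"least_optimistic"`
#' @param library a [scenario_library()]
#' @return list of four `intervention_spec`
#' @export
build_package <- function(kind = c("most_optimistic", "least_optimistic"),
                          library = scenario_library()) {
  kind <- match.arg(kind)
  ids <- attr(library, "packages")[[kind]]
  if (is.null(ids)) stop("unknown package kind: ", kind, call. = FALSE)
  unname(library[unlist(ids)])
}
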