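#' Counterfactual comparison of two trajectories
#'
#' Produces the four outcome series: prevalence under baseline and
#' intervention, annual new cases under both, cumulative averted cases
#' (sum of annual baseline-minus-intervention case differences from the
#' intervention start), and the proportion averted (cumulative averted
#' divided by cumulative baseline new cases over the same years). The
#' absolute prevalence reduction in percentage points and the relative
#' prevalence reduction are both reported.
#'
#' @param baseline,intervention `trajectory` objects over the same horizon
#'   from the same initial population
#' @return object of class `scenario_result`: a data frame per calendar
#'   year with columns `prevalence_baseline`, `prevalence_intervention`,
#'   `new_cases_baseline`, `new_cases_intervention`, `cum_averted`,
#'   `prop_averted`, `prevalence_reduction_pp`, `prevalence_reduction_rel`
#' @export
compare_trajectories <- function(baseline, intervention) {
  if (!identical(baseline$times, intervention$times))
    stop("trajectories have mismatched horizons", call. = FALSE)
  years <- utils::head(baseline$times, -1L)
  nb <- vapply(years, function(y) annual_new_cases(baseline, y), 0)
  ni <- vapply(years, function(y) annual_new_cases(intervention, y), 0)
  cum_b <- cumsum(nb)
  cum_av <- cumsum(nb - ni)
  pb <- vapply(years, function(y) prevalence(baseline, y), 0)
  pi_ <- vapply(years, function(y) prevalence(intervention, y), 0)
  out <- data.frame(
    year = years,
    prevalence_baseline = pb,
    prevalence_intervention = pi_,
    new_cases_baseline = nb,
    new_cases_intervention = ni,
    cum_averted = cum_av,
    prop_averted = ifelse(cum_b > 0, cum_av / cum_b, 0),
    prevalence_reduction_pp = 100 * (pb - pi_),
    prevalence_reduction_rel = ifelse(pb > 0, (pb - pi_) / pb, 0))
  class(out) <- c("scenario_result", "data.frame")
  out
}

#' @export
print.scenario_result <- function(x, ...) {
  f <- x[nrow(x), ]
  cat(sprintf("<scenario_result> %d-%d\n", min(x$year), max(x$year)))
  cat(sprintf("  %d: prevalence %.1f%% vs %.1f%% baseline (-%.1f pp)\n",
              f$year, 100 * f$prevalence_intervention,
              100 * f$prevalence_baseline, f$prevalence_reduction_pp))
  cat(sprintf("  cumulative averted %.0f cases (%.1f%% of baseline cases)\n",
              f$cum_averted, 100 * f$prop_averted))
  invisible(x)
}

resolve_scenarios <- function(scenario, library) {
  if (inherits(scenario, "intervention_spec")) return(list(scenario))
  if (is.list(scenario)) return(scenario)
  if (is.character(scenario) && length(scenario) == 1L) {
    pk <- attr(library, "packages")
    if (scenario %in% names(pk)) return(build_package(scenario, library))
    if (scenario %in% names(library)) return(list(library[[scenario]]))
    stop("unknown scenario '", scenario, "'; available: ",
         paste(c(names(library), names(pk)), collapse = ", "), call. = FALSE)
  }
  stop("scenario must be an id, a package name, a spec, or a list of specs",
       call. = FALSE)
}

#' Run one intervention scenario against its counterfactual
#'
#' Simulates the calibrated model twice over the horizon — without any
#' intervention (the counterfactual) and with the scenario's coverage,
#' incidence and obesity effects — and compares the trajectories. Obesity
#' endpoints, where stated, are first solved by [solve_obesity_forcing()].
#'
#' @param scenario a scenario id, a package name (`"most_optimistic"` /
#'   `"least_optimistic"`), an `intervention_spec`, or a list of specs
#' @param params calibrated `nh_params`
#' @param targets `calibration_targets` supplying the initial population
#' @param library a [scenario_library()]
#' @param horizon `c(start, end)` calendar years (default: the targets')
#' @param control solver control for [simulate_model()]
#' @return `scenario_result` with the solved forcing attached as attribute
#'   `forcing` and the scenario list as attribute `scenarios`
#' @export
run_scenario <- function(scenario, params, targets,
                         library = scenario_library(),
                         horizon = NULL, control = list()) {
  specs <- resolve_scenarios(scenario, library)
  horizon <- horizon %||% range(targets$year)
  t0 <- horizon[1]; t1 <- horizon[2] + 1
  base_state <- initial_state(targets, params)
  baseline <- simulate_model(base_state, params, t0 = t0, t1 = t1,
                             control = control)
  int_state <- initial_state(targets, params, n_scenarios = length(specs))
  forcing <- solve_obesity_forcing(specs, int_state, params, t0 = t0,
                                   control = control)
  intervention <- simulate_model(int_state, params, specs, t0 = t0, t1 = t1,
                                 forcing = forcing, control = control)
  res <- compare_trajectories(baseline, intervention)
  attr(res, "forcing") <- forcing
  attr(res, "scenarios") <- specs
  attr(res, "trajectories") <- list(baseline = baseline,
                                    intervention = intervention)
  res
}

#' One-at-a-time sensitivity sweep
#'
#' Re-runs a scenario across a grid of values of one parameter — a scenario
#' field (`uptake`, `adherence`, `incidence_multiplier`) applied to every
#' spec in the scenario, or a natural-history parameter — and summarizes
#' the 2050 outcomes per grid point.
#'
#' @param parameter parameter name
#' @param grid numeric vector of values
#' @param scenario as in [run_scenario()]
#' @param params,targets,library,control as in [run_scenario()]
#' @return data frame per grid point: value, 2050 cumulative averted cases,
#'   proportion averted, prevalence reduction (pp); attribute `monotone`
#'   says whether cumulative averted cases are monotone across the grid
#' @export
sensitivity_sweep <- function(parameter, grid, scenario, params, targets,
                              library = scenario_library(),
                              control = list()) {
  if (!length(grid)) stop("empty grid", call. = FALSE)
  spec_fields <- c("uptake", "adherence", "incidence_multiplier")
  nh_fields <- names(FIT_BOUNDS)
  extra <- c("rr_obese", "rr_inactive", "rr_smoker", "kappa_t2dm",
             "alpha_obese", "omega_obese", "mu_scale")
  if (!parameter %in% c(spec_fields, nh_fields, extra))
    stop("unknown parameter '", parameter, "'", call. = FALSE)
  rows <- lapply(grid, function(v) {
    p <- params
    sc <- resolve_scenarios(scenario, library)
    if (parameter %in% spec_fields) {
      sc <- lapply(sc, function(s) { s[[parameter]] <- v; s })
    } else {
      p <- set_free(p, setNames(
        if (parameter %in% LOG_SCALE_PARAMS) log(v) else v, parameter))
    }
    r <- run_scenario(sc, p, targets, library, control = control)
    f <- r[nrow(r), ]
    data.frame(parameter = parameter, value = v,
               cum_averted_2050 = f$cum_averted,
               prop_averted_2050 = f$prop_averted,
               prevalence_reduction_pp_2050 = f$prevalence_reduction_pp)
  })
  out <- do.call(rbind, rows)
  d <- diff(out$cum_averted_2050)
  attr(out, "monotone") <- all(d >= -1e-6) || all(d <= 1e-6)
  out
}
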