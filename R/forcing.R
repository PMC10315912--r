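#' Solve the obesity-prevalence forcing for a set of scenarios
#'
#' Scenarios that state an obesity-prevalence endpoint (reached by the end
#' of scale-up and held thereafter) are implemented as a forced perturbation
#' of the obesity transition rates among covered persons: an additional exit
#' rate `multiplier * s(t) * omega_ref` and a matching acquisition damping
#' `1 / (1 + multiplier * s(t))`, where `s(t)` ramps linearly over the
#' scale-up window. The scalar multiplier is solved by bisection so the
#' simulated obesity prevalence in the stated scope (total population or the
#' covered subgroup) hits the target at the end of scale-up within
#' tolerance. After scale-up a proportional feedback controller holds the
#' prevalence at the target (it only acts when prevalence is above target,
#' so the trajectory never overshoots below it).
#'
#' Scenarios sharing a scope are solved jointly with one shared multiplier
#' targeting the most stringent (lowest) applicable endpoint; groups of
#' different scope are solved by alternating bisections until every group
#' is within tolerance.
#'
#' @param scenarios list of `intervention_spec` (the full set that will be
#'   simulated together; those without an obesity endpoint are carried
#'   along for their coverage/incidence effects)
#' @param state initial `model_state` with matching coverage dimension
#' @param params `nh_params`
#' @param t0 start year of the simulation
#' @param tol achievement tolerance on prevalence (default 5e-4, i.e.
#'   0.05 percentage points)
#' @param omega_ref reference exit rate (per year) scaled by the multiplier
#' @param max_mult upper bound for the bracketed search
#' @param control solver control passed to [simulate_model()]
#' @return object of class `obesity_forcing`: list of solved groups with
#'   their multipliers and achieved prevalences
#' @export
solve_obesity_forcing <- function(scenarios, state, params, t0 = state$year,
                                  tol = 5e-4, omega_ref = 0.1,
                                  max_mult = 64, control = list()) {
  has_target <- vapply(scenarios, function(s) !is.null(s$obesity_prev_target),
                       TRUE)
  if (!any(has_target))
    return(structure(list(groups = list()), class = "obesity_forcing"))

  idx <- which(has_target)
  scopes <- vapply(scenarios[idx], `[[`, "", "obesity_scope")
  groups <- list()
  for (sc in unique(scopes)) {
    members <- idx[scopes == sc]
    targets <- vapply(scenarios[members], `[[`, 0, "obesity_prev_target")
    groups[[length(groups) + 1L]] <- list(
      scope = sc,
      scenario_idx = members,
      scenario_ids = vapply(scenarios[members], `[[`, "", "id"),
      target = min(targets),
      ramp_start = min(vapply(scenarios[members], `[[`, 0, "ramp_start")),
      ramp_end = max(vapply(scenarios[members], `[[`, 0, "ramp_end")),
      omega_ref = omega_ref,
      multiplier = 0, achieved = NA_real_)
  }
  t_end <- max(vapply(groups, `[[`, 0, "ramp_end"))
  # measured with the same integrator settings as the production runs, so
  # the achieved value and the final trajectory agree by construction
  ctl <- control

  measure <- function(forcing) {
    traj <- simulate_model(state, params, scenarios, t0 = t0, t1 = t_end,
                           forcing = forcing, control = ctl)
    vapply(seq_along(groups), function(i) {
      g <- forcing$groups[[i]]
      st <- state_at(traj, g$ramp_end)
      cl <- if (identical(g$scope, "covered"))
        covered_classes(length(scenarios), g$scenario_idx) else NULL
      obesity_prevalence_sim(st, classes = cl)
    }, 0)
  }

  forcing <- structure(list(groups = groups), class = "obesity_forcing")
  base <- measure(forcing)
  for (i in seq_along(groups)) {
    if (base[i] <= groups[[i]]$target + tol) {
      # target at or above the unforced value: zero forcing suffices
      forcing$groups[[i]]$multiplier <- 0
      forcing$groups[[i]]$achieved <- base[i]
      groups[[i]]$solved <- TRUE
    } else groups[[i]]$solved <- FALSE
  }
  unsolved <- which(!vapply(groups, `[[`, TRUE, "solved"))

  # bracketed monotone search on the multiplier: bounded doubling to
  # bracket the target, then regula falsi inside the bracket
  bisect_group <- function(forcing, i) {
    g <- forcing$groups[[i]]
    eval_m <- function(m) {
      forcing$groups[[i]]$multiplier <- m
      measure(forcing)[i]
    }
    lo <- 0; p_lo <- eval_m(0)
    hi <- 1; p_hi <- eval_m(1)
    while (p_hi > g$target && hi < max_mult) {
      lo <- hi; p_lo <- p_hi
      hi <- min(hi * 2, max_mult)
      p_hi <- eval_m(hi)
    }
    if (p_hi > g$target + tol && hi >= max_mult)
      stop(sprintf(
        "obesity target %.3f unreachable in scope '%s'; closest achievable %.4f",
        g$target, g$scope, p_hi), call. = FALSE)
    m <- hi
    for (it in 1:12) {
      m <- lo + (hi - lo) * (p_lo - g$target) /
        max(p_lo - p_hi, 1e-12)
      m <- min(max(m, lo + 0.05 * (hi - lo)), hi - 0.05 * (hi - lo))
      p <- eval_m(m)
      if (abs(p - g$target) < tol / 5) break
      if (p > g$target) { lo <- m; p_lo <- p } else { hi <- m; p_hi <- p }
      if ((hi - lo) / max(hi, 1e-12) < 1e-3) break
    }
    forcing$groups[[i]]$multiplier <- m
    forcing$groups[[i]]$achieved <- eval_m(m)
    forcing
  }

  for (round in 1:3) {
    for (i in unsolved) forcing <- bisect_group(forcing, i)
    ach <- measure(forcing)
    for (i in seq_along(groups)) forcing$groups[[i]]$achieved <- ach[i]
    ok <- all(abs(ach[unsolved] -
                    vapply(forcing$groups[unsolved], `[[`, 0, "target")) <= tol)
    if (ok || length(unsolved) <= 1L) break
  }
  forcing
}

# coverage classes (1-based) containing any of the given scenario indices
covered_classes <- function(n_scenarios, scenario_idx) {
  C <- 2L^n_scenarios
  mask <- rep(FALSE, C)
  for (k in scenario_idx)
    mask <- mask | bitwAnd(seq_len(C) - 1L, bitwShiftL(1L, k - 1L)) > 0L
  which(mask)
}

#' @export
print.obesity_forcing <- function(x, ...) {
  if (!length(x$groups)) {
    cat("<obesity_forcing> (none)\n")
    return(invisible(x))
  }
  cat("<obesity_forcing>\n")
  for (g in x$groups)
    cat(sprintf("  %s scope [%s]: target %.1f%% by %d, multiplier %.3f, achieved %s\n",
                g$scope, paste(g$scenario_ids, collapse = ", "),
                100 * g$target, g$ramp_end, g$multiplier,
                ifelse(is.na(g$achieved), "?",
                       sprintf("%.2f%%", 100 * g$achieved))))
  invisible(x)
}
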