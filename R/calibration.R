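#' @importFrom minpack.lm nls.lm nls.lm.control
NULL

FIT_BOUNDS <- list(
  lambda_a = c(-12, -1),
  lambda_b = c(-2, 3),
  lambda_c = c(-1.5, 1),
  lambda_trend = c(-0.3, 0.3),
  lambda_trend2 = c(-0.015, 0.015),
  lambda_trend3 = c(-5e-4, 5e-4),
  alpha_obese_scale = c(0.1, 10),
  entry_scale = c(1, 1e7),
  entry_trend = c(-0.05, 0.15),
  kappa_t2dm = c(1, 5)
)
LOG_SCALE_PARAMS <- c("entry_scale", "alpha_obese_scale")
# internal optimizer rescaling so all coordinates have comparable magnitude
PARAM_SCALE <- c(lambda_trend = 10, lambda_trend2 = 100, lambda_trend3 = 1000)

fit_scale <- function(nm) if (nm %in% names(PARAM_SCALE)) PARAM_SCALE[[nm]] else 1

#' Calibration specification
#'
#' @param free names of the parameters estimated by [fit_parameters()];
#'   any of `lambda_a`, `lambda_b`, `lambda_c` (log-hazard age polynomial,
#'   applied to both sexes), `lambda_trend`, `alpha_obese_scale`,
#'   `entry_scale`, `entry_trend`, `kappa_t2dm`
#' @param bounds named list of `c(lower, upper)` overriding the defaults
#' @param weights named loss weights per target family: `t2dm`, `t2dm_age`,
#'   `obesity`, `inactivity`, `smoking`, `population`. Aggregate prevalence
#'   residuals are in percentage points and population residuals in percent
#'   deviation, so unit weights equalize the family scales
#' @param max_iter Levenberg-Marquardt iteration cap per stage
#' @param tol relative convergence tolerance on the residual sum of squares
#' @param n_starts multistart count for the disease-stage fit
#' @param seed seed for the multistart perturbations
#' @param age_profile_years calendar years at which age-resolved T2DM
#'   residuals are evaluated (NULL = first/last plus two interior years)
#' @param sim_control solver control used during fitting
#' @return object of class `fit_spec`
#' @export
fit_spec <- function(free = c("lambda_a", "lambda_b", "lambda_c",
                              "lambda_trend", "lambda_trend2",
                              "lambda_trend3", "alpha_obese_scale",
                              "entry_scale", "entry_trend"),
                     bounds = list(),
                     weights = c(t2dm = 1, t2dm_age = 0.3, obesity = 1,
                                 inactivity = 0.2, smoking = 0.2,
                                 population = 1),
                     max_iter = 120, tol = 1e-10, n_starts = 5, seed = 1L,
                     age_profile_years = NULL,
                     sim_control = list(rtol = 1e-7)) {
  unknown <- setdiff(free, names(FIT_BOUNDS))
  if (length(unknown))
    stop("unknown free parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  b <- modifyList(FIT_BOUNDS, bounds)
  for (nm in names(b))
    if (b[[nm]][1] >= b[[nm]][2]) stop_field(nm, "bounds must have lower < upper")
  if (any(weights < 0) || all(weights == 0))
    stop_field("weights", "must be non-negative and not all zero")
  structure(list(free = free, bounds = b, weights = weights,
                 max_iter = max_iter, tol = tol, n_starts = n_starts,
                 seed = as.integer(seed),
                 age_profile_years = age_profile_years,
                 sim_control = sim_control),
            class = "fit_spec")
}

get_free <- function(params, free) {
  vapply(free, function(nm) {
    v <- params[[nm]]
    if (length(v) > 1L) v <- v[[1]]
    if (nm %in% LOG_SCALE_PARAMS) log(v) else v * fit_scale(nm)
  }, 0)
}

set_free <- function(params, values) {
  for (nm in names(values)) {
    v <- values[[nm]]
    v <- if (nm %in% LOG_SCALE_PARAMS) exp(v) else v / fit_scale(nm)
    if (length(params[[nm]]) > 1L) params[[nm]][] <- v else params[[nm]] <- v
  }
  params
}

fit_bounds_vec <- function(spec, free, side) {
  vapply(free, function(nm) {
    b <- spec$bounds[[nm]][side]
    if (nm %in% LOG_SCALE_PARAMS) log(b) else b * fit_scale(nm)
  }, 0)
}

# weighted residual vector between a simulated baseline and the targets
target_residuals <- function(params, targets, spec, state0, horizon,
                             families = NULL, long = FALSE) {
  w <- spec$weights
  traj <- simulate_model(state0, params, t0 = horizon[1], t1 = horizon[2] + 1,
                         control = spec$sim_control)
  years <- horizon[1]:horizon[2]
  agg_t <- aggregate_targets(targets)
  agg_t <- agg_t[match(years, agg_t$year), ]
  ob <- which(PROFILE_FLAGS[, "obese"] == 1)
  ia <- which(PROFILE_FLAGS[, "inactive"] == 1)
  sm <- which(PROFILE_FLAGS[, "smoker"] == 1)
  sim <- t(vapply(years, function(y) {
    cnt <- counts_of(traj, y)
    tot <- sum(cnt)
    c(pop = tot,
      t2dm = sum(cnt[, , , 2L, ]) / tot,
      obesity = sum(cnt[, , ob, , ]) / tot,
      inactivity = sum(cnt[, , ia, , ]) / tot,
      smoking = sum(cnt[, , sm, , ]) / tot)
  }, numeric(5)))
  res <- list(
    population = w["population"] * 100 * (sim[, "pop"] / agg_t$population - 1),
    t2dm = w["t2dm"] * 100 * (sim[, "t2dm"] - agg_t$t2dm_prev),
    obesity = w["obesity"] * 100 * (sim[, "obesity"] - agg_t$obesity_prev),
    inactivity = w["inactivity"] * 100 * (sim[, "inactivity"] - agg_t$inactivity_prev),
    smoking = w["smoking"] * 100 * (sim[, "smoking"] - agg_t$smoking_prev)
  )
  ay <- spec$age_profile_years %||%
    unique(round(seq(horizon[1], horizon[2], length.out = 4)))
  age_res <- numeric(0)
  for (y in ay) {
    cnt <- counts_of(traj, y)
    d <- targets[targets$year == y, ]
    for (s in 1:2) {
      dd <- d[d$sex == SEXES[s], ]
      dd <- dd[order(dd$age_band), ]
      tot_b <- apply(cnt[s, , , , , drop = FALSE], 2L, sum)
      dia_b <- apply(cnt[s, , , 2L, , drop = FALSE], 2L, sum)
      pv <- ifelse(tot_b > 0, dia_b / tot_b, 0)
      # weight bands by their population share so sparse old bands
      # do not dominate
      ws <- sqrt(dd$population / sum(dd$population) * N_BANDS)
      age_res <- c(age_res,
                   w["t2dm_age"] * 100 * ws * (pv - dd$t2dm_prev))
    }
  }
  res$t2dm_age <- age_res
  if (!is.null(families)) res <- res[families]
  if (long) return(list(residuals = res, trajectory = traj))
  unlist(res, use.names = FALSE)
}

# Profile-matching initialization of the hazard level and secular trend:
# the incidence path implied by the target surfaces (stock change plus
# mortality/ageing exits, both computable from the targets and the fixed
# demographic parameters) is compared with the simulated path, and the log
# ratio is regressed onto the trend polynomial. Two or three passes land
# the parameters next to the least-squares basin; the LM stages then only
# polish.
init_trend_profile <- function(params, targets, spec, state0, horizon,
                               n_pass = 3L) {
  years <- horizon[1]:horizon[2]
  mids <- band_midpoints()
  mu <- params$mu_scale * exp(params$mu_slope * (mids - 50))
  kap <- params$kappa_t2dm
  by_year <- split(targets, targets$year)
  D_t <- vapply(by_year, function(d) sum(d$population * d$t2dm_prev), 0)
  e_t <- vapply(by_year, function(d) {
    D_j <- tapply(d$population * d$t2dm_prev, d$age_band, sum)
    (kap * sum(mu * D_j) + D_j[N_BANDS] / BAND_WIDTH) / sum(D_j)
  }, 0)
  ny <- length(years) - 1L
  mid_t <- (seq_len(ny) - 0.5)
  I_implied <- diff(D_t) + (e_t[-length(e_t)] + e_t[-1]) / 2 *
    (D_t[-length(D_t)] + D_t[-1]) / 2
  bounds_lo <- vapply(c("lambda_a", "lambda_trend", "lambda_trend2",
                        "lambda_trend3"), function(nm) spec$bounds[[nm]][1], 0)
  bounds_hi <- vapply(c("lambda_a", "lambda_trend", "lambda_trend2",
                        "lambda_trend3"), function(nm) spec$bounds[[nm]][2], 0)
  for (pass in seq_len(n_pass)) {
    traj <- simulate_model(state0, params, t0 = horizon[1],
                           t1 = horizon[2] + 1, control = spec$sim_control)
    I_mod <- vapply(years[seq_len(ny)], function(y)
      annual_new_cases(traj, y), 0)
    lr <- log(pmax(I_implied, 1e-9) / pmax(I_mod, 1e-9))
    cf <- stats::coef(stats::lm(lr ~ mid_t + I(mid_t^2) + I(mid_t^3)))
    upd <- c(params$lambda_a[[1]] + cf[[1]],
             params$lambda_trend + cf[[2]],
             params$lambda_trend2 + cf[[3]],
             params$lambda_trend3 + cf[[4]])
    upd <- pmin(pmax(upd, bounds_lo), bounds_hi)
    params$lambda_a[] <- upd[1]
    params$lambda_trend <- upd[2]
    params$lambda_trend2 <- upd[3]
    params$lambda_trend3 <- upd[4]
  }
  params
}

run_lm <- function(par0, fn, lower, upper, spec) {
  nls.lm(par = par0, fn = fn, lower = lower, upper = upper,
         control = nls.lm.control(maxiter = spec$max_iter,
                                  ftol = spec$tol, ptol = 1e-10,
                                  epsfcn = 1e-6))
}

#' Fit natural-history parameters to calibration targets
#'
#' Nonlinear least squares: minimizes weighted squared differences between
#' the simulated no-intervention baseline and the target surfaces
#' (aggregate population, T2DM, obesity, inactivity and smoking prevalence
#' per year, plus age-resolved T2DM prevalence at selected years).
#'
#' The fit proceeds in interpretable stages — demography (entry rates on
#' population totals), risk factors (obesity acquisition scale on the
#' obesity path), disease (hazard age-polynomial and trend on the T2DM
#' surfaces, with multistart), then a joint Levenberg-Marquardt polish of
#' all free parameters on the full weighted loss.
#'
#' @param targets `calibration_targets`
#' @param spec a [fit_spec()]
#' @param initial starting `nh_params` (default:
#'   [default_natural_history()] for the targets' configuration)
#' @return object of class `fit_result`: `params`, `rss`, `residuals`
#'   (named by family), `converged`, `iterations`, `rss_trace`
#' @export
fit_parameters <- function(targets, spec = fit_spec(), initial = NULL) {
  validate_targets(targets)
  cfg <- attr(targets, "config")
  if (is.null(initial))
    initial <- if (!is.null(cfg)) default_natural_history(cfg)
               else default_natural_history()
  horizon <- range(targets$year)
  state0 <- initial_state(targets, initial)
  params <- initial
  iterations <- 0L
  rss_trace <- numeric(0)

  stage <- function(params, free, families, starts = NULL) {
    free <- intersect(spec$free, free)
    if (!length(free)) return(list(params = params, info = 0, niter = 0L,
                                   trace = numeric(0), deviance = NA_real_))
    fn <- function(p) {
      names(p) <- free
      target_residuals(set_free(params, p), targets, spec, state0, horizon,
                       families = families)
    }
    lower <- fit_bounds_vec(spec, free, 1L)
    upper <- fit_bounds_vec(spec, free, 2L)
    par0 <- pmin(pmax(get_free(params, free), lower), upper)
    fits <- list(run_lm(par0, fn, lower, upper, spec))
    if (!is.null(starts) && starts > 1L) {
      set.seed(spec$seed)
      for (i in seq_len(starts - 1L)) {
        pert <- par0 + stats::rnorm(length(par0), 0, 0.15) * (upper - lower)
        pert <- pmin(pmax(pert, lower), upper)
        fits[[i + 1L]] <- run_lm(pert, fn, lower, upper, spec)
      }
    }
    best <- fits[[which.min(vapply(fits, stats::deviance, 0))]]
    est <- best$par
    names(est) <- free
    list(params = set_free(params, est), info = best$info,
         niter = best$niter, trace = best$rsstrace,
         deviance = stats::deviance(best))
  }

  s1 <- stage(params, c("entry_scale", "entry_trend"), "population")
  params <- s1$params
  s2 <- stage(params, "alpha_obese_scale", "obesity")
  params <- s2$params
  params <- init_trend_profile(params, targets, spec, state0, horizon)
  s3 <- stage(params, c("lambda_a", "lambda_b", "lambda_c", "lambda_trend",
                        "lambda_trend2", "lambda_trend3", "kappa_t2dm"),
              c("t2dm", "t2dm_age"), starts = spec$n_starts)
  params <- s3$params
  s4 <- stage(params, spec$free, NULL)
  params <- s4$params
  iterations <- sum(s1$niter, s2$niter, s3$niter, s4$niter)
  rss_trace <- s4$trace

  final <- target_residuals(params, targets, spec, state0, horizon,
                            long = TRUE)
  rss <- sum(unlist(final$residuals)^2)
  converged <- all(vapply(list(s1, s2, s3, s4), function(s)
    s$niter == 0L || s$info %in% 1:4 ||
      (is.finite(s$deviance) && s$deviance < 1e-6), TRUE))
  structure(list(params = params, rss = rss,
                 residuals = lapply(final$residuals, unname),
                 converged = converged, iterations = iterations,
                 rss_trace = rss_trace, spec = spec,
                 horizon = horizon),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> RSS %.4g after %d iterations (%s)\n",
              x$rss, x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  print(x$params)
  invisible(x)
}

#' Per-cell residual table for a fitted model
#'
#' @param result a `fit_result`
#' @param targets the `calibration_targets` that were fitted
#' @return data frame with one row per (sex, age band, year, family):
#'   target value, simulated value and residual (simulated - target)
#' @export
residual_report <- function(result, targets) {
  validate_targets(targets)
  horizon <- range(targets$year)
  state0 <- initial_state(targets, result$params)
  traj <- simulate_model(state0, result$params, t0 = horizon[1],
                         t1 = horizon[2] + 1,
                         control = result$spec$sim_control %||% list())
  sim <- trajectory_targets(traj, years = horizon[1]:horizon[2])
  key <- c("sex", "age_band", "year")
  m <- merge(targets, sim, by = key, suffixes = c("_target", "_sim"))
  fams <- c(population = "population", t2dm = "t2dm_prev",
            obesity = "obesity_prev", inactivity = "inactivity_prev",
            smoking = "smoking_prev")
  out <- do.call(rbind, lapply(names(fams), function(f) {
    col <- fams[[f]]
    data.frame(m[key], family = f,
               target = m[[paste0(col, "_target")]],
               simulated = m[[paste0(col, "_sim")]],
               residual = m[[paste0(col, "_sim")]] -
                 m[[paste0(col, "_target")]],
               stringsAsFactors = FALSE)
  }))
  out[order(out$family, out$year, out$sex, out$age_band), ]
}
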