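#' Baseline configuration for the synthetic target generator
#'
#' Encodes the published burden anchors for the Qatari adult (20-79)
#' population that the synthetic calibration targets must reproduce:
#' T2DM prevalence rising from 17.1% (2021) to 29.5% (2050), prevalent
#' cases 33,821 to 84,516, annual new cases 2,145 to 3,931, baseline
#' obesity prevalence 53.3% in 2030 (53.1% in 2023), physical inactivity
#' 46.5% and smoking 20.7% in 2023. Population totals default to the
#' ratios implied by the printed case counts and prevalences.
#'
#' @param start_year,end_year projection horizon (calendar years)
#' @param pop_20_79_start,pop_20_79_end total population aged 20-79 at the
#'   horizon ends (persons)
#' @param t2dm_prev_start,t2dm_prev_end aggregate T2DM prevalence anchors
#'   (fractions)
#' @param new_cases_start,new_cases_end annual incident T2DM cases in the
#'   first and last calendar year of the horizon (persons/year)
#' @param cum_new_cases cumulative incident cases over the whole horizon
#'   (persons); the default is derived from the published averted-case
#'   count/proportion pairs of the combination packages
#' @param obesity_prev_2023,obesity_prev_2030 aggregate obesity anchors
#' @param inactivity_prev_2023,smoking_prev_2023 risk-factor anchors,
#'   held flat over age and calendar time
#' @param sex_ratio fraction male
#' @param age_profile_shape exponential decay rate (per year of age) of the
#'   start-year population density across 20-79; the default reflects a
#'   young, fast-grown adult pyramid
#' @param t2dm_hazard_b,t2dm_hazard_c log-quadratic age shape of the T2DM
#'   onset hazard, `exp(b*z + c*z^2)` with `z = (age - 45)/10` — the same
#'   family the model's baseline hazard uses; the defaults put the fastest
#'   rise through ages 40-55 with onset peaking in the mid-60s
#' @param obesity_age_gradient relative spread of obesity prevalence across
#'   the age range (0 = flat)
#' @param noise_sd multiplicative log-normal jitter applied to the generated
#'   prevalence surfaces (0 = smooth, the default)
#' @param seed integer seed used when `noise_sd > 0`
#' @return an object of class `baseline_config`
#' @export
baseline_config <- function(start_year = 2021,
                            end_year = 2050,
                            pop_20_79_start = 33821 / 0.171,
                            pop_20_79_end = 84516 / 0.295,
                            t2dm_prev_start = 0.171,
                            t2dm_prev_end = 0.295,
                            new_cases_start = 2145,
                            new_cases_end = 3931,
                            cum_new_cases = mean(c(18619 / 0.228, 38379 / 0.469)),
                            obesity_prev_2023 = 0.531,
                            obesity_prev_2030 = 0.533,
                            inactivity_prev_2023 = 0.465,
                            smoking_prev_2023 = 0.207,
                            sex_ratio = 0.5,
                            age_profile_shape = 0.04,
                            t2dm_hazard_b = 0.8,
                            t2dm_hazard_c = -0.2,
                            obesity_age_gradient = 0.2,
                            noise_sd = 0,
                            seed = 20210L) {
  cfg <- list(
    start_year = start_year, end_year = end_year,
    pop_20_79_start = pop_20_79_start, pop_20_79_end = pop_20_79_end,
    t2dm_prev_start = t2dm_prev_start, t2dm_prev_end = t2dm_prev_end,
    new_cases_start = new_cases_start, new_cases_end = new_cases_end,
    cum_new_cases = cum_new_cases,
    obesity_prev_2023 = obesity_prev_2023,
    obesity_prev_2030 = obesity_prev_2030,
    inactivity_prev_2023 = inactivity_prev_2023,
    smoking_prev_2023 = smoking_prev_2023,
    sex_ratio = sex_ratio,
    age_profile_shape = age_profile_shape,
    t2dm_hazard_b = t2dm_hazard_b,
    t2dm_hazard_c = t2dm_hazard_c,
    obesity_age_gradient = obesity_age_gradient,
    noise_sd = noise_sd,
    seed = as.integer(seed)
  )
  class(cfg) <- "baseline_config"
  validate_baseline_config(cfg)
  cfg
}

validate_baseline_config <- function(cfg) {
  for (f in c("t2dm_prev_start", "t2dm_prev_end", "obesity_prev_2023",
              "obesity_prev_2030", "inactivity_prev_2023",
              "smoking_prev_2023", "sex_ratio"))
    check_fraction(cfg[[f]], f)
  for (f in c("pop_20_79_start", "pop_20_79_end", "new_cases_start",
              "new_cases_end", "cum_new_cases"))
    check_positive(cfg[[f]], f)
  if (cfg$start_year >= cfg$end_year)
    stop_field("start_year", "must be strictly before end_year")
  if (!is.numeric(cfg$age_profile_shape) || cfg$age_profile_shape < 0)
    stop_field("age_profile_shape", "must be non-negative")
  if (cfg$noise_sd < 0) stop_field("noise_sd", "must be non-negative")
  invisible(cfg)
}

#' @export
print.baseline_config <- function(x, ...) {
  cat("<baseline_config> ", x$start_year, "-", x$end_year, "\n", sep = "")
  cat(sprintf("  T2DM prevalence: %.1f%% -> %.1f%%\n",
              100 * x$t2dm_prev_start, 100 * x$t2dm_prev_end))
  cat(sprintf("  population 20-79: %.0f -> %.0f\n",
              x$pop_20_79_start, x$pop_20_79_end))
  cat(sprintf("  annual new cases: %.0f -> %.0f (cumulative %.0f)\n",
              x$new_cases_start, x$new_cases_end, x$cum_new_cases))
  invisible(x)
}

#' Aggregate burden path implied by the baseline anchors
#'
#' The generator treats the aggregate incidence path as the primitive:
#' log-quadratic in time, \eqn{I(t) = \exp(a_0 + a_1 t + a_2 t^2)} over the
#' horizon — the same secular family the model's hazard trend spans — with
#' the coefficients pinned by the first-year case count, the last-year case
#' count, and the cumulative case count. The diabetic stock then satisfies \eqn{D'(t) = I(t) - e D(t)}
#' with the constant aggregate exit rate \eqn{e} (mortality plus ageing out
#' of the modeled range) solved so the stock lands on the end-year anchor.
#' Aggregate prevalence is \eqn{D(t)/N(t)} with exponentially interpolated
#' population totals, so both prevalence anchors hold exactly.
#'
#' @param config a [baseline_config()]
#' @return list with the incidence log-path coefficients `A`, `B`, `g`
#'   (intercept, linear, quadratic), the exit rate `exit_rate`, population growth rate `pop_growth`, and vectorized
#'   functions `incidence(t)`, `diabetic(t)`, `population(t)`,
#'   `prevalence(t)` of time since `start_year`
#' @export
implied_burden_path <- function(config = baseline_config()) {
  T_prev <- config$end_year - config$start_year      # prevalence anchor time
  T_full <- T_prev + 1                               # cases through end year
  D0 <- config$t2dm_prev_start * config$pop_20_79_start
  D1 <- config$t2dm_prev_end * config$pop_20_79_end
  gN <- log(config$pop_20_79_end / config$pop_20_79_start) / T_prev
  Nfun <- function(t) config$pop_20_79_start * exp(gN * t)

  flat <- abs(config$t2dm_prev_start - config$t2dm_prev_end) < 1e-9

  I0 <- config$new_cases_start
  I1 <- config$new_cases_end
  Icum <- config$cum_new_cases
  # log-quadratic incidence path I(t) = exp(a0 + a1 t + a2 t^2), the same
  # secular family the model's hazard trend spans; coefficients solved from
  # the three case-count constraints by damped Newton iteration
  tgrid <- seq(0, T_full, by = 0.01)
  path_int <- function(a, lo, hi) {
    sel <- tgrid >= lo - 1e-12 & tgrid <= hi + 1e-12
    v <- exp(a[1] + a[2] * tgrid + a[3] * tgrid^2)
    # trapezoid on the fine grid (ample at dt = 0.01)
    tt <- tgrid[sel]; vv <- v[sel]
    sum((vv[-1] + vv[-length(vv)]) / 2 * diff(tt))
  }
  resid3 <- function(a) c(path_int(a, 0, 1) / I0 - 1,
                          path_int(a, T_full - 1, T_full) / I1 - 1,
                          path_int(a, 0, T_full) / Icum - 1)
  if (abs(I1 - I0) < 1e-9 && abs(Icum - T_full * I0) < 1e-6 * Icum) {
    a <- c(log(I0), 0, 0)
  } else {
    a <- c(log(I0), log(I1 / I0) / T_full, 0)
    ok <- FALSE
    for (it in 1:100) {
      r <- resid3(a)
      if (max(abs(r)) < 1e-12) { ok <- TRUE; break }
      J <- matrix(0, 3, 3)
      h <- 1e-7
      for (j in 1:3) {
        ap <- a; ap[j] <- ap[j] + h
        J[, j] <- (resid3(ap) - r) / h
      }
      step <- tryCatch(solve(J, r), error = function(e) NULL)
      if (is.null(step)) break
      a <- a - pmin(pmax(step, -1), 1)
    }
    if (!ok && max(abs(resid3(a))) > 1e-6)
      stop_field("cum_new_cases",
                 "inconsistent with the annual case anchors (no incidence-path solution)")
  }
  A <- a[1]; B <- a[2]; g <- a[3]      # log-quadratic coefficients
  Ifun <- function(t) exp(a[1] + a[2] * t + a[3] * t^2)

  # constant exit rate landing D on the end anchor (RK4, yearly steps / 8)
  integrate_D <- function(e) {
    n <- T_prev * 8L
    h <- T_prev / n
    D <- D0
    f <- function(t, D) Ifun(t) - e * D
    t <- 0
    path <- numeric(n + 1L); path[1L] <- D
    for (i in seq_len(n)) {
      k1 <- f(t, D); k2 <- f(t + h / 2, D + h * k1 / 2)
      k3 <- f(t + h / 2, D + h * k2 / 2); k4 <- f(t + h, D + h * k3)
      D <- D + h * (k1 + 2 * k2 + 2 * k3 + k4) / 6
      t <- t + h
      path[i + 1L] <- D
    }
    list(end = D, path = path, h = h)
  }
  if (flat) {
    exit_rate <- NA_real_
    Dfun <- function(t) config$t2dm_prev_start * Nfun(t)
  } else {
    gap <- function(e) integrate_D(e)$end - D1
    if (gap(0) < 0)
      stop_field("t2dm_prev_end",
                 "end-year diabetic stock exceeds cumulative incidence; anchors inconsistent")
    exit_rate <- uniroot(gap, c(0, 0.25), tol = 1e-12, extendInt = "downX")$root
    sol <- integrate_D(exit_rate)
    Dfun <- function(t) {
      idx <- t / sol$h
      lo <- pmax(pmin(floor(idx), length(sol$path) - 2L), 0L)
      w <- idx - lo
      sol$path[lo + 1L] * (1 - w) + sol$path[lo + 2L] * w
    }
  }
  list(A = A, B = B, g = g, exit_rate = exit_rate, pop_growth = gN,
       incidence = Ifun, diabetic = Dfun, population = Nfun,
       prevalence = function(t) Dfun(t) / Nfun(t))
}

#' Start-year demographic and disease age structure
#'
#' Builds the start-year cross-section the synthetic world begins from.
#' The population pyramid is an exponential age density (decay
#' `age_profile_shape` per year of
#' age — a young, fast-grown pyramid), split 50/50 by default between the
#' sexes. The start-year T2DM prevalence age profile comes from an
#' along-chain balance of the ageing flow, onset and excess mortality under
#' the configured onset-hazard age shape, with the hazard level solved (by
#' [uniroot()]) so the start-year prevalent-case anchor holds exactly;
#' prevalence therefore builds from near zero at the entry age and rises
#' monotonically with age. Obesity, inactivity and smoking marginals are
#' the configured anchor values.
#'
#' @param config a [baseline_config()]
#' @param mu_scale,mu_slope Gompertz mortality at age 50 (per year) and
#'   log-slope per year of age
#' @param kappa excess-mortality multiplier for diabetics
#' @return list: `w_age` (band shares), `shape` (onset-hazard age shape),
#'   `prev0` (start-year band prevalences), `mu` (band mortality),
#'   `mu_scale`, `mu_slope`, `kappa`, `rho`, `pop_growth`
#' @export
consistent_structure <- function(config = baseline_config(),
                                 mu_scale = 0.002, mu_slope = 0.085,
                                 kappa = 1.5) {
  gN <- log(config$pop_20_79_end / config$pop_20_79_start) /
    (config$end_year - config$start_year)
  mids <- band_midpoints()
  mu <- mu_scale * exp(mu_slope * (mids - 50))
  zz <- (mids - 45) / 10
  shape <- exp(config$t2dm_hazard_b * zz + config$t2dm_hazard_c * zz^2)
  rho <- config$age_profile_shape
  w <- exp(-rho * (mids - AGE_MIN))
  w <- w / sum(w)
  n <- config$pop_20_79_start * w
  D0_tot <- config$t2dm_prev_start * config$pop_20_79_start

  # start-year diabetic age distribution from the along-chain balance
  # (ageing inflow + onset = ageing outflow + excess mortality + cohort
  # growth), hazard level solved so the start-year stock is exact
  gamma_j <- pmax(c(0, n[-N_BANDS] / (BAND_WIDTH * n[-1])) -
                    1 / BAND_WIDTH - mu, 0)
  D_of <- function(H) {
    D <- numeric(N_BANDS)
    for (j in seq_len(N_BANDS)) {
      inflow <- if (j > 1) D[j - 1] / BAND_WIDTH else 0
      h <- H * shape[j]
      D[j] <- (inflow + h * n[j]) /
        (1 / BAND_WIDTH + kappa * mu[j] + gamma_j[j] + h)
    }
    pmin(D, 0.95 * n)
  }
  H0 <- uniroot(function(lh) sum(D_of(exp(lh))) - D0_tot,
                c(-15, 5), extendInt = "upX", tol = 1e-12)$root
  D <- D_of(exp(H0))
  D <- D * D0_tot / sum(D)

  list(w_age = w, shape = shape, prev0 = pmin(D / n, 0.99), mu = mu,
       mu_scale = mu_scale, mu_slope = mu_slope, kappa = kappa,
       rho = rho, pop_growth = gN)
}

# start-year cross-section as a one-year calibration-targets frame
baseline_cross_section <- function(config, struct = consistent_structure(config)) {
  ob21 <- config$obesity_prev_2023 +
    (config$obesity_prev_2030 - config$obesity_prev_2023) / 7 *
      (config$start_year - 2023)
  mids <- band_midpoints()
  raw <- 1 + config$obesity_age_gradient *
    ((mids - AGE_MIN) / (max(mids) - AGE_MIN) - 0.5)
  ob_j <- pmin(ob21 * raw / sum(struct$w_age * raw), 0.95)
  grid <- expand.grid(sex = SEXES, age_band = seq_len(N_BANDS),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  sex_w <- ifelse(grid$sex == "male", config$sex_ratio, 1 - config$sex_ratio)
  out <- data.frame(
    sex = grid$sex, age_band = as.integer(grid$age_band),
    year = as.integer(config$start_year),
    population = config$pop_20_79_start * sex_w * struct$w_age[grid$age_band],
    t2dm_prev = struct$prev0[grid$age_band],
    obesity_prev = ob_j[grid$age_band],
    inactivity_prev = config$inactivity_prev_2023,
    smoking_prev = config$smoking_prev_2023,
    stringsAsFactors = FALSE)
  class(out) <- c("calibration_targets", "data.frame")
  out
}

#' Solve generating parameters for the baseline anchors
#'
#' Finds the natural-history parameter set whose no-intervention model run,
#' started from the start-year cross-section, reproduces the configured
#' anchors: end-year T2DM prevalence, first- and last-year annual new
#' cases, cumulative new cases over the horizon, the obesity prevalence
#' anchor year, and the end-year population total. Six parameters (hazard
#' level and three secular-trend coefficients, obesity acquisition scale,
#' entry-rate scale) are adjusted by bounded Levenberg-Marquardt least
#' squares on the six normalized anchor gaps. The synthetic targets are
#' then literally a model trajectory, so every generated surface lies on
#' the model's own solution manifold ("shape from the model, scale from the
#' published anchors").
#'
#' @param config a [baseline_config()]
#' @param tol anchor tolerance (relative) below which the solve is accepted
#' @return list: `params` (the generating `nh_params`), `state0`
#'   (start-year `model_state`), `trajectory` (the generating run),
#'   `gaps` (named relative anchor gaps)
#' @export
solve_baseline_params <- function(config = baseline_config(), tol = 1e-6) {
  flat <- abs(config$t2dm_prev_start - config$t2dm_prev_end) < 1e-9
  params <- default_natural_history(config)
  t0 <- config$start_year
  t1 <- config$end_year + 1
  years <- config$start_year:config$end_year
  ob_year <- max(min(2030, config$end_year), config$start_year + 1)

  state_for <- function(rho) {
    cfg2 <- config
    cfg2$age_profile_shape <- rho
    initial_state(baseline_cross_section(cfg2), params)
  }
  sc <- c(1, 10, 100, 1000, 1, 1)
  gaps_of <- function(traj) {
    cum <- sum(vapply(years, function(y) annual_new_cases(traj, y), 0))
    if (flat) {
      qy <- round(seq(config$start_year + 1, config$end_year, length.out = 3))
      c(prev_a = prevalence(traj, qy[1]) / config$t2dm_prev_start - 1,
        prev_b = prevalence(traj, qy[2]) / config$t2dm_prev_start - 1,
        prev_end = prevalence(traj, qy[3]) / config$t2dm_prev_start - 1,
        cum = 0,
        obesity = obesity_prevalence_sim(traj, ob_year) /
          aggregate_obesity_target(config, ob_year) - 1,
        pop_end = population_size(traj, config$end_year) /
          config$pop_20_79_end - 1)
    } else {
      c(prev_end = prevalence(traj, config$end_year) /
          config$t2dm_prev_end - 1,
        new_start = annual_new_cases(traj, config$start_year) /
          config$new_cases_start - 1,
        new_end = annual_new_cases(traj, config$end_year) /
          config$new_cases_end - 1,
        cum = cum / config$cum_new_cases - 1,
        obesity = obesity_prevalence_sim(traj, ob_year) /
          aggregate_obesity_target(config, ob_year) - 1,
        pop_end = population_size(traj, config$end_year) /
          config$pop_20_79_end - 1)
    }
  }
  # the seventh unknown is the start-year pyramid slope, which governs the
  # structural exit rate (ageing out at 80); a weak prior keeps it in the
  # demographically plausible range while the anchors dominate
  rho0 <- config$age_profile_shape
  fn <- function(u) {
    p <- params
    p$lambda_a[] <- u[1] / sc[1]
    p$lambda_trend <- u[2] / sc[2]
    p$lambda_trend2 <- u[3] / sc[3]
    p$lambda_trend3 <- u[4] / sc[4]
    p$alpha_obese_scale <- exp(u[5])
    p$entry_scale <- exp(u[6])
    rho <- u[7] / 10
    traj <- tryCatch(
      simulate_model(state_for(rho), p, t0 = t0, t1 = t1,
                     control = list(rtol = 1e-8)),
      error = function(e) NULL)
    if (is.null(traj)) return(rep(10, 7))
    c(gaps_of(traj), prior_rho = 0.01 * (rho - rho0) / rho0)
  }
  u0 <- c(params$lambda_a[[1]] * sc[1], params$lambda_trend * sc[2],
          params$lambda_trend2 * sc[3], params$lambda_trend3 * sc[4],
          log(params$alpha_obese_scale), log(params$entry_scale),
          rho0 * 10)
  lower <- c(-12, -3, -1.5, -0.5, log(0.05), log(10), 0.1)
  upper <- c(-1, 3, 1.5, 0.5, log(20), log(1e7), 1.5)
  u0 <- pmin(pmax(u0, lower), upper)
  fit <- nls.lm(par = u0, fn = fn, lower = lower, upper = upper,
                control = nls.lm.control(maxiter = 200, ftol = 1e-14,
                                         ptol = 1e-12, epsfcn = 1e-6))
  u <- fit$par
  params$lambda_a[] <- u[1] / sc[1]
  params$lambda_trend <- u[2] / sc[2]
  params$lambda_trend2 <- u[3] / sc[3]
  params$lambda_trend3 <- u[4] / sc[4]
  params$alpha_obese_scale <- exp(u[5])
  params$entry_scale <- exp(u[6])
  rho <- u[7] / 10
  state0 <- state_for(rho)
  traj <- simulate_model(state0, params, t0 = t0, t1 = t1,
                         control = list(rtol = 1e-8))
  gaps <- gaps_of(traj)
  if (max(abs(gaps)) > 1e-3)
    warning(sprintf("baseline anchor solve left a %.2g relative gap (%s)",
                    max(abs(gaps)), names(gaps)[which.max(abs(gaps))]))
  list(params = params, state0 = state0, trajectory = traj, gaps = gaps,
       rho = rho)
}

# population-weighted aggregate obesity target at a calendar year (linear
# through the 2023 and 2030 anchors)
aggregate_obesity_target <- function(config, year) {
  config$obesity_prev_2023 +
    (config$obesity_prev_2030 - config$obesity_prev_2023) / 7 * (year - 2023)
}
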