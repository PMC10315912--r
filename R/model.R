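#' @importFrom deSolve ode
NULL

# Precompute everything static for the ODE right-hand side.
# scenarios: list of intervention_spec; forcing: obesity_forcing or NULL.
build_context <- function(params, scenarios = list(), forcing = NULL,
                          recruit_gain = 2, norm_completion = 0.99,
                          hold_gain = 150) {
  K <- length(scenarios)
  C <- 2L^K
  dims <- c(2L, N_BANDS, 8L, 2L, C)
  member <- matrix(FALSE, K, C)
  if (K > 0)
    for (k in seq_len(K))
      member[k, ] <- bitwAnd(seq_len(C) - 1L, bitwShiftL(1L, k - 1L)) > 0L

  mu <- mu_by_band(params)                       # [2, 20]
  kap <- c(1, params$kappa_t2dm)
  mort <- array(0, dims)
  for (st in 1:2) mort[, , , st, ] <- array(mu * kap[st], dims[c(1, 2)])
  base_out <- mort + 1 / BAND_WIDTH              # mortality + ageing out

  rrp <- rr_products(params)
  mids <- band_midpoints()
  z <- (mids - 45) / 10
  lam0 <- rbind(
    female = exp(params$lambda_a["female"] + params$lambda_b["female"] * z +
                   params$lambda_c["female"] * z^2),
    male = exp(params$lambda_a["male"] + params$lambda_b["male"] * z +
                 params$lambda_c["male"] * z^2))

  # eligibility masks and incidence multipliers
  elig <- vector("list", K)
  haz_mult <- array(1, c(2L, N_BANDS, 8L, C))
  if (K > 0) {
    for (k in seq_len(K)) {
      sp <- scenarios[[k]]
      m <- array(0, c(2L, N_BANDS, 8L))
      bands <- seq(sp$filter$min_band, sp$filter$max_band)
      profs <- if (isTRUE(sp$filter$require_obese))
        which(PROFILE_FLAGS[, "obese"] == 1) else 1:8
      m[, bands, profs] <- 1
      full <- array(0, dims)
      for (st in 1:2) for (cc in seq_len(C)) full[, , , st, cc] <- m
      elig[[k]] <- list(mask3 = m, mask = full, spec = sp,
                        bit = bitwShiftL(1L, k - 1L))
      for (cc in which(member[k, ]))
        haz_mult[, , , cc] <- haz_mult[, , , cc] *
          ifelse(m == 1, sp$incidence_multiplier, 1)
    }
  }
  haz_base <- array(0, c(2L, N_BANDS, 8L, C))
  for (cc in seq_len(C))
    haz_base[, , , cc] <- array(lam0, c(2L, N_BANDS, 8L)) *
      rep(rrp, each = 2L * N_BANDS) * haz_mult[, , , cc]

  # profile lattice edges
  edges <- lapply(1:3, function(f) {
    from <- which(PROFILE_FLAGS[, f] == 0)
    list(from = from, to = from + c(1L, 2L, 4L)[f])
  })
  alpha <- c(params$alpha_obese * params$alpha_obese_scale,
             params$alpha_inactive, params$alpha_smoker)
  omega <- c(params$omega_obese, params$omega_inactive, params$omega_smoker)

  # inactivity normalization: classes covered by a normalizing scenario
  norm_classes <- rep(FALSE, C)
  norm_rate <- 0
  norm_start <- Inf
  if (K > 0) {
    for (k in seq_len(K)) {
      sp <- scenarios[[k]]
      if (isTRUE(sp$normalize_inactivity)) {
        norm_classes <- norm_classes | member[k, ]
        dur <- sp$ramp_end - sp$ramp_start
        norm_rate <- max(norm_rate, -log(1 - norm_completion) / dur)
        norm_start <- min(norm_start, sp$ramp_start)
      }
    }
  }

  # obesity forcing groups (solved multipliers attached by the caller)
  fgroups <- list()
  if (!is.null(forcing)) {
    fgroups <- lapply(forcing$groups, function(g) {
      g$apply_classes <- rep(FALSE, C)
      for (k in g$scenario_idx) g$apply_classes <- g$apply_classes | member[k, ]
      if (identical(g$scope, "covered")) {
        g$measure_classes <- rep(FALSE, C)
        for (k in g$scenario_idx) g$measure_classes <- g$measure_classes | member[k, ]
      } else g$measure_classes <- rep(TRUE, C)
      g$hold_gain <- g$hold_gain %||% hold_gain
      g
    })
  }

  obese_profiles <- which(PROFILE_FLAGS[, "obese"] == 1)

  list(params = params, dims = dims, C = C, K = K, member = member,
       base_out = base_out, haz_base = haz_base, lam0 = lam0,
       edges = edges, alpha = alpha, omega = omega, elig = elig,
       norm_classes = norm_classes, norm_rate = norm_rate,
       norm_start = norm_start, fgroups = fgroups, mort = mort,
       obese_profiles = obese_profiles, recruit_gain = recruit_gain,
       n_counts = prod(dims))
}

# forcing controls per class at time t: list(extra_omega[C], alpha_damp[C]).
# The regime (off / ramp / hold) is selected by `ctx$regime_time` — the
# midpoint of the current integration segment — so that solver stages at a
# segment boundary cannot straddle two regimes; only the within-ramp slope
# uses the actual time t.
forcing_controls <- function(ctx, t, Xp) {
  C <- ctx$C
  extra <- numeric(C)
  damp <- rep(1, C)
  rt <- ctx$regime_time %||% t
  for (g in ctx$fgroups) {
    if (rt < g$ramp_start) next
    if (rt < g$ramp_end) {
      s <- clip01((t - g$ramp_start) / (g$ramp_end - g$ramp_start))
      phi <- g$multiplier * s
      extra[g$apply_classes] <- extra[g$apply_classes] + phi * g$omega_ref
      damp[g$apply_classes] <- damp[g$apply_classes] / (1 + phi)
    } else {
      sel <- g$measure_classes
      tot <- sum(Xp[, , , , sel])
      if (tot > 1e-6) {
        pcur <- sum(Xp[, , ctx$obese_profiles, , sel]) / tot
        # smooth one-sided feedback (softplus) so the controller engages
        # only above target without a derivative discontinuity
        wdt <- 5e-4
        xg <- (pcur - g$target) / wdt
        soft <- if (xg > 30) pcur - g$target else wdt * log1p(exp(xg))
        extra[g$apply_classes] <- extra[g$apply_classes] + g$hold_gain * soft
      }
    }
  }
  list(extra = extra, damp = damp)
}

model_deriv <- function(t, y, ctx) {
  dims <- ctx$dims
  C <- ctx$C
  n <- ctx$n_counts
  X <- array(y[seq_len(n)], dims)
  Xp <- array(pmax(X, 0), dims)
  p <- ctx$params

  dX <- -ctx$base_out * Xp
  # ageing in
  dX[, 2:N_BANDS, , , ] <- dX[, 2:N_BANDS, , , ] +
    as.vector(Xp[, 1:(N_BANDS - 1L), , , , drop = FALSE]) / BAND_WIDTH
  # entry into band 1, susceptible, uncovered
  E <- p$entry_scale * exp(p$entry_trend * (t - p$ref_year))
  dX[1L, 1L, , 1L, 1L] <- dX[1L, 1L, , 1L, 1L] +
    E * (1 - p$entry_sex_split) * p$entry_profile_mix
  dX[2L, 1L, , 1L, 1L] <- dX[2L, 1L, , 1L, 1L] +
    E * p$entry_sex_split * p$entry_profile_mix

  # inactivity / smoking transitions (class-independent rates)
  for (f in 2:3) {
    ed <- ctx$edges[[f]]
    acq <- as.vector(ctx$alpha[f] * Xp[, , ed$from, , , drop = FALSE])
    rel <- as.vector(ctx$omega[f] * Xp[, , ed$to, , , drop = FALSE])
    dX[, , ed$from, , ] <- dX[, , ed$from, , ] - acq + rel
    dX[, , ed$to, , ] <- dX[, , ed$to, , ] + acq - rel
  }
  # inactivity normalization for covered classes
  if (ctx$norm_rate > 0 && (ctx$regime_time %||% t) >= ctx$norm_start) {
    ed <- ctx$edges[[2L]]
    for (cc in which(ctx$norm_classes)) {
      mv <- as.vector(ctx$norm_rate * Xp[, , ed$to, , cc, drop = FALSE])
      dX[, , ed$to, , cc] <- dX[, , ed$to, , cc] - mv
      dX[, , ed$from, , cc] <- dX[, , ed$from, , cc] + mv
    }
  }
  # obesity transitions, with per-class forcing
  ed <- ctx$edges[[1L]]
  if (length(ctx$fgroups)) {
    fc <- forcing_controls(ctx, t, Xp)
    for (cc in seq_len(C)) {
      a <- ctx$alpha[1L] * fc$damp[cc]
      w <- ctx$omega[1L] + fc$extra[cc]
      acq <- as.vector(a * Xp[, , ed$from, , cc, drop = FALSE])
      rel <- as.vector(w * Xp[, , ed$to, , cc, drop = FALSE])
      dX[, , ed$from, , cc] <- dX[, , ed$from, , cc] - acq + rel
      dX[, , ed$to, , cc] <- dX[, , ed$to, , cc] + acq - rel
    }
  } else {
    acq <- as.vector(ctx$alpha[1L] * Xp[, , ed$from, , , drop = FALSE])
    rel <- as.vector(ctx$omega[1L] * Xp[, , ed$to, , , drop = FALSE])
    dX[, , ed$from, , ] <- dX[, , ed$from, , ] - acq + rel
    dX[, , ed$to, , ] <- dX[, , ed$to, , ] + acq - rel
  }

  # T2DM incidence (susceptible -> diabetic, no remission)
  dt_ <- t - p$ref_year
  trend <- exp(p$lambda_trend * dt_ + p$lambda_trend2 * dt_^2 +
                 p$lambda_trend3 * dt_^3)
  flow <- ctx$haz_base * trend * array(Xp[, , , 1L, ], c(2L, N_BANDS, 8L, C))
  dX[, , , 1L, ] <- dX[, , , 1L, ] - as.vector(flow)
  dX[, , , 2L, ] <- dX[, , , 2L, ] + as.vector(flow)
  dcum <- apply(flow, c(1L, 2L), sum)

  # coverage recruitment
  if (ctx$K > 0) {
    for (k in seq_len(ctx$K)) {
      el <- ctx$elig[[k]]
      sp <- el$spec
      if (t < sp$ramp_start) next
      Xe <- Xp * el$mask
      elig_tot <- sum(Xe)
      if (elig_tot <= 1e-9) next
      cov_tot <- sum(Xe[, , , , ctx$member[k, ]])
      f <- cov_tot / elig_tot
      r <- recruitment_rate(t, sp, min(f, 1), gain = ctx$recruit_gain)
      if (r <= 0) next
      for (cc in which(!ctx$member[k, ])) {
        mv <- r * Xe[, , , , cc]
        dX[, , , , cc] <- dX[, , , , cc] - mv
        dX[, , , , cc + el$bit] <- dX[, , , , cc + el$bit] + mv
      }
    }
  }

  # mass-balance accumulators: entries, deaths, ageing out at 80
  ddeaths <- sum(ctx$mort * Xp)
  dexit <- sum(Xp[, N_BANDS, , , ]) / BAND_WIDTH
  list(c(as.vector(dX), as.vector(dcum), E, ddeaths, dexit))
}

#' Simulate the compartmental model
#'
#' Integrates the ODE system with an adaptive solver (`deSolve::lsoda`) and
#' returns annual snapshots. The state dimension is
#' sex (2) x age band (20) x risk profile (8) x T2DM status (2) x coverage
#' class (`2^K` for `K` active scenarios), plus the cumulative-incidence
#' accumulator by sex and band.
#'
#' @param state a `model_state` from [initial_state()]; its coverage
#'   dimension must match `2^length(scenarios)`
#' @param params `nh_params`
#' @param scenarios list of [intervention_spec()] (empty for the baseline /
#'   counterfactual run)
#' @param t0,t1 calendar years bounding the integration (annual snapshots at
#'   integer years; `t1 = t0` returns the initial state unchanged)
#' @param forcing an `obesity_forcing` object from
#'   [solve_obesity_forcing()], or NULL
#' @param control list: `rtol` (default 1e-8), `atol` (default 1e-8 x total
#'   initial population), `method` (default "ode45", adaptive Runge-Kutta)
#' @return object of class `trajectory`: annual snapshots with accessors
#'   [prevalence()], [prevalent_cases()], [annual_new_cases()],
#'   [state_at()]
#' @export
simulate_model <- function(state, params, scenarios = list(),
                           t0 = state$year, t1, forcing = NULL,
                           control = list()) {
  check_state(state)
  if (t1 < t0) stop("t1 must be >= t0", call. = FALSE)
  K <- length(scenarios)
  if (dim(state$counts)[5L] != 2L^K)
    stop("state coverage dimension does not match the number of scenarios",
         call. = FALSE)
  ctx <- build_context(params, scenarios, forcing)
  y0 <- state_to_vector(state)
  tot0 <- sum(state$counts)
  if (t1 == t0) {
    traj <- list(times = t0,
                 counts = array(y0[seq_len(ctx$n_counts)], c(1L, ctx$dims)),
                 cum = array(y0[ctx$n_counts + seq_len(40L)], c(1L, 2L, N_BANDS)),
                 flows = matrix(y0[ctx$n_counts + 40L + 1:3], 1L, 3L,
                                dimnames = list(NULL, c("entry", "deaths",
                                                        "aged_out"))),
                 dims = ctx$dims, params = params, scenarios = scenarios)
    class(traj) <- "trajectory"
    return(traj)
  }
  rtol <- control$rtol %||% 1e-8
  atol <- control$atol %||% max(1e-8 * tot0, 1e-10)
  method <- control$method %||% "ode45"
  times <- seq(t0, t1, by = 1)
  # integrate piecewise at the structural breakpoints (scale-up starts and
  # ends) so the right-hand side is smooth within every segment and
  # adaptive steppers cannot smear the kinks
  breaks <- numeric(0)
  for (sp in scenarios) breaks <- c(breaks, sp$ramp_start, sp$ramp_end)
  if (!is.null(forcing))
    for (g in forcing$groups) breaks <- c(breaks, g$ramp_start, g$ramp_end)
  breaks <- sort(unique(breaks[breaks > t0 & breaks < t1]))
  seg_bounds <- c(t0, breaks, t1)
  sol <- NULL
  y <- y0
  for (si in seq_len(length(seg_bounds) - 1L)) {
    seg_times <- sort(unique(c(seg_bounds[si], seg_bounds[si + 1L],
                               times[times >= seg_bounds[si] &
                                       times <= seg_bounds[si + 1L]])))
    ctx$regime_time <- (seg_bounds[si] + seg_bounds[si + 1L]) / 2
    seg <- deSolve::ode(y = y, times = seg_times, func = model_deriv,
                        parms = ctx, method = method, rtol = rtol,
                        atol = atol)
    if (nrow(seg) < length(seg_times))
      stop(sprintf("ODE solver failed at t = %.2f", seg[nrow(seg), 1]),
           call. = FALSE)
    y <- seg[nrow(seg), -1L]
    keep <- seg[, 1L] %in% times & !(seg[, 1L] %in% (sol[, 1L] %||% numeric(0)))
    sol <- rbind(sol, seg[keep, , drop = FALSE])
  }
  sol <- sol[order(sol[, 1L]), , drop = FALSE]
  n <- ctx$n_counts
  traj <- list(times = times,
               counts = array(sol[, 1L + seq_len(n)], c(length(times), ctx$dims)),
               cum = array(sol[, 1L + n + seq_len(40L)],
                           c(length(times), 2L, N_BANDS)),
               flows = matrix(sol[, 1L + n + 40L + 1:3], length(times), 3L,
                              dimnames = list(NULL, c("entry", "deaths",
                                                      "aged_out"))),
               dims = ctx$dims, params = params, scenarios = scenarios)
  class(traj) <- "trajectory"
  traj
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d-%d, %d scenario(s), %d compartments\n",
              min(x$times), max(x$times), length(x$scenarios),
              prod(x$dims)))
  invisible(x)
}

time_index <- function(traj, year) {
  i <- match(year, traj$times)
  if (is.na(i)) stop("year ", year, " outside the simulated horizon",
                     call. = FALSE)
  i
}

#' Extract the model state at a snapshot year
#' @param traj a `trajectory`
#' @param year calendar year (must be a snapshot time)
#' @return `model_state`
#' @export
state_at <- function(traj, year) {
  i <- time_index(traj, year)
  structure(list(counts = array(traj$counts[i, , , , , ], traj$dims),
                 cum_inc = array(traj$cum[i, , ], c(2L, N_BANDS)),
                 flows = stats::setNames(
                   if (is.null(traj$flows)) c(0, 0, 0) else traj$flows[i, ],
                   c("entry", "deaths", "aged_out")),
                 year = year),
            class = "model_state")
}

select_bands <- function(age_range) {
  if (is.null(age_range)) return(seq_len(N_BANDS))
  lo <- age_range[1]; hi <- age_range[2]
  sel <- which(band_lower() >= lo & band_lower() + BAND_WIDTH - 1 <= hi)
  if (length(sel) == 0L) stop("empty age selection", call. = FALSE)
  sel
}

counts_of <- function(x, year = NULL) {
  if (inherits(x, "trajectory")) {
    if (is.null(year)) stop("year required for a trajectory", call. = FALSE)
    x <- state_at(x, year)
  }
  x$counts
}

#' T2DM prevalence over a selection of the lattice
#'
#' @param x a `model_state` or `trajectory`
#' @param year snapshot year (required for a trajectory)
#' @param sex `"female"`, `"male"` or NULL for both
#' @param age_range `c(lo, hi)` in years of age, or NULL for 20-79
#' @return diabetic count / total count over the selection
#' @export
prevalence <- function(x, year = NULL, sex = NULL, age_range = NULL) {
  cnt <- counts_of(x, year)
  s <- if (is.null(sex)) 1:2 else match(sex, SEXES)
  b <- select_bands(age_range)
  tot <- sum(cnt[s, b, , , ])
  if (tot <= 0) stop("empty selection: no population", call. = FALSE)
  sum(cnt[s, b, , 2L, ]) / tot
}

#' Prevalent T2DM case count over a selection
#' @inheritParams prevalence
#' @export
prevalent_cases <- function(x, year = NULL, sex = NULL, age_range = NULL) {
  cnt <- counts_of(x, year)
  s <- if (is.null(sex)) 1:2 else match(sex, SEXES)
  sum(cnt[s, select_bands(age_range), , 2L, ])
}

#' Total population over a selection
#' @inheritParams prevalence
#' @export
population_size <- function(x, year = NULL, sex = NULL, age_range = NULL) {
  cnt <- counts_of(x, year)
  s <- if (is.null(sex)) 1:2 else match(sex, SEXES)
  sum(cnt[s, select_bands(age_range), , , ])
}

#' Obesity prevalence over a selection, optionally within coverage classes
#' @inheritParams prevalence
#' @param classes integer vector of coverage classes (NULL = all)
#' @export
obesity_prevalence_sim <- function(x, year = NULL, sex = NULL,
                                   age_range = NULL, classes = NULL) {
  cnt <- counts_of(x, year)
  s <- if (is.null(sex)) 1:2 else match(sex, SEXES)
  b <- select_bands(age_range)
  cl <- if (is.null(classes)) seq_len(dim(cnt)[5L]) else classes
  ob <- which(PROFILE_FLAGS[, "obese"] == 1)
  tot <- sum(cnt[s, b, , , cl])
  if (tot <= 0) stop("empty selection: no population", call. = FALSE)
  sum(cnt[s, b, ob, , cl]) / tot
}

#' Incident T2DM cases in a calendar year
#'
#' Difference of the cumulative-incidence accumulator between the start and
#' end of the calendar year, so the trajectory must extend to `year + 1`.
#'
#' @param traj `trajectory`
#' @param year calendar year
#' @return persons (non-negative)
#' @export
annual_new_cases <- function(traj, year) {
  i0 <- time_index(traj, year)
  i1 <- time_index(traj, year + 1)
  max(sum(traj$cum[i1, , ]) - sum(traj$cum[i0, , ]), 0)
}

#' Mass-balance check of a trajectory
#'
#' At every snapshot, the population must equal the initial population plus
#' cumulative entries minus cumulative deaths and ageing-out exits; the
#' residual measures the integrator's mass leakage.
#'
#' @param traj a `trajectory`
#' @return data frame per snapshot year: population, the three cumulative
#'   flows, and `balance_error` relative to the initial population
#' @export
mass_balance <- function(traj) {
  pop <- vapply(traj$times, function(y) population_size(traj, y), 0)
  fl <- traj$flows
  err <- (pop - pop[1] - (fl[, "entry"] - fl[1, "entry"]) +
            (fl[, "deaths"] - fl[1, "deaths"]) +
            (fl[, "aged_out"] - fl[1, "aged_out"])) / pop[1]
  data.frame(year = traj$times, population = pop,
             cum_entry = fl[, "entry"], cum_deaths = fl[, "deaths"],
             cum_aged_out = fl[, "aged_out"], balance_error = err)
}

#' Rebuild a calibration-targets table from a simulated trajectory
#'
#' Used for parameter-recovery experiments: surfaces extracted from a run
#' with known parameters become the fitting targets.
#'
#' @param traj `trajectory`
#' @param years calendar years to include (default: all but the last
#'   snapshot)
#' @return `calibration_targets` data frame
#' @export
trajectory_targets <- function(traj, years = utils::head(traj$times, -1L)) {
  ob <- which(PROFILE_FLAGS[, "obese"] == 1)
  ia <- which(PROFILE_FLAGS[, "inactive"] == 1)
  sm <- which(PROFILE_FLAGS[, "smoker"] == 1)
  rows <- list()
  for (y in years) {
    cnt <- counts_of(traj, y)
    for (s in 1:2) for (b in seq_len(N_BANDS)) {
      tot <- sum(cnt[s, b, , , ])
      rows[[length(rows) + 1L]] <- data.frame(
        sex = SEXES[s], age_band = b, year = as.integer(y),
        population = tot,
        t2dm_prev = if (tot > 0) sum(cnt[s, b, , 2L, ]) / tot else 0,
        obesity_prev = if (tot > 0) sum(cnt[s, b, ob, , ]) / tot else 0,
        inactivity_prev = if (tot > 0) sum(cnt[s, b, ia, , ]) / tot else 0,
        smoking_prev = if (tot > 0) sum(cnt[s, b, sm, , ]) / tot else 0,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("calibration_targets", "data.frame")
  validate_targets(out)
  out
}

#' Export a trajectory as long-format and aggregate CSV tables
#'
#' @param traj `trajectory`
#' @param path_compartments,path_aggregate output CSV paths (NULL to skip)
#' @return invisibly, a list with the two data frames
#' @export
export_trajectory <- function(traj, path_compartments = NULL,
                              path_aggregate = NULL) {
  years <- utils::head(traj$times, -1L)
  agg <- data.frame(
    year = years,
    population = vapply(years, function(y) population_size(traj, y), 0),
    prevalence = vapply(years, function(y) prevalence(traj, y), 0),
    prevalent_cases = vapply(years, function(y) prevalent_cases(traj, y), 0),
    annual_new_cases = vapply(years, function(y) annual_new_cases(traj, y), 0))
  comp <- NULL
  if (!is.null(path_compartments)) {
    grid <- expand.grid(sex = SEXES, band = seq_len(N_BANDS),
                        profile = rownames(PROFILE_FLAGS),
                        status = c("susceptible", "diabetic"),
                        class = seq_len(traj$dims[5L]),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    comp <- do.call(rbind, lapply(years, function(y) {
      g <- grid
      g$year <- y
      g$count <- as.vector(counts_of(traj, y))
      g
    }))
    write.csv(comp, path_compartments, row.names = FALSE)
  }
  if (!is.null(path_aggregate)) write.csv(agg, path_aggregate, row.names = FALSE)
  invisible(list(aggregate = agg, compartments = comp))
}
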