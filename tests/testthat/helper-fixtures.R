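# Shared fixtures, memoised: the default synthetic world, its calibration,
# and scenario runs are expensive, so every test file draws from this cache.
.fx <- new.env(parent = emptyenv())

fx_config <- function() {
  if (is.null(.fx$config)) .fx$config <- baseline_config()
  .fx$config
}

fx_targets <- function() {
  if (is.null(.fx$targets)) .fx$targets <- generate_baseline(fx_config())
  .fx$targets
}

fx_fit <- function() {
  if (is.null(.fx$fit)) .fx$fit <- fit_parameters(fx_targets(), fit_spec())
  .fx$fit
}

fx_baseline_traj <- function() {
  if (is.null(.fx$baseline)) {
    p <- fx_fit()$params
    st <- initial_state(fx_targets(), p)
    .fx$baseline <- simulate_model(st, p, t0 = 2021, t1 = 2051)
  }
  .fx$baseline
}

fx_scenario <- function(id) {
  key <- paste0("scen_", id)
  if (is.null(.fx[[key]]))
    .fx[[key]] <- run_scenario(id, fx_fit()$params, fx_targets())
  .fx[[key]]
}

# --- toy states and parameter sets ------------------------------------------

# population placed in chosen bands, susceptible, no risk factors
toy_state <- function(pop_by_band, n_scenarios = 0L) {
  C <- 2L^n_scenarios
  counts <- array(0, c(2L, 20L, 8L, 2L, C))
  for (b in seq_along(pop_by_band)) {
    counts[1L, b, 1L, 1L, 1L] <- pop_by_band[b] / 2
    counts[2L, b, 1L, 1L, 1L] <- pop_by_band[b] / 2
  }
  structure(list(counts = counts,
                 cum_inc = array(0, c(2L, 20L)), year = 2021),
            class = "model_state")
}

# closed system: uniform hazard lambda, every other flow switched off
toy_params <- function(lambda = 0.02) {
  natural_history_params(
    lambda_a = log(lambda), lambda_b = 0, lambda_c = 0,
    lambda_trend = 0, lambda_trend2 = 0, lambda_trend3 = 0,
    rr_obese = 1, rr_inactive = 1, rr_smoker = 1,
    alpha_obese = 0, omega_obese = 0, alpha_inactive = 0,
    omega_inactive = 0, alpha_smoker = 0, omega_smoker = 0,
    mu_scale = 0, kappa_t2dm = 1, entry_scale = 0, entry_trend = 0)
}

# --- independent fixed-step Euler integrator --------------------------------
# Baseline-only (no interventions) re-implementation of the model equations
# with plain loops over the lattice; deliberately a separate code path from
# the package's vectorized right-hand side.
euler_baseline <- function(state, params, t0, t1, dt = 1e-3) {
  S <- state$counts[, , , 1L, 1L]          # [sex, band, profile]
  D <- state$counts[, , , 2L, 1L]
  cum <- 0
  mids <- band_midpoints()
  z <- (mids - 45) / 10
  fl <- get("PROFILE_FLAGS", envir = asNamespace("t2dmsim"))
  rr <- params$rr_obese^fl[, 1] * params$rr_inactive^fl[, 2] *
    params$rr_smoker^fl[, 3]
  mu <- params$mu_scale * exp(params$mu_slope * (mids - 50))
  al <- c(params$alpha_obese * params$alpha_obese_scale,
          params$alpha_inactive, params$alpha_smoker)
  om <- c(params$omega_obese, params$omega_inactive, params$omega_smoker)
  from <- lapply(1:3, function(f) which(fl[, f] == 0))
  steps <- round((t1 - t0) / dt)
  for (i in seq_len(steps)) {
    t <- t0 + (i - 1) * dt
    dtt <- t - params$ref_year
    lam <- exp(params$lambda_a[1] + params$lambda_b[1] * z +
                 params$lambda_c[1] * z^2 +
                 params$lambda_trend * dtt + params$lambda_trend2 * dtt^2 +
                 params$lambda_trend3 * dtt^3)
    dS <- array(0, dim(S)); dD <- array(0, dim(D))
    for (s in 1:2) for (p in 1:8) {
      haz <- lam * rr[p]
      inc <- haz * S[s, , p]
      dS[s, , p] <- dS[s, , p] - inc - S[s, , p] / 3 - mu * S[s, , p]
      dD[s, , p] <- dD[s, , p] + inc - D[s, , p] / 3 -
        params$kappa_t2dm * mu * D[s, , p]
      dS[s, 2:20, p] <- dS[s, 2:20, p] + S[s, 1:19, p] / 3
      dD[s, 2:20, p] <- dD[s, 2:20, p] + D[s, 1:19, p] / 3
      cum <- cum + dt * sum(inc)
    }
    # risk-factor transitions along lattice edges
    for (f in 1:3) {
      if (al[f] == 0 && om[f] == 0) next
      for (s in 1:2) for (j in from[[f]]) {
        k <- j + c(1L, 2L, 4L)[f]
        dS[s, , j] <- dS[s, , j] - al[f] * S[s, , j] + om[f] * S[s, , k]
        dS[s, , k] <- dS[s, , k] + al[f] * S[s, , j] - om[f] * S[s, , k]
        dD[s, , j] <- dD[s, , j] - al[f] * D[s, , j] + om[f] * D[s, , k]
        dD[s, , k] <- dD[s, , k] + al[f] * D[s, , j] - om[f] * D[s, , k]
      }
    }
    # entry
    E <- params$entry_scale * exp(params$entry_trend * dtt)
    mix <- params$entry_profile_mix
    dS[1, 1, ] <- dS[1, 1, ] + E * (1 - params$entry_sex_split) * mix
    dS[2, 1, ] <- dS[2, 1, ] + E * params$entry_sex_split * mix
    S <- S + dt * dS
    D <- D + dt * dD
  }
  list(S = S, D = D, cum = cum,
       total = sum(S) + sum(D),
       prevalence = sum(D) / (sum(S) + sum(D)))
}
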