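#' Natural-history and demographic parameters
#'
#' Container for every rate entering the compartmental model.
#'
#' The baseline T2DM hazard among adults free of all three risk factors is
#' log-quadratic in age with a secular trend,
#' \deqn{\lambda_0(s, a, t) = \exp(a_s + b_s z + c_s z^2 + g (t - t_{ref})),
#'   \quad z = (a - 45)/10,}
#' and is multiplied by the relative risks of the risk factors present
#' (multiplicative composition) and by any intervention incidence
#' multiplier. Risk-factor transitions move along lattice edges at
#' acquisition rates `alpha_*` and exit rates `omega_*` (per year).
#' Background mortality is Gompertz in age,
#' `mu = mu_scale * exp(mu_slope * (a - 50))`, multiplied by `kappa_t2dm`
#' for diabetics. New 20-year-olds enter band 1, susceptible, at rate
#' `entry_scale * exp(entry_trend * (t - t_ref))` persons/year split by
#' sex, with risk-profile mix `entry_profile_mix`.
#'
#' @param lambda_a,lambda_b,lambda_c length-2 named vectors (female, male)
#'   of the log-hazard age polynomial coefficients
#' @param lambda_trend,lambda_trend2,lambda_trend3 polynomial secular
#'   log-hazard trend coefficients: the hazard carries a factor
#'   `exp(lambda_trend*dt + lambda_trend2*dt^2 + lambda_trend3*dt^3)`
#'   with `dt = t - ref_year`
#' @param rr_obese,rr_inactive,rr_smoker relative risks (>= 1) of T2DM
#'   onset for each factor; defaults are literature-typical pooled values
#' @param alpha_obese,omega_obese,alpha_inactive,omega_inactive,alpha_smoker,omega_smoker
#'   acquisition/exit rates per year for each factor
#' @param alpha_obese_scale calibrated multiplier on `alpha_obese`
#' @param mu_scale,mu_slope Gompertz mortality at age 50 (per year) and
#'   log-slope (per year of age)
#' @param kappa_t2dm excess-mortality multiplier for diabetics (>= 1)
#' @param entry_scale,entry_trend entry rate (persons/year) into band 1 at
#'   `ref_year` and its exponential trend
#' @param entry_sex_split fraction of entrants who are male
#' @param entry_profile_mix length-8 fractions over the risk-profile
#'   lattice, summing to 1
#' @param ref_year calendar year at which trends are anchored
#' @return object of class `nh_params`
#' @export
natural_history_params <- function(lambda_a = c(female = -4.5, male = -4.5),
                                   lambda_b = c(female = 0.8, male = 0.8),
                                   lambda_c = c(female = -0.15, male = -0.15),
                                   lambda_trend = 0.02,
                                   lambda_trend2 = 0,
                                   lambda_trend3 = 0,
                                   rr_obese = 3.6,
                                   rr_inactive = 1.3,
                                   rr_smoker = 1.4,
                                   alpha_obese = 0.0566,
                                   omega_obese = 0.05,
                                   alpha_inactive = 0.0869,
                                   omega_inactive = 0.10,
                                   alpha_smoker = 0.0261,
                                   omega_smoker = 0.10,
                                   alpha_obese_scale = 1,
                                   mu_scale = 0.002,
                                   mu_slope = 0.085,
                                   kappa_t2dm = 1.5,
                                   entry_scale = 3500,
                                   entry_trend = 0.013,
                                   entry_sex_split = 0.5,
                                   entry_profile_mix = NULL,
                                   ref_year = 2021) {
  two <- function(x, nm) {
    if (length(x) == 1L) x <- c(female = unname(x), male = unname(x))
    if (length(x) != 2L) stop_field(nm, "must have length 1 or 2")
    if (is.null(names(x))) names(x) <- SEXES
    x[SEXES]
  }
  if (is.null(entry_profile_mix)) {
    entry_profile_mix <- profile_mix(0.35, 0.465, 0.207)
  }
  p <- list(
    lambda_a = two(lambda_a, "lambda_a"),
    lambda_b = two(lambda_b, "lambda_b"),
    lambda_c = two(lambda_c, "lambda_c"),
    lambda_trend = lambda_trend, lambda_trend2 = lambda_trend2,
    lambda_trend3 = lambda_trend3,
    rr_obese = rr_obese, rr_inactive = rr_inactive, rr_smoker = rr_smoker,
    alpha_obese = alpha_obese, omega_obese = omega_obese,
    alpha_inactive = alpha_inactive, omega_inactive = omega_inactive,
    alpha_smoker = alpha_smoker, omega_smoker = omega_smoker,
    alpha_obese_scale = alpha_obese_scale,
    mu_scale = mu_scale, mu_slope = mu_slope, kappa_t2dm = kappa_t2dm,
    entry_scale = entry_scale, entry_trend = entry_trend,
    entry_sex_split = entry_sex_split,
    entry_profile_mix = entry_profile_mix,
    ref_year = ref_year
  )
  class(p) <- "nh_params"
  validate_params(p)
  p
}

validate_params <- function(p) {
  rates <- c("alpha_obese", "omega_obese", "alpha_inactive", "omega_inactive",
             "alpha_smoker", "omega_smoker", "alpha_obese_scale",
             "mu_scale", "entry_scale")
  for (f in rates)
    if (!is.finite(p[[f]]) || p[[f]] < 0)
      stop_field(f, "must be a finite non-negative rate")
  for (f in c("rr_obese", "rr_inactive", "rr_smoker", "kappa_t2dm"))
    if (!is.finite(p[[f]]) || p[[f]] < 1)
      stop_field(f, "must be >= 1")
  if (abs(sum(p$entry_profile_mix) - 1) > 1e-9)
    stop_field("entry_profile_mix", "must sum to 1")
  if (any(p$entry_profile_mix < 0))
    stop_field("entry_profile_mix", "must be non-negative")
  invisible(p)
}

#' Risk-profile mix under factor independence
#'
#' @param p_obese,p_inactive,p_smoker marginal prevalences
#' @return length-8 vector over the profile lattice summing to 1
#' @export
profile_mix <- function(p_obese, p_inactive, p_smoker) {
  marg <- cbind(p_obese, p_inactive, p_smoker)
  mix <- apply(PROFILE_FLAGS, 1L, function(fl)
    prod(ifelse(fl == 1, marg, 1 - marg)))
  mix / sum(mix)
}

#' Baseline hazard of T2DM onset, free of risk factors
#'
#' @param params `nh_params`
#' @param sex `"female"` or `"male"` (vectorized)
#' @param age age in years (vectorized)
#' @param t calendar year (applies the secular trend); default `ref_year`
#' @return hazard per person-year
#' @export
lambda0 <- function(params, sex, age, t = params$ref_year) {
  z <- (age - 45) / 10
  dt <- t - params$ref_year
  exp(params$lambda_a[sex] + params$lambda_b[sex] * z +
        params$lambda_c[sex] * z^2 +
        params$lambda_trend * dt + params$lambda_trend2 * dt^2 +
        params$lambda_trend3 * dt^3)
}

#' T2DM onset hazard for a risk profile
#'
#' Multiplies the baseline hazard by the relative risk of every factor
#' present and by an intervention effect multiplier (an IRR/RR in (0, 1]).
#'
#' @param profile logical/0-1 vector `c(obese=, inactive=, smoker=)` or a
#'   profile index 1-8
#' @param sex,age_band stratum
#' @param params `nh_params`
#' @param effect_multiplier intervention incidence multiplier in (0, 1]
#' @return hazard per person-year
#' @export
incidence_hazard <- function(profile, sex, age_band, params,
                             effect_multiplier = 1) {
  if (effect_multiplier <= 0 || effect_multiplier > 1)
    stop_field("effect_multiplier", "must be in (0, 1]")
  if (length(profile) == 1L && is.numeric(profile) && profile >= 1 && profile <= 8)
    profile <- PROFILE_FLAGS[profile, ]
  age <- band_midpoints()[age_band]
  base <- lambda0(params, sex, age)
  if (any(!is.finite(base)) || any(base <= 0))
    stop_field("lambda0", "baseline hazard must be positive and finite")
  rr <- params$rr_obese^profile[[1]] * params$rr_inactive^profile[[2]] *
    params$rr_smoker^profile[[3]]
  unname(base * rr * effect_multiplier)
}

rr_products <- function(params) {
  apply(PROFILE_FLAGS, 1L, function(fl)
    params$rr_obese^fl[1] * params$rr_inactive^fl[2] * params$rr_smoker^fl[3])
}

mu_by_band <- function(params) {
  mids <- band_midpoints()
  mu <- params$mu_scale * exp(params$mu_slope * (mids - 50))
  rbind(female = mu, male = mu)
}

#' Default parameters consistent with the baseline anchors
#'
#' Builds an `nh_params` whose fixed components are made self-consistent
#' with a [baseline_config()]:
#' \itemize{
#'   \item inactivity and smoking transition rates are set to hold their
#'     target prevalences at equilibrium at the chosen turnover;
#'   \item the obesity acquisition base rate is set to the 2021 equilibrium
#'     value (the calibrated `alpha_obese_scale` supplies any drift);
#'   \item the mortality scale is solved so the aggregate diabetic exit rate
#'     (mortality x `kappa_t2dm` plus ageing out of band 20) at the 2021
#'     synthetic age/prevalence structure matches the exit rate implied by
#'     the published case-count anchors (see [implied_burden_path()]) — the
#'     incidence anchors are unreachable from a prevalence-only calibration
#'     without this consistency;
#'   \item the entry rate is initialized from the population growth balance.
#' }
#' The calibrated parameters (hazard coefficients, trend, obesity scale,
#' entry rates) are set to reasonable starting values here and refined by
#' [fit_parameters()].
#'
#' @param config a [baseline_config()]
#' @return `nh_params`
#' @export
default_natural_history <- function(config = baseline_config()) {
  path <- implied_burden_path(config)
  struct <- consistent_structure(config)
  y0 <- baseline_cross_section(config, struct)
  w <- y0$population / sum(y0$population)
  mids <- band_midpoints()[y0$age_band]

  # inactivity / smoking at equilibrium (turnover 0.10 / yr)
  turn <- 0.10
  pI <- config$inactivity_prev_2023
  pS <- config$smoking_prev_2023
  alpha_inactive <- pI / (1 - pI) * turn
  alpha_smoker <- pS / (1 - pS) * turn
  q0 <- sum(w * y0$obesity_prev)
  omega_obese <- 0.05
  alpha_obese <- q0 / (1 - q0) * omega_obese

  # mortality from the structure; entry from the start-year balance
  mu_scale <- struct$mu_scale
  mu_slope <- struct$mu_slope
  kappa <- struct$kappa
  mueff <- struct$mu * (1 + (kappa - 1) * struct$prev0)
  n_j <- config$pop_20_79_start * struct$w_age
  deaths0 <- sum(mueff * n_j)
  entry_scale <- max(struct$pop_growth * config$pop_20_79_start + deaths0 +
                       n_j[N_BANDS] / BAND_WIDTH, 1)
  entry_trend <- struct$pop_growth

  p <- natural_history_params(
    alpha_obese = alpha_obese, omega_obese = omega_obese,
    alpha_inactive = alpha_inactive, omega_inactive = turn,
    alpha_smoker = alpha_smoker, omega_smoker = turn,
    mu_scale = mu_scale, mu_slope = mu_slope, kappa_t2dm = kappa,
    entry_scale = entry_scale, entry_trend = entry_trend,
    entry_sex_split = config$sex_ratio,
    entry_profile_mix = profile_mix(
      y0$obesity_prev[y0$age_band == 1][1],
      y0$inactivity_prev[y0$age_band == 1][1],
      y0$smoking_prev[y0$age_band == 1][1]),
    ref_year = config$start_year
  )

  # hazard age polynomial starts at the structure's onset shape (the same
  # log-quadratic family)
  z <- (band_midpoints() - 45) / 10
  p$lambda_b[] <- config$t2dm_hazard_b
  p$lambda_c[] <- config$t2dm_hazard_c

  # hazard intercept so model incidence at 2021 matches the implied path
  rrp <- rr_products(p)
  st <- initial_state(y0, p)
  X <- st$counts
  shape <- exp(p$lambda_b[1] * z + p$lambda_c[1] * z^2)
  sus <- apply(X[, , , 1L, 1L, drop = FALSE], c(2L, 3L), sum)  # [band, profile]
  denom <- sum(shape * (sus %*% rrp))
  p$lambda_a[] <- log(path$incidence(0.5) / denom)
  # trend initial guess: incidence log-path net of population growth
  p$lambda_trend <- path$B - path$pop_growth
  p$lambda_trend2 <- min(max(path$g, -0.004), 0.004)
  p
}

#' @export
print.nh_params <- function(x, ...) {
  cat("<nh_params>\n")
  cat(sprintf("  lambda0(45y): %.4f/yr, age slope b=%.3f c=%.3f, trend %.4f/yr\n",
              exp(x$lambda_a[1]), x$lambda_b[1], x$lambda_c[1], x$lambda_trend))
  cat(sprintf("  RR obese %.2f / inactive %.2f / smoker %.2f; kappa %.2f\n",
              x$rr_obese, x$rr_inactive, x$rr_smoker, x$kappa_t2dm))
  cat(sprintf("  mortality at 50: %.4f/yr; entry %.0f/yr (trend %.4f)\n",
              x$mu_scale, x$entry_scale, x$entry_trend))
  invisible(x)
}
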