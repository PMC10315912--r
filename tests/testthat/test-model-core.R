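test_that("incidence hazard composes multiplicatively over risk factors", {
  p <- natural_history_params(lambda_a = log(0.01), lambda_b = 0,
                              lambda_c = 0, lambda_trend = 0,
                              lambda_trend2 = 0, lambda_trend3 = 0,
                              rr_obese = 4, rr_inactive = 1.3,
                              rr_smoker = 1.4)
  ob <- c(obese = 1, inactive = 0, smoker = 0)
  expect_equal(incidence_hazard(ob, "female", 5, p), 0.04)
  expect_equal(incidence_hazard(ob, "female", 5, p, 0.70), 0.028)
  none <- c(obese = 0, inactive = 0, smoker = 0)
  expect_equal(incidence_hazard(none, "male", 12, p), 0.01)
  both <- c(obese = 1, inactive = 1, smoker = 0)
  expect_equal(incidence_hazard(both, "male", 12, p), 0.01 * 4 * 1.3)
  expect_error(incidence_hazard(ob, "female", 5, p, 0), "effect_multiplier")
  expect_error(incidence_hazard(ob, "female", 5, p, 1.2), "effect_multiplier")
})

test_that("a closed system conserves the population over 30 years", {
  # people exit the modeled range at 80 by design, so closure is checked
  # through the explicit mass balance: population + cumulative ageing-out
  # (no entry, no mortality) must stay at the initial total
  p <- toy_params(lambda = 0.02)
  st <- toy_state(rep(1000, 20))
  traj <- simulate_model(st, p, t0 = 2021, t1 = 2051)
  mb <- mass_balance(traj)
  expect_lt(max(abs(mb$balance_error)), 1e-6)
  expect_equal(mb$cum_entry[31], 0)
  expect_equal(mb$cum_deaths[31], 0)
  # totals never increase (outflow only through band 20)
  expect_true(all(diff(mb$population) <= 1e-9 * mb$population[1]))
  # the open calibrated baseline obeys the same balance identity
  expect_lt(max(abs(mass_balance(fx_baseline_traj())$balance_error)), 1e-6)
})

test_that("uniform hazard reproduces the exponential-decay closed form", {
  lam <- 0.05
  p <- toy_params(lambda = lam)
  # mass only in bands 1-3 so that nobody reaches the age-80 exit within
  # the test horizon and the single-cohort closed form applies exactly
  st <- toy_state(c(rep(1000, 3), rep(0, 17)))
  traj <- simulate_model(st, p, t0 = 2021, t1 = 2029)
  S0 <- sum(st$counts[, , , 1L, ])
  for (y in c(2024, 2027, 2029)) {
    cnt <- state_at(traj, y)$counts
    S <- sum(cnt[, , , 1L, ])
    expect_equal(S, S0 * exp(-lam * (y - 2021)), tolerance = 1e-6)
    # aggregate prevalence is 1 - exp(-lambda t) under uniform hazard
    expect_equal(prevalence(traj, y), 1 - exp(-lam * (y - 2021)),
                 tolerance = 1e-6)
  }
  # annual new cases in year one: P (1 - exp(-lambda))
  expect_equal(annual_new_cases(traj, 2021), S0 * (1 - exp(-lam)),
               tolerance = 1e-6)
  # zero hazard everywhere gives zero cases
  p0 <- toy_params(lambda = 1e-12)
  tr0 <- simulate_model(st, p0, t0 = 2021, t1 = 2026)
  expect_lt(annual_new_cases(tr0, 2023), 1e-6)
})

test_that("the adaptive solver agrees with an independent Euler oracle", {
  p <- attr(fx_targets(), "true_params")
  st <- initial_state(fx_targets(), p)
  traj <- simulate_model(st, p, t0 = 2021, t1 = 2026)
  orc <- euler_baseline(st, p, 2021, 2026, dt = 5e-4)
  expect_equal(population_size(traj, 2026), orc$total, tolerance = 1e-4)
  expect_equal(prevalence(traj, 2026), orc$prevalence, tolerance = 1e-4)
  cnt <- state_at(traj, 2026)$counts
  expect_equal(sum(cnt[, , , 2L, ]), sum(orc$D), tolerance = 1e-4)
})

test_that("trajectories preserve non-negativity and admit no remission", {
  traj <- fx_baseline_traj()
  tot <- population_size(traj, 2021)
  for (y in seq(2021, 2051, by = 5))
    expect_gt(min(state_at(traj, y)$counts), -1e-9 * tot)
  # diabetics in a mortality-free, exit-free cohort never decrease
  p <- toy_params(lambda = 0.03)
  st <- toy_state(c(rep(1000, 3), rep(0, 17)))
  tr <- simulate_model(st, p, t0 = 2021, t1 = 2031)
  dia <- vapply(2021:2031, function(y) prevalent_cases(tr, y), 0)
  expect_true(all(diff(dia) > -1e-9))
})

test_that("trajectory accessors validate their inputs", {
  traj <- fx_baseline_traj()
  expect_error(annual_new_cases(traj, 2051), "horizon")
  expect_error(annual_new_cases(traj, 1999), "horizon")
  expect_error(prevalence(traj, 2030, age_range = c(200, 300)), "empty")
  st <- toy_state(rep(0, 20))
  expect_error(prevalence(st), "population")
  # zero-length horizon returns the initial state
  st2 <- toy_state(rep(100, 20))
  tr0 <- simulate_model(st2, toy_params(), t0 = 2021, t1 = 2021)
  expect_equal(state_at(tr0, 2021)$counts, st2$counts)
  # corrupt input state
  bad <- st2; bad$counts[1] <- NaN
  expect_error(simulate_model(bad, toy_params(), t0 = 2021, t1 = 2022),
               "non-finite")
})

test_that("trajectory export writes consistent aggregate tables", {
  traj <- fx_baseline_traj()
  f <- tempfile(fileext = ".csv")
  out <- export_trajectory(traj, path_aggregate = f)
  expect_true(file.exists(f))
  agg <- read.csv(f)
  expect_equal(nrow(agg), 30)
  expect_equal(agg$prevalence[1], prevalence(traj, 2021), tolerance = 1e-12)
  expect_equal(agg$annual_new_cases[30], annual_new_cases(traj, 2050),
               tolerance = 1e-12)
})
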