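# minimal hand-built trajectory with prescribed annual new cases and
# constant population/prevalence
fake_traj <- function(new_cases, pop = 1000, dia = 100) {
  ny <- length(new_cases)
  times <- 2021:(2021 + ny)
  counts <- array(0, c(ny + 1L, 2, 20, 8, 2, 1))
  counts[, 1, 1, 1, 1, 1] <- pop - dia
  counts[, 1, 1, 1, 2, 1] <- dia
  cum <- array(0, c(ny + 1L, 2, 20))
  cum[, 1, 1] <- cumsum(c(0, new_cases))
  flows <- matrix(0, ny + 1L, 3,
                  dimnames = list(NULL, c("entry", "deaths", "aged_out")))
  structure(list(times = times, counts = counts, cum = cum, flows = flows,
                 dims = c(2L, 20L, 8L, 2L, 1L), params = NULL,
                 scenarios = list()),
            class = "trajectory")
}

test_that("counterfactual comparison does the averted-case arithmetic", {
  base <- fake_traj(c(100, 100))
  intv <- fake_traj(c(90, 80))
  res <- compare_trajectories(base, intv)
  expect_equal(res$cum_averted, c(10, 30))
  expect_equal(res$prop_averted, c(0.1, 0.15))
  expect_equal(res$prevalence_reduction_pp, c(0, 0))
  # identical trajectories avert nothing
  res0 <- compare_trajectories(base, base)
  expect_true(all(res0$cum_averted == 0))
  expect_true(all(res0$prop_averted == 0))
  expect_error(compare_trajectories(base, fake_traj(c(1, 2, 3))),
               "mismatched")
})

test_that("a null intervention is equivalent to the counterfactual", {
  null_spec <- intervention_spec("null", 0.5, 0.5, 2021, 2025)
  res <- run_scenario(null_spec, fx_fit()$params, fx_targets(),
                      control = list(method = "lsoda", rtol = 1e-12, atol = 1e-8))
  expect_lt(max(abs(res$prop_averted)), 1e-8)
  expect_lt(max(abs(res$prevalence_baseline - res$prevalence_intervention) /
                  res$prevalence_baseline), 1e-8)
  expect_lt(max(abs(res$new_cases_baseline - res$new_cases_intervention) /
                  res$new_cases_baseline), 1e-8)
})

test_that("averted cases accumulate monotonically and respect the IRR bound", {
  res <- fx_scenario("fruit_veg")
  expect_true(all(diff(res$cum_averted) > -1e-9))
  expect_true(all(res$prop_averted >= 0 & res$prop_averted <= 1))
  # cannot avert a larger share than the hazard reduction among the covered
  expect_lt(res$prop_averted[nrow(res)], 1 - 0.93)
})

test_that("unknown scenarios are rejected with the available ids listed", {
  expect_error(run_scenario("teleportation", fx_fit()$params, fx_targets()),
               "available.*lifestyle_obese")
})

test_that("sensitivity sweeps reproduce single runs and expose monotonicity", {
  p <- fx_fit()$params
  tg <- fx_targets()
  base <- fx_scenario("fruit_veg")
  one <- sensitivity_sweep("incidence_multiplier", 0.93, "fruit_veg", p, tg)
  expect_equal(one$cum_averted_2050, base$cum_averted[nrow(base)],
               tolerance = 1e-6)
  # zero uptake averts nothing
  z <- sensitivity_sweep("uptake", 0, "fruit_veg", p, tg)
  expect_lt(abs(z$prop_averted_2050), 1e-7)
  # averted cases strictly decreasing in the IRR
  sw <- sensitivity_sweep("incidence_multiplier", c(0.6, 0.7, 0.8),
                          "fruit_veg", p, tg)
  expect_true(all(diff(sw$cum_averted_2050) < 0))
  expect_true(attr(sw, "monotone"))
  expect_error(sensitivity_sweep("warp_factor", 1, "fruit_veg", p, tg),
               "unknown parameter")
})
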