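test_that("a target equal to the unforced prevalence needs zero forcing", {
  p <- fx_fit()$params
  tg <- fx_targets()
  st <- initial_state(tg, p, n_scenarios = 1)
  base <- simulate_model(st, p,
                         list(intervention_spec("n", 0.2, 1, 2021, 2030)),
                         t0 = 2021, t1 = 2030)
  b30 <- obesity_prevalence_sim(base, 2030)
  sp <- intervention_spec("n", 0.2, 1, 2021, 2030,
                          obesity_prev_target = round(b30 + 0.002, 4))
  fr <- solve_obesity_forcing(list(sp), st, p)
  expect_equal(fr$groups[[1]]$multiplier, 0)
  expect_equal(fr$groups[[1]]$achieved, b30, tolerance = 1e-3)
})

test_that("lower obesity targets need strictly larger forcing multipliers", {
  p <- fx_fit()$params
  tg <- fx_targets()
  st <- initial_state(tg, p, n_scenarios = 1)
  mults <- vapply(c(0.52, 0.50, 0.48), function(tgt) {
    sp <- intervention_spec("g", 1, 1, 2021, 2030,
                            obesity_prev_target = tgt)
    fr <- solve_obesity_forcing(list(sp), st, p)
    expect_equal(fr$groups[[1]]$achieved, tgt, tolerance = 1e-3)
    fr$groups[[1]]$multiplier
  }, 0)
  expect_true(all(diff(mults) > 0))
})

test_that("unreachable targets raise an infeasibility error", {
  p <- fx_fit()$params
  st <- initial_state(fx_targets(), p, n_scenarios = 1)
  sp <- intervention_spec("tiny", 0.01, 1, 2021, 2030,
                          obesity_prev_target = 0.05)
  expect_error(solve_obesity_forcing(list(sp), st, p),
               "closest achievable")
})
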