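test_that("effective coverage is the product of uptake and adherence", {
  sp <- intervention_spec("a", 0.5, 0.5, 2021, 2025)
  expect_equal(effective_coverage(sp), 0.25)
  expect_equal(effective_coverage(intervention_spec("b", 0.4, 1, 2021, 2030)),
               0.40)
  expect_equal(effective_coverage(intervention_spec("c", 0, 1, 2021, 2030)), 0)
})

test_that("the coverage ramp is linear and saturates at the target", {
  sp <- intervention_spec("lifestyle", 0.5, 0.5, 2021, 2025)
  expect_equal(coverage_ramp(2021, sp), 0)
  expect_equal(coverage_ramp(2023, sp), 0.125)
  expect_equal(coverage_ramp(2025, sp), 0.25)
  expect_equal(coverage_ramp(2040, sp), 0.25)
  expect_equal(coverage_ramp(2015, sp), 0)
})

test_that("recruitment tracks the ramp in a single-compartment integration", {
  sp <- intervention_spec("x", 0.5, 0.5, 2021, 2025)
  f <- 0; dt <- 0.001
  for (t in seq(2021, 2025 - dt, by = dt))
    f <- f + dt * recruitment_rate(t, sp, f) * (1 - f)
  expect_lt(abs(f - 0.25), 1e-3)
  # before the ramp and at target the rate is zero
  expect_equal(recruitment_rate(2019, sp, 0), 0)
  expect_equal(recruitment_rate(2030, sp, 0.25), 0)
  expect_warning(r <- recruitment_rate(2023, sp, 1), "covered fraction")
  expect_equal(r, 0)
})

test_that("the packaged scenario library mirrors the study design", {
  lib <- scenario_library()
  expect_length(lib, 12)
  expect_false(anyDuplicated(names(lib)) > 0)
  up <- vapply(lib, `[[`, 0, "uptake")
  ad <- vapply(lib, `[[`, 0, "adherence")
  expect_equal(unname(up),
               c(0.5, 0.5, 0.5, 0.4, 0.2, 0.5, 0.5, 0.5, 0.5, 0.2, 0.2, 0.2))
  expect_equal(unname(ad), c(0.5, 0.5, 0.5, rep(1, 9)))
  ramps <- t(vapply(lib, function(s) c(s$ramp_start, s$ramp_end), c(0, 0)))
  expect_true(all(ramps[1:3, 2] == 2025))  # lifestyle scale-up 2021-2025
  expect_true(all(ramps[4:12, 2] == 2030)) # all others 2021-2030
  expect_true(all(ramps[, 1] == 2021))
  # incidence effects
  irr <- vapply(lib, `[[`, 0, "incidence_multiplier")
  expect_equal(unname(irr[c("fruit_veg", "vegetables", "leafy_greens",
                            "cycling_walking", "workplace_diet")]),
               c(0.93, 0.90, 0.87, 0.76, 0.93))
  expect_true(all(irr[1:3] == 0.70))
  # obesity endpoints
  tgt <- vapply(lib, function(s) s$obesity_prev_target %||% NA_real_, 0)
  expect_equal(unname(tgt[c("public_transport", "cycling_walking",
                            "workplace_diet", "subsidies_fv", "ssb_tax",
                            "subsidies_ssb_tax")]),
               c(0.509, 0.504, 0.348, 0.526, 0.523, 0.516))
  expect_identical(lib$workplace_diet$obesity_scope, "covered")
  expect_true(lib$public_transport$normalize_inactivity)
  # eligibility windows
  expect_equal(lib$lifestyle_age50$filter$min_band, 11)   # age >= 50
  expect_equal(lib$lifestyle_obese_35plus$filter$min_band, 6)  # age >= 35
  expect_true(lib$lifestyle_obese$filter$require_obese)
  expect_equal(lib$workplace_diet$filter$max_band, 15)    # working age 20-65
})

test_that("combination packages bundle the stated scenarios", {
  most <- build_package("most_optimistic")
  least <- build_package("least_optimistic")
  expect_equal(vapply(most, `[[`, "", "id"),
               c("lifestyle_obese_35plus", "cycling_walking",
                 "workplace_diet", "subsidies_ssb_tax"))
  expect_equal(vapply(least, `[[`, "", "id"),
               c("lifestyle_obese", "public_transport", "fruit_veg",
                 "subsidies_fv"))
  expect_length(intersect(vapply(most, `[[`, "", "id"),
                          vapply(least, `[[`, "", "id")), 0)
  for (sp in c(most, least)) expect_s3_class(sp, "intervention_spec")
  expect_error(build_package("mediocre"), "one of")
})

test_that("effects compose multiplicatively for covered compartments", {
  lib <- scenario_library()
  specs <- list(lib$workplace_diet, lib$lifestyle_obese_35plus)
  # obese 41-43 year-old (band 8), covered by both
  eff <- apply_effects("female", 8, c(obese = 1, inactive = 0, smoker = 0),
                       "susceptible", specs, covered = c(TRUE, TRUE))
  expect_equal(eff$incidence_multiplier, 0.93 * 0.70)
  # uncovered compartment is untouched
  eff0 <- apply_effects("female", 8, 2, "susceptible", specs,
                        covered = c(FALSE, FALSE))
  expect_equal(eff0$incidence_multiplier, 1)
  # covered but outside the filter (non-obese for the lifestyle scenario)
  eff1 <- apply_effects("female", 8, 1, "susceptible", specs,
                        covered = c(TRUE, TRUE))
  expect_equal(eff1$incidence_multiplier, 0.93)
  # cycling alone
  eff2 <- apply_effects("male", 10, 1, "susceptible",
                        list(lib$cycling_walking), covered = TRUE)
  expect_equal(eff2$incidence_multiplier, 0.76)
  # duplicate ids are a configuration error
  expect_error(apply_effects("male", 10, 1, "susceptible",
                             list(lib$fruit_veg, lib$fruit_veg)),
               "duplicate")
})

test_that("scenario specifications are validated", {
  expect_error(intervention_spec("x", 1.5, 1, 2021, 2030), "uptake")
  expect_error(intervention_spec("x", 0.5, 1, 2030, 2021), "ramp_start")
  expect_error(intervention_spec("x", 0.5, 1, 2021, 2060,
                                 horizon_end = 2050), "ramp_end")
  expect_error(intervention_spec("x", 0.5, 1, 2021, 2030,
                                 incidence_multiplier = 0), "incidence")
  expect_error(intervention_spec("x", 0.5, 1, 2021, 2030,
                                 min_age = 75, max_age = 76), "max_age")
})
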