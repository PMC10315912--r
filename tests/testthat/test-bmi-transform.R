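test_that("normal-tail obesity prevalence matches a quadrature oracle", {
  expect_equal(bmi_obesity_prevalence(bmi_distribution(30, 4.7)), 0.5)
  expect_lt(bmi_obesity_prevalence(bmi_distribution(10, 3)), 1e-6)
  for (m in c(25, 27.5, 29, 31)) for (s in c(3, 6, 9.3)) {
    dist <- bmi_distribution(m, s)
    oracle <- integrate(function(x) dnorm(x, m, s), 30, Inf,
                        rel.tol = 1e-10)$value
    expect_equal(bmi_obesity_prevalence(dist), oracle, tolerance = 1e-6)
  }
})

test_that("prevalence after a shift is a mixture, decreasing in its inputs", {
  dist <- bmi_distribution(29, 6)
  expect_equal(bmi_prevalence_after_shift(dist, 0), bmi_obesity_prevalence(dist))
  expect_equal(bmi_prevalence_after_shift(dist, 2, 0),
               bmi_obesity_prevalence(dist))
  deltas <- seq(0, 3, by = 0.25)
  vals <- vapply(deltas, function(d) bmi_prevalence_after_shift(dist, d), 0)
  expect_true(all(diff(vals) < 0))
  fr <- vapply(seq(0, 1, by = 0.1), function(f)
    bmi_prevalence_after_shift(dist, 1.5, f), 0)
  expect_true(all(diff(fr) < 0))
  expect_true(all(vals >= 0 & vals <= 1))
  expect_true(all(vals <= bmi_obesity_prevalence(dist) + 1e-12))
  expect_error(bmi_prevalence_after_shift(dist, -1), "delta")
})

test_that("implied sd inverts the shift mapping", {
  sd_star <- bmi_implied_sd(0.533, 0.509, 0.51)
  dist <- bmi_distribution(30 - qnorm(1 - 0.533) * sd_star, sd_star)
  expect_equal(bmi_prevalence_after_shift(dist, 0.51), 0.509,
               tolerance = 1e-6)
  expect_error(bmi_implied_sd(0.5, 0.6, 1), "p1")
  expect_error(bmi_implied_sd(0.533, 0.509, 0), "delta")
})

test_that("the subsidy endpoint pairs imply mutually close sd values", {
  audit <- audit_bmi_endpoints()
  expect_s3_class(audit, "data.frame")
  sub <- audit[audit$id %in% c("subsidies_fv", "ssb_tax",
                               "subsidies_ssb_tax"), ]
  expect_equal(nrow(sub), 3)
  expect_true(all(is.finite(sub$implied_sd)))
  # mutual consistency of the three fiscal-scenario pairs: spread under 15%
  expect_lt(max(sub$implied_sd) / min(sub$implied_sd), 1.15)
  # the active-commuting pairs are not consistent with the same model,
  # which is why scenario runs consume the endpoints directly
  cyc <- audit$implied_sd[audit$id == "cycling_walking"]
  expect_gt(cyc / mean(sub$implied_sd), 1.5)
})
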