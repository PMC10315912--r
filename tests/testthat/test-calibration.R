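test_that("calibration recovers the generating parameters", {
  fit <- fx_fit()
  truth <- attr(fx_targets(), "true_params")
  expect_true(fit$converged)
  # hazard level and obesity acquisition scale recovered within 1%
  expect_equal(exp(fit$params$lambda_a[[1]]), exp(truth$lambda_a[[1]]),
               tolerance = 0.01)
  expect_equal(fit$params$alpha_obese_scale, truth$alpha_obese_scale,
               tolerance = 0.01)
  expect_equal(fit$params$lambda_trend, truth$lambda_trend,
               tolerance = 0.01)
  # residual surfaces are essentially flat
  expect_lt(max(abs(fit$residuals$t2dm)), 0.02)       # pp
  expect_lt(max(abs(fit$residuals$population)), 0.02) # percent
})

test_that("starting at the truth is a fixed point of the fit", {
  truth <- attr(fx_targets(), "true_params")
  spec <- fit_spec(n_starts = 1)
  fit <- fit_parameters(fx_targets(), spec, initial = truth)
  expect_true(fit$converged)
  expect_lt(fit$rss, 1e-4)
  # refitting from the fitted optimum does not move the loss
  fit2 <- fit_parameters(fx_targets(), spec, initial = fit$params)
  expect_lt(abs(fit2$rss - fit$rss), 1e-6 + 1e-6 * fit$rss)
})

test_that("the optimizer's loss trace is essentially monotone", {
  tr <- fx_fit()$rss_trace
  expect_gt(length(tr), 0)
  # the trust-region iterations drive the loss down; the recorded trace can
  # tick up marginally where bound projection intervenes, so interior
  # increases must be negligible against the total decrease
  total_drop <- tr[1] - tr[length(tr)]
  expect_gt(total_drop, 0)
  expect_lt(max(c(diff(tr), 0)), 0.01 * total_drop)
  expect_lte(tr[length(tr)], min(tr) + 1e-12)
})

test_that("residual report localizes a perturbed target cell", {
  fit <- fx_fit()
  rep0 <- residual_report(fit, fx_targets())
  expect_true(all(c("sex", "age_band", "year", "family", "residual") %in%
                    names(rep0)))
  prev_rows <- rep0[rep0$family == "t2dm", ]
  expect_lt(max(abs(prev_rows$residual)), 5e-3)

  tg2 <- fx_targets()
  i <- which(tg2$year == 2035 & tg2$sex == "male" & tg2$age_band == 10)
  tg2$t2dm_prev[i] <- tg2$t2dm_prev[i] + 0.05
  rep1 <- residual_report(fit, tg2)
  t2 <- rep1[rep1$family == "t2dm", ]
  worst <- t2[which.max(abs(t2$residual)), ]
  expect_equal(worst$year, 2035)
  expect_equal(worst$age_band, 10)
  expect_identical(worst$sex, "male")
})

test_that("fit specifications are validated", {
  expect_error(fit_spec(free = "not_a_parameter"), "unknown free parameter")
  expect_error(fit_spec(bounds = list(lambda_a = c(2, 1))), "lambda_a")
  expect_error(fit_spec(weights = c(t2dm = -1)), "weights")
})
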