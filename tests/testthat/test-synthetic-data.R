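test_that("generated targets reproduce the aggregate burden anchors", {
  cfg <- fx_config()
  ag <- aggregate_targets(fx_targets())
  expect_equal(ag$t2dm_prev[ag$year == 2021], 0.171, tolerance = 1e-6)
  expect_equal(ag$t2dm_prev[ag$year == 2050], 0.295, tolerance = 2e-3)
  expect_equal(ag$population[ag$year == 2021], 33821 / 0.171,
               tolerance = 1e-6)
  expect_equal(ag$population[ag$year == 2050], 84516 / 0.295,
               tolerance = 2e-3)
  expect_equal(ag$obesity_prev[ag$year == 2030], 0.533, tolerance = 1e-3)
  expect_equal(ag$obesity_prev[ag$year == 2023], 0.531, tolerance = 5e-3)
  expect_equal(ag$inactivity_prev[ag$year == 2023], 0.465, tolerance = 1e-3)
  expect_equal(ag$smoking_prev[ag$year == 2023], 0.207, tolerance = 1e-3)
  # prevalent-case anchors
  d21 <- subset(fx_targets(), year == 2021)
  expect_equal(sum(d21$population * d21$t2dm_prev), 33821, tolerance = 1e-6)
  d50 <- subset(fx_targets(), year == 2050)
  expect_equal(sum(d50$population * d50$t2dm_prev), 84516, tolerance = 5e-3)
})

test_that("the generating model run hits the incident-case anchors", {
  pt <- attr(fx_targets(), "true_params")
  expect_s3_class(pt, "nh_params")
  tr <- simulate_model(initial_state(fx_targets(), pt), pt,
                       t0 = 2021, t1 = 2051)
  expect_equal(annual_new_cases(tr, 2021), 2145, tolerance = 1e-3)
  expect_equal(annual_new_cases(tr, 2050), 3931, tolerance = 1e-3)
  cum <- sum(vapply(2021:2050, function(y) annual_new_cases(tr, y), 0))
  expect_equal(cum, mean(c(18619 / 0.228, 38379 / 0.469)), tolerance = 2e-3)
})

test_that("T2DM prevalence increases monotonically with age band", {
  tg <- fx_targets()
  for (y in c(2021, 2035, 2050)) {
    d <- subset(tg, year == y & sex == "female")
    d <- d[order(d$age_band), ]
    expect_true(all(diff(d$t2dm_prev[1:17]) > -1e-9),
                info = paste("year", y))
  }
})

test_that("degenerate equal anchors give a flat prevalence trajectory", {
  flat_cfg <- baseline_config(t2dm_prev_end = 0.171)
  tg <- generate_baseline(flat_cfg)
  ag <- aggregate_targets(tg)
  expect_lt(max(abs(ag$t2dm_prev - 0.171)), 0.005)
})

test_that("generation is deterministic and the CSV round trip is lossless", {
  cfg <- baseline_config(noise_sd = 0.01, seed = 7L)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_targets(generate_baseline(cfg), f1)
  # clear the memo so the second call recomputes from scratch
  rm(list = ls(t2dmsim:::.generator_cache), envir = t2dmsim:::.generator_cache)
  write_targets(generate_baseline(cfg), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  back <- read_targets(f1)
  orig <- generate_baseline(cfg)
  for (col in c("population", "t2dm_prev", "obesity_prev",
                "inactivity_prev", "smoking_prev"))
    expect_equal(back[[col]], orig[[col]], tolerance = 1e-9)
  expect_identical(back$sex, orig$sex)
  expect_identical(back$age_band, orig$age_band)
})

test_that("malformed targets files and configs are rejected with clear errors", {
  expect_error(baseline_config(t2dm_prev_start = 1.7), "t2dm_prev_start")
  expect_error(baseline_config(pop_20_79_start = -5), "pop_20_79_start")
  expect_error(baseline_config(start_year = 2050, end_year = 2021),
               "start_year")

  tg <- fx_targets()
  f <- tempfile(fileext = ".csv")
  write_targets(tg, f)
  # missing column
  d <- read.csv(f)
  write.csv(d[, setdiff(names(d), "sex")], f, row.names = FALSE)
  expect_error(read_targets(f), "sex")
  # non-numeric cell
  write_targets(tg, f)
  d <- read.csv(f, colClasses = "character")
  d$population[5] <- "oops"
  write.csv(d, f, row.names = FALSE)
  expect_error(read_targets(f), "population")
  # empty file
  file.create(f2 <- tempfile(fileext = ".csv"))
  expect_error(read_targets(f2), "empty")
  expect_error(read_targets(tempfile()), "no such file")
})
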