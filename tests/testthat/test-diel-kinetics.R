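test_that("multiplicative decomposition recovers trend and diel component", {
  # constant series: trend equals the constant, ratio is 1 in the interior
  d <- decompose_multiplicative(rep(5, 72), window = 24)
  interior <- !is.na(d$trend)
  expect_identical(which(interior), 13:60)
  expect_equal(d$trend[interior], rep(5, sum(interior)), tolerance = 1e-12)
  expect_equal(d$detrended[interior], rep(1, sum(interior)),
               tolerance = 1e-12)

  # exactly 24-h periodic component times a constant trend
  t <- 0:95
  periodic <- 1 + 0.4 * sin(2 * pi * t / 24)   # period mean exactly 1
  x <- 7 * periodic
  d2 <- decompose_multiplicative(x, window = 24)
  ok <- !is.na(d2$trend)
  expect_equal(d2$trend[ok], rep(7, sum(ok)), tolerance = 1e-9)
  expect_equal(d2$detrended[ok], periodic[ok], tolerance = 1e-9)
  expect_equal(d2$observed[ok], (d2$trend * d2$detrended)[ok])

  # missing hours knock out every window that contains them
  x_na <- x
  x_na[40] <- NA
  d3 <- decompose_multiplicative(x_na, window = 24)
  expect_true(all(is.na(d3$trend[28:52])))
  expect_false(anyNA(d3$trend[13:27]))

  expect_error(decompose_multiplicative(c(rep(2, 47), 0), window = 24),
               "positive")
  expect_error(decompose_multiplicative(rep(2, 40), window = 24),
               "two windows")
})

test_that("daylight windows come from interpolated threshold crossings", {
  cfg <- cruise_config(duration_days = 3, day_length_h = 12, par_peak = 2000)
  uw <- simulate_underway(cfg)
  w <- daylight_windows(uw$timestamp, uw$par, threshold = 10)
  expect_identical(nrow(w), 3L)
  # closed-form half-sine crossings: offset (L/pi) asin(thr/peak) each side
  offset <- (12 / pi) * asin(10 / 2000)
  expect_equal(w$daylight_hours, rep(12 - 2 * offset, 3), tolerance = 1e-2)
  expect_true(all(w$sunrise < w$sunset))

  # threshold 0 recovers the configured generator window exactly
  w0 <- daylight_windows(uw$timestamp, uw$par, threshold = 0)
  expect_equal(w0$daylight_hours, rep(12, 3), tolerance = 1e-9)
  hod <- as.numeric(w0$sunrise - trunc(w0$sunrise, "days"), units = "hours")
  expect_equal(hod, rep(cfg$sunrise_hour, 3), tolerance = 1e-9)

  # PAR identically zero: no windows; all-missing PAR: error
  expect_identical(nrow(daylight_windows(uw$timestamp, rep(0, nrow(uw)))), 0L)
  expect_error(daylight_windows(uw$timestamp, rep(NA_real_, nrow(uw))),
               "missing")
})

test_that("daily growth fit recovers a noiseless exponential exactly", {
  ts <- as.POSIXct("2020-01-01 00:00", tz = "UTC") + 3600 * (0:23)
  win <- tibble::tibble(date = as.Date("2020-01-01"),
                        sunrise = ts[7], sunset = ts[19],
                        daylight_hours = 12)
  r_h <- 0.03
  t_sr <- pmax(as.numeric(ts - ts[7], units = "hours"), 0)
  quota <- 0.04 * exp(r_h * pmin(t_sr, 12))
  data <- tibble::tibble(timestamp = ts, detrended = quota / 0.05,
                         trend = 0.05, abundance = 1)
  fit <- fit_daily_growth(data, win, population = "Prochlorococcus")
  expect_equal(fit$r_hourly, 0.03, tolerance = 1e-12)
  expect_equal(fit$r_daily, 0.36, tolerance = 1e-12)
  expect_equal(fit$q_c0, 0.04, tolerance = 1e-12)
  expect_identical(fit$n_obs, 13L)
  expect_lt(fit$p_value, 1e-12)
  expect_true(fit$accepted)

  # slope invariance: scaling the series only moves the intercept
  data2 <- data
  data2$detrended <- data$detrended * 3.7
  fit2 <- fit_daily_growth(data2, win, population = "Prochlorococcus")
  expect_equal(fit2$r_daily, fit$r_daily, tolerance = 1e-12)
  expect_equal(fit2$q_c0, 3.7 * fit$q_c0, tolerance = 1e-10)
})

test_that("acceptance filters require >6 usable hours and p <= 0.01", {
  ts <- as.POSIXct("2020-01-01 00:00", tz = "UTC") + 3600 * (0:23)
  win <- tibble::tibble(date = as.Date("2020-01-01"),
                        sunrise = ts[7], sunset = ts[15],
                        daylight_hours = 8)
  # constant quota over 8 usable hours: zero slope, p = 1, not accepted
  flat <- tibble::tibble(timestamp = ts, detrended = 1, trend = 0.05,
                         abundance = 1)
  f_flat <- fit_daily_growth(flat, win)
  expect_identical(f_flat$n_obs, 9L)
  expect_identical(f_flat$r_hourly, 0)
  expect_identical(f_flat$p_value, 1)
  expect_false(f_flat$accepted)

  # a perfect exponential on 5 usable hours is rejected by the n filter
  t_sr <- as.numeric(ts - ts[7], units = "hours")
  grow <- tibble::tibble(timestamp = ts,
                         detrended = exp(0.05 * pmax(t_sr, 0)),
                         trend = 0.05,
                         abundance = c(rep(1, 10), rep(0.001, 14)))
  f5 <- fit_daily_growth(grow, win)
  expect_identical(f5$n_obs, 4L)
  expect_false(f5$accepted)

  # acceptance monotonicity: dropping usable hours never turns an
  # unaccepted day into an accepted one
  for (keep in c(9, 7, 6, 3)) {
    d <- flat
    d$abundance[seq_len(nrow(d)) > keep + 6] <- 0.001
    expect_false(fit_daily_growth(d, win)$accepted)
  }

  # fewer than 2 usable points: reported, not an error
  none <- flat
  none$abundance <- 0.001
  f0 <- fit_daily_growth(none, win)
  expect_true(is.na(f0$r_daily))
  expect_false(f0$accepted)
})

test_that("pipeline-scale rate recovery is exact without noise", {
  cfg <- noiseless_config(duration_days = 6)
  cr <- simulate_cruise(cfg, seed = 31)
  red <- reduce_populations(cr$populations)
  fits <- estimate_growth(red, cr$underway, par_threshold = 0)
  tr <- merge(fits, cr$daily_truth, by = c("population", "date"))
  tr <- tr[!is.na(tr$r_daily), ]
  expect_gt(nrow(tr), 15)
  expect_lt(max(abs(tr$r_daily - tr$r_daily_true)), 1e-8)
  # GrowthFit invariant: r_daily = r_hourly * daylight_hours
  expect_equal(tr$r_daily, tr$r_hourly * tr$daylight_hours)
  # accepted flag consistent with its definition
  expect_identical(tr$accepted,
                   tr$n_obs > 6 & !is.na(tr$p_value) & tr$p_value <= 0.01)
})
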