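test_that("underway generator honours the configured track and diel cycle", {
  cfg <- cruise_config(duration_days = 10, salinity_noise_sd = 0)
  uw <- simulate_underway(cfg, seed = 1)
  expect_equal(nrow(uw), 240L)
  expect_true(all(diff(as.numeric(uw$timestamp)) == 3600))
  expect_true(all(uw$par >= 0))

  # PAR is positive exactly on the open daylight window
  hod <- (as.numeric(uw$timestamp - uw$timestamp[1]) / 3600) %% 24
  in_day <- hod > cfg$sunrise_hour & hod < cfg$sunrise_hour + cfg$day_length_h
  expect_identical(uw$par > 0, in_day)

  # logistic symmetry: salinity at the configured front equals the plateau
  # mean (speed chosen so a sample falls exactly on the front)
  cfg2 <- cruise_config(duration_days = 10, speed_kmh = 20, front_km = 500,
                        front_width_km = 10, salinity_noise_sd = 0)
  uw2 <- simulate_underway(cfg2)
  mid <- cfg2$salinity_inside +
    (cfg2$salinity_outside - cfg2$salinity_inside) / 2
  expect_equal(uw2$salinity[uw2$along_track_km == 500], mid,
               tolerance = 1e-12)
  expect_true(all(uw2$salinity >= 30 & uw2$salinity <= 38))
})

test_that("generator is deterministic and rejects bad configs", {
  cfg <- cruise_config(duration_days = 5)
  a <- simulate_cruise(cfg, seed = 11)
  b <- simulate_cruise(cfg, seed = 11)
  expect_identical(a$underway, b$underway)
  expect_identical(a$populations, b$populations)
  expect_identical(a$nutrients, b$nutrients)
  expect_identical(a$events, b$events)

  expect_error(cruise_config(duration_days = 0), "duration")
  expect_error(cruise_config(speed_kmh = -1), "speed")
  expect_error(cruise_config(din_inside = -0.1), "non-negative")
})

test_that("noiseless carbon quotas are log-linear by day and reset at night", {
  cfg <- noiseless_config()
  cr <- simulate_cruise(cfg, seed = 3)
  red <- reduce_populations(cr$populations)
  pro <- red[red$population == "Prochlorococcus", ]
  hod <- (as.numeric(pro$timestamp - pro$timestamp[1]) / 3600) %% 24
  day2 <- as.Date(pro$timestamp) == as.Date(pro$timestamp[1]) + 1

  r_h <- cr$daily_truth$r_daily_true[1] / cfg$day_length_h
  q0 <- cr$daily_truth$q0_true[1]
  t <- hod - cfg$sunrise_hour
  daylit <- day2 & t >= 0 & t <= cfg$day_length_h
  expect_equal(log(pro$quota[daylit]), log(q0) + r_h * t[daylit],
               tolerance = 1e-9)
  night <- day2 & (t < 0 | t > cfg$day_length_h)
  expect_equal(pro$quota[night], rep(q0, sum(night)), tolerance = 1e-9)

  # zero growth, zero noise: quota constant over the whole series
  cfg0 <- constant_rate_config(rates = rep(0, 4), noise_sigma = 0)
  cr0 <- simulate_cruise(cfg0, seed = 4)
  red0 <- reduce_populations(cr0$populations)
  syn0 <- red0$quota[red0$population == "Synechococcus"]
  expect_lt(diff(range(syn0)), 1e-12)
})

test_that("noiseless scatter round-trips through the generating table", {
  cfg <- noiseless_config(duration_days = 3)
  uw <- simulate_underway(cfg)
  truth <- synthetic_truth(cfg)
  tables <- default_calibration_tables()
  pops <- simulate_population_series(cfg, uw, truth, tables)
  tab <- tables[["1.38"]]
  obs <- pops$observations
  esd_back <- scatter_to_esd(obs$scatter, tab)
  q_back <- carbon_quota(esd_to_volume(esd_back))
  # regenerate the deterministic quotas and compare
  obs2 <- simulate_population_series(cfg, uw, truth, tables)$observations
  expect_identical(obs$scatter, obs2$scatter)
  expect_true(all(abs(esd_to_scatter(esd_back, tab) - obs$scatter) <
                    1e-12 * obs$scatter))
  expect_true(all(q_back > 0))
})

test_that("population generator refuses an unknown refractive index", {
  cfg <- cruise_config(duration_days = 2, refractive_index = 1.44)
  uw <- simulate_underway(cfg)
  expect_error(simulate_population_series(cfg, uw), "1.44")
})

test_that("nutrient plateaus, decoupled mode and monotone DIP behave", {
  cfg <- cruise_config(duration_days = 10, front_km = 2000,
                       din_inside = 0.05, din_outside = 11,
                       nutrient_sigma = 0)
  uw <- simulate_underway(cfg, seed = 5)
  nut <- simulate_nutrients(cfg, uw)
  ratio <- nut$din[nrow(nut)] / nut$din[1]
  expect_equal(ratio, 11 / 0.05, tolerance = 0.01)

  cfg_d <- cruise_config(duration_days = 10, front_km = 2000,
                         decouple_din = TRUE, nutrient_sigma = 0)
  nut_d <- simulate_nutrients(cfg_d, simulate_underway(cfg_d))
  expect_lt(stats::var(nut_d$din), 1e-20)

  cfg_p <- cruise_config(duration_days = 10, front_km = 2000,
                         dip_inside = 0.2, dip_outside = 1.1,
                         nutrient_sigma = 0)
  nut_p <- simulate_nutrients(cfg_p, simulate_underway(cfg_p))
  expect_true(all(diff(nut_p$dip) >= -1e-12))
})

test_that("cruise bundles survive a text write/read round trip", {
  dir <- withr::local_tempdir()
  cr <- simulate_cruise(cruise_config(duration_days = 2), seed = 9)
  write_cruise(cr, dir)
  back <- read_cruise(dir)
  expect_equal(back$underway$salinity, cr$underway$salinity,
               tolerance = 1e-12)
  expect_identical(back$underway$timestamp, cr$underway$timestamp)
  expect_equal(back$populations$scatter, cr$populations$scatter,
               tolerance = 1e-12)
  expect_equal(unname(back$truth_meta["front_km"]), cr$truth$front_km)
  expect_equal(unname(back$truth_meta["seed"]), 9)
})
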