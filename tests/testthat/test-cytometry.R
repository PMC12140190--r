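test_that("scatter-to-ESD interpolation is exact at nodes and geometric between", {
  tab <- calibration_table(c(0.01, 0.1, 1, 10), c(0.3, 0.8, 2.0, 5.0), 1.38)
  expect_equal(scatter_to_esd(c(0.01, 0.1, 1, 10), tab),
               c(0.3, 0.8, 2.0, 5.0), ignore_attr = TRUE)
  # halfway in log space between two nodes -> geometric mean of node ESDs
  s_mid <- sqrt(0.1 * 1)
  expect_equal(as.numeric(scatter_to_esd(s_mid, tab)), sqrt(0.8 * 2.0),
               tolerance = 1e-12, ignore_attr = TRUE)
  # identical nodes -> identical outputs whatever the labelled index
  tab2 <- calibration_table(tab$scatter, tab$esd, 1.41)
  s <- c(0.02, 0.5, 3)
  expect_identical(as.numeric(scatter_to_esd(s, tab)),
                   as.numeric(scatter_to_esd(s, tab2)))
  # out-of-range values clamp to the end nodes and are flagged
  out <- scatter_to_esd(c(0.001, 100), tab)
  expect_equal(as.numeric(out), c(0.3, 5.0))
  expect_identical(attr(out, "clamped"), c(TRUE, TRUE))

  expect_error(calibration_table(c(0.1, 0.05), c(0.5, 1), 1.38),
               "increasing")
  expect_error(calibration_table(0.1, 0.5, 1.38), "2 nodes")
})

test_that("refractive-index selection picks the median ESD nearest 0.6 um", {
  # tables built so the candidate median ESDs are exactly 0.55, 0.61, 0.68
  mk <- function(target, ri) {
    esd <- c(0.1, 4)
    calibration_table(c(0.1, 4) * (0.6 / target), esd, ri)
  }
  tabs <- list(mk(0.55, 1.35), mk(0.61, 1.38), mk(0.68, 1.41))
  sel <- select_refractive_index(0.6, tabs)
  expect_equal(sel$refractive_index, 1.38)
  expect_equal(sort(sel$medians$median_esd), c(0.55, 0.61, 0.68),
               tolerance = 1e-9)

  # single candidate -> that candidate; duplication leaves the choice alone
  expect_equal(select_refractive_index(0.6, tabs[2])$refractive_index, 1.38)
  sample <- c(0.3, 0.6, 0.9)
  expect_equal(select_refractive_index(rep(sample, 3), tabs)$refractive_index,
               select_refractive_index(sample, tabs)$refractive_index)
  expect_error(select_refractive_index(numeric(), tabs), "at least one")
})

test_that("volume, carbon quota and biomass follow the allometric chain", {
  expect_equal(esd_to_volume(0.6), pi / 6 * 0.6^3)
  expect_equal(esd_to_volume(0.6), 0.11310, tolerance = 1e-4)
  expect_equal(esd_to_volume(1.2406), 8 * esd_to_volume(0.6203))
  esd <- c(0.4, 1.3, 2.8)
  expect_equal(volume_to_esd(esd_to_volume(esd)), esd)
  expect_error(esd_to_volume(-1), "positive")

  expect_identical(carbon_quota(1), 0.261)
  expect_equal(carbon_quota(esd_to_volume(0.6)), 0.0400506481,
               tolerance = 1e-8)
  grid <- exp(seq(log(0.01), log(100), length.out = 50))
  expect_true(all(diff(carbon_quota(grid)) > 0))
  expect_error(carbon_quota(0), "positive")
  expect_error(allometric_model(b = 1.2), "exponent")

  expect_equal(carbon_biomass(2e8, 0.04), 8.0)
  expect_equal(carbon_biomass(200, 0.04, unit = "1e6_cells_per_l"), 8.0)
  expect_equal(carbon_biomass(0, 0.04), 0)
  expect_equal(carbon_biomass(4e8, 0.04), 2 * carbon_biomass(2e8, 0.04))
  expect_error(carbon_biomass(-1, 0.04), "non-negative")
})

test_that("eukaryote size classes split at 2 and 5 um", {
  expect_identical(split_eukaryotes(c(1.0, 2.0, 4.9, 6.0)),
                   c("picoeukaryote", "nanoeukaryote", "nanoeukaryote",
                     "out_of_range"))
  expect_error(split_eukaryotes(0), "positive")
})

test_that("gating applies precedence and round-trips generator labels", {
  gates <- default_gate_config()
  # an event inside both the bead and eukaryote rectangles is a bead
  ev <- tibble::tibble(scatter = 1.0, chlorophyll = 2, phycoerythrin = 1.5)
  expect_identical(gate_events(ev, gates)$label, "bead")
  # empty table stays empty
  empty <- tibble::tibble(scatter = numeric(), chlorophyll = numeric(),
                          phycoerythrin = numeric())
  expect_identical(nrow(gate_events(empty, gates)), 0L)
  # synthetic labeled events regated with the generating boundaries agree 100%
  ev2 <- simulate_events(n_per_population = 300, seed = 21)
  regated <- gate_events(ev2[, 1:3], gates)
  expect_identical(regated$label, ev2$label)
  # missing channel is named in the error
  expect_error(gate_events(ev2[, c("scatter", "chlorophyll")], gates),
               "phycoerythrin")
})

test_that("biomass is additive across the four populations", {
  cr <- simulate_cruise(cruise_config(duration_days = 4), seed = 13)
  red <- reduce_populations(cr$populations)
  total <- tapply(red$biomass, red$timestamp, sum)
  parts <- sapply(split(red, red$population), function(d) {
    d$biomass[order(d$timestamp)]
  })
  expect_equal(unname(rowSums(parts)), unname(as.numeric(total)),
               tolerance = 1e-12)
  expect_identical(ncol(parts), 4L)
})
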