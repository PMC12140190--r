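#' Configuration for the synthetic cruise generator
#'
#' Defaults emulate a northward transect out of a subtropical gyre:
#' constant ship speed (10 knots = 18.52 km/h), a half-sine PAR diel cycle,
#' a sigmoidal (logistic) salinity front, region-dependent temperature and
#' nutrient plateaus, and per-population diel carbon-quota dynamics with
#' multiplicative lognormal noise. The plateau values mirror the regional
#' averages reported for the North Pacific Subtropical Gyre and the waters
#' north of it.
#'
#' @param duration_days Cruise length in days (> 0).
#' @param speed_kmh Ship speed in km/h (> 0), default 18.52 (10 knots).
#' @param start_time First record timestamp (UTC, treated as local solar
#'   time).
#' @param start_lat,start_lon Starting position (degrees).
#' @param direction Track direction: `"north"`, `"south"`, or `"east"`.
#' @param front_km Along-track position of the salinity front (km).
#' @param front_width_km Logistic scale of the front (km); the half-maximum
#'   gradient width is `2 * acosh(3) * front_width_km` (about 3.53 scales).
#' @param salinity_inside,salinity_outside Plateau salinities (PSU) on the
#'   gyre / non-gyre side.
#' @param salinity_noise_sd Additive Gaussian noise on salinity (PSU).
#' @param temperature_inside,temperature_outside Plateau temperatures (deg C).
#' @param day_length_h Daylight duration (h); PAR is a half-sine over
#'   `[sunrise_hour, sunrise_hour + day_length_h]` and exactly zero at night.
#' @param sunrise_hour Local hour of sunrise.
#' @param par_peak Peak PAR (umol photons m-2 s-1).
#' @param din_inside,din_outside,dip_inside,dip_outside Nutrient plateaus
#'   (umol/L, >= 0).
#' @param nutrient_sigma Multiplicative lognormal sigma on nutrients.
#' @param decouple_din If `TRUE`, DIN stays flat at its inside plateau while
#'   DIP crosses the front (the eastern-transect pattern).
#' @param noise_sigma Multiplicative lognormal sigma applied to carbon
#'   quotas and abundances.
#' @param refractive_index True refractive index used to emit scatter; must
#'   name one of the candidate calibration tables.
#' @param populations Tibble with one row per simulated population:
#'   `population`, baseline `esd` (um), `rate_inside`/`rate_outside`
#'   (d^-1, >= 0), `abund_inside`/`abund_outside` (10^6 cells/L).
#' @param dt_hours Sampling interval in hours (default 1, the native
#'   resolution of the pipeline).
#' @return A list of class `cruise_config`.
#' @export
cruise_config <- function(duration_days = 15,
                          speed_kmh = 18.52,
                          start_time = as.POSIXct("2019-04-10 00:00:00",
                                                  tz = "UTC"),
                          start_lat = 22, start_lon = -158,
                          direction = c("north", "south", "east"),
                          front_km = 4000,
                          front_width_km = 8.5,
                          salinity_inside = 34.8,
                          salinity_outside = 34.1,
                          salinity_noise_sd = 0.01,
                          temperature_inside = 26.3,
                          temperature_outside = 20.6,
                          day_length_h = 12,
                          sunrise_hour = 6,
                          par_peak = 2000,
                          din_inside = 0.05, din_outside = 11,
                          dip_inside = 0.2, dip_outside = 1.1,
                          nutrient_sigma = 0.05,
                          decouple_din = FALSE,
                          noise_sigma = 0.05,
                          refractive_index = 1.38,
                          populations = default_population_truth(),
                          dt_hours = 1) {
  direction <- match.arg(direction)
  if (!is.numeric(duration_days) || duration_days <= 0)
    stop("duration_days must be positive")
  if (!is.numeric(speed_kmh) || speed_kmh <= 0)
    stop("speed_kmh must be positive")
  if (front_width_km <= 0) stop("front_width_km must be positive")
  if (any(c(din_inside, din_outside, dip_inside, dip_outside) < 0))
    stop("nutrient plateau concentrations must be non-negative")
  if (noise_sigma < 0 || nutrient_sigma < 0 || salinity_noise_sd < 0)
    stop("noise levels must be non-negative")
  if (day_length_h <= 0 || day_length_h > 24)
    stop("day_length_h must be in (0, 24]")
  populations <- tibble::as_tibble(populations)
  if (any(populations$rate_inside < 0) || any(populations$rate_outside < 0))
    stop("true growth rates must be non-negative")
  structure(as.list(environment()), class = "cruise_config")
}

#' Default per-population ground truth
#'
#' Baseline sizes and regional growth rates / abundances chosen so the
#' within-gyre biomasses land near the regional averages reported for the
#' four small-phytoplankton groups (about 7.7, 1.2, 1.0 and 1.9 ugC/L for
#' Prochlorococcus, Synechococcus, picoeukaryotes, nanoeukaryotes).
#'
#' @return Tibble with columns `population`, `esd`, `rate_inside`,
#'   `rate_outside`, `abund_inside`, `abund_outside`.
#' @export
default_population_truth <- function() {
  tibble::tibble(
    population = c("Prochlorococcus", "Synechococcus", "picoeukaryote",
                   "nanoeukaryote"),
    esd = c(0.6, 1.0, 1.5, 3.0),
    rate_inside = c(0.43, 0.26, 0.20, 0.11),
    rate_outside = c(0.28, 0.23, 0.18, 0.11),
    abund_inside = c(192, 8, 2.3, 0.75),
    abund_outside = c(12, 16, 14.9, 3.6)
  )
}

logistic_profile <- function(x, inside, outside, center, scale) {
  inside + (outside - inside) / (1 + exp(-(x - center) / scale))
}

half_sine_par <- function(hour_of_day, sunrise, day_length, peak) {
  t <- hour_of_day - sunrise
  ifelse(t > 0 & t < day_length, peak * sin(pi * t / day_length), 0)
}

#' Simulate hourly underway records
#'
#' Generates the ship-track series: timestamps, positions along a
#' constant-speed track, salinity and temperature following a logistic
#' transition across the configured front, and a half-sine PAR diel cycle
#' that is exactly zero at night.
#'
#' @param config A [cruise_config()].
#' @param seed Integer seed; if `NULL` the current RNG state is used.
#' @return Tibble with columns `timestamp`, `latitude`, `longitude`,
#'   `along_track_km`, `salinity`, `temperature`, `par`.
#' @export
simulate_underway <- function(config = cruise_config(), seed = NULL) {
  stopifnot(inherits(config, "cruise_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(round(config$duration_days * 24 / config$dt_hours))
  hours <- (seq_len(n) - 1) * config$dt_hours
  km <- hours * config$speed_kmh
  km_per_deg <- 6371.0 * pi / 180
  lat <- config$start_lat
  lon <- config$start_lon
  if (config$direction == "north") {
    latitude <- lat + km / km_per_deg
    longitude <- rep(lon, n)
  } else if (config$direction == "south") {
    latitude <- lat - km / km_per_deg
    longitude <- rep(lon, n)
  } else {
    latitude <- rep(lat, n)
    longitude <- lon + km / (km_per_deg * cos(lat * pi / 180))
  }
  timestamp <- config$start_time + hours * 3600
  start_hour <- as.numeric(format(config$start_time, "%H")) +
    as.numeric(format(config$start_time, "%M")) / 60
  hod <- (hours + start_hour) %% 24
  par <- half_sine_par(hod, config$sunrise_hour, config$day_length_h,
                       config$par_peak)
  salinity <- logistic_profile(km, config$salinity_inside,
                               config$salinity_outside,
                               config$front_km, config$front_width_km)
  if (config$salinity_noise_sd > 0)
    salinity <- salinity + stats::rnorm(n, 0, config$salinity_noise_sd)
  temperature <- logistic_profile(km, config$temperature_inside,
                                  config$temperature_outside,
                                  config$front_km, config$front_width_km)
  tibble::tibble(timestamp = timestamp, latitude = latitude,
                 longitude = longitude, along_track_km = km,
                 salinity = salinity, temperature = temperature, par = par)
}

#' Ground truth for a synthetic cruise
#'
#' @param config A [cruise_config()].
#' @param seed Integer seed recorded in the truth object.
#' @return A list of class `synthetic_truth` holding the true front
#'   position, refractive index, noise level, and per-population regional
#'   rates and abundance plateaus.
#' @export
synthetic_truth <- function(config, seed = NA_integer_) {
  stopifnot(inherits(config, "cruise_config"))
  structure(list(
    front_km = config$front_km,
    front_width_km = config$front_width_km,
    refractive_index = config$refractive_index,
    noise_sigma = config$noise_sigma,
    seed = seed,
    populations = config$populations
  ), class = "synthetic_truth")
}

#' Simulate hourly per-population observations
#'
#' For each population and day, the carbon quota grows exponentially from
#' its baseline over the daylight window -- `Q(t) = Q0 * exp(r_h * t)` with
#' `r_h = r_d / day_length` and `t` hours since sunrise -- and resets to the
#' baseline overnight. The day's true rate `r_d` is the logistic blend of
#' the inside/outside rates evaluated at the ship's local-noon position.
#' Scatter is produced by inverting the true calibration table at the ESD
#' implied by the (noisy) quota, so the downstream scatter-to-carbon chain
#' round-trips exactly when `noise_sigma = 0`. Abundance follows the
#' configured logistic spatial profile. Multiplicative lognormal noise with
#' sigma `noise_sigma` is applied to quota and abundance.
#'
#' @param config A [cruise_config()].
#' @param underway Output of [simulate_underway()] for the same config.
#' @param truth A [synthetic_truth()]; defaults to the config's own truth.
#' @param tables Candidate calibration tables; must contain the truth's
#'   refractive index.
#' @param seed Integer seed; if `NULL` the current RNG state is used.
#' @return A list with `observations` (tibble: `timestamp`, `population`,
#'   `scatter`, `abundance`) and `daily_truth` (tibble: `population`,
#'   `date`, `r_daily_true`, `q0_true`).
#' @export
simulate_population_series <- function(config, underway,
                                       truth = synthetic_truth(config),
                                       tables = default_calibration_tables(),
                                       seed = NULL) {
  stopifnot(inherits(config, "cruise_config"),
            inherits(truth, "synthetic_truth"))
  if (!is.null(seed)) set.seed(seed)
  idx <- vapply(tables, `[[`, numeric(1), "refractive_index")
  hit <- which(abs(idx - truth$refractive_index) < 1e-9)
  if (length(hit) != 1L)
    stop(sprintf("true refractive index %.2f is not among the candidate tables",
                 truth$refractive_index))
  tab <- tables[[hit]]
  model <- allometric_model()

  hours <- as.numeric(difftime(underway$timestamp, underway$timestamp[1],
                               units = "hours"))
  start_hour <- as.numeric(format(underway$timestamp[1], "%H")) +
    as.numeric(format(underway$timestamp[1], "%M")) / 60
  hod <- (hours + start_hour) %% 24
  day_index <- floor(hours / 24)
  dates <- as.Date(underway$timestamp[match(unique(day_index), day_index)])
  t_since_sunrise <- hod - config$sunrise_hour
  daytime <- t_since_sunrise >= 0 & t_since_sunrise <= config$day_length_h

  # ship position at local noon of each day, for the day's true rate
  noon_hour <- (unique(day_index)) * 24 + config$sunrise_hour +
    config$day_length_h / 2
  noon_km <- noon_hour * config$speed_kmh

  obs <- list(); daily <- list()
  for (p in seq_len(nrow(truth$populations))) {
    pop <- truth$populations[p, ]
    q0 <- carbon_quota(esd_to_volume(pop$esd), model)
    r_day <- logistic_profile(noon_km, pop$rate_inside, pop$rate_outside,
                              truth$front_km, truth$front_width_km)
    r_h <- r_day / config$day_length_h
    quota <- q0 * exp(ifelse(daytime, r_h[day_index + 1] * t_since_sunrise, 0))
    abund <- logistic_profile(underway$along_track_km,
                              pop$abund_inside, pop$abund_outside,
                              truth$front_km, truth$front_width_km)
    if (truth$noise_sigma > 0) {
      quota <- quota * exp(stats::rnorm(length(quota), 0, truth$noise_sigma))
      abund <- abund * exp(stats::rnorm(length(abund), 0, truth$noise_sigma))
    }
    esd <- volume_to_esd((quota / model$a)^(1 / model$b))
    obs[[p]] <- tibble::tibble(
      timestamp = underway$timestamp,
      population = pop$population,
      scatter = esd_to_scatter(esd, tab),
      abundance = abund
    )
    daily[[p]] <- tibble::tibble(
      population = pop$population,
      date = dates,
      r_daily_true = r_day,
      q0_true = q0
    )
  }
  list(observations = dplyr::bind_rows(obs),
       daily_truth = dplyr::bind_rows(daily))
}

#' Simulate nutrient records along the track
#'
#' DIN and DIP follow the same logistic transition as salinity, with
#' multiplicative lognormal noise. In decoupled mode DIN stays flat at its
#' inside-gyre plateau (the eastern-transect pattern of rising DIP without
#' rising DIN).
#'
#' @inheritParams simulate_population_series
#' @return Tibble with `timestamp`, `din`, `dip` (umol/L) and a `source`
#'   flag (`"measured"`).
#' @export
simulate_nutrients <- function(config, underway, seed = NULL) {
  stopifnot(inherits(config, "cruise_config"))
  if (any(c(config$din_inside, config$din_outside,
            config$dip_inside, config$dip_outside) < 0))
    stop("nutrient plateau concentrations must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  km <- underway$along_track_km
  din_out <- if (config$decouple_din) config$din_inside else config$din_outside
  din <- logistic_profile(km, config$din_inside, din_out,
                          config$front_km, config$front_width_km)
  dip <- logistic_profile(km, config$dip_inside, config$dip_outside,
                          config$front_km, config$front_width_km)
  if (config$nutrient_sigma > 0) {
    din <- din * exp(stats::rnorm(length(km), 0, config$nutrient_sigma))
    dip <- dip * exp(stats::rnorm(length(km), 0, config$nutrient_sigma))
  }
  tibble::tibble(timestamp = underway$timestamp, din = din, dip = dip,
                 source = "measured")
}

#' Simulate a minimal labeled event table for gate testing
#'
#' Draws uniform clusters in (scatter, chlorophyll, phycoerythrin) space,
#' one per population plus reference beads, positioned strictly inside the
#' [default_gate_config()] rectangles so regating reproduces the generating
#' labels exactly.
#'
#' @param n_per_population Events per cluster.
#' @param seed Integer seed.
#' @return Tibble with `scatter`, `chlorophyll`, `phycoerythrin`, `label`.
#' @export
simulate_events <- function(n_per_population = 200, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  runifc <- function(lo, hi) stats::runif(n_per_population, lo, hi)
  clusters <- list(
    bead = tibble::tibble(scatter = runifc(0.9, 1.1),
                          chlorophyll = runifc(0.01, 0.05),
                          phycoerythrin = runifc(2, 4)),
    Synechococcus = tibble::tibble(scatter = runifc(0.05, 0.3),
                                   chlorophyll = runifc(0.5, 2),
                                   phycoerythrin = runifc(0.5, 2)),
    Prochlorococcus = tibble::tibble(scatter = runifc(0.005, 0.05),
                                     chlorophyll = runifc(0.1, 0.5),
                                     phycoerythrin = runifc(0, 0.05)),
    eukaryote = tibble::tibble(scatter = runifc(0.3, 10),
                               chlorophyll = runifc(2, 50),
                               phycoerythrin = runifc(0, 0.1))
  )
  out <- dplyr::bind_rows(clusters, .id = "label")
  out[c("scatter", "chlorophyll", "phycoerythrin", "label")]
}

#' Simulate a complete synthetic cruise
#'
#' Runs the underway, population, nutrient and event generators under a
#' single seed so that identical `(config, seed)` pairs give bit-identical
#' bundles.
#'
#' @param config A [cruise_config()].
#' @param seed Integer seed (fully determines the output).
#' @param tables Candidate calibration tables.
#' @return A list of class `synthetic_cruise` with elements `underway`,
#'   `populations`, `daily_truth`, `nutrients`, `events`, `truth`,
#'   `config`.
#' @export
simulate_cruise <- function(config = cruise_config(), seed = 1L,
                            tables = default_calibration_tables()) {
  set.seed(seed)
  truth <- synthetic_truth(config, seed = seed)
  underway <- simulate_underway(config)
  pops <- simulate_population_series(config, underway, truth, tables)
  nutrients <- simulate_nutrients(config, underway)
  events <- simulate_events(seed = NULL)
  structure(list(underway = underway,
                 populations = pops$observations,
                 daily_truth = pops$daily_truth,
                 nutrients = nutrients,
                 events = events,
                 truth = truth,
                 config = config),
            class = "synthetic_cruise")
}

#' Write / read a synthetic cruise bundle as delimited text
#'
#' One CSV per stream (underway, populations, nutrients, events) plus a
#' truth sidecar split into a per-day rate table and a key-value metadata
#' table, all plain text.
#'
#' @param cruise A [simulate_cruise()] bundle.
#' @param dir Directory to write into (created if needed).
#' @return `write_cruise()` returns `dir` invisibly; `read_cruise()`
#'   returns a list with the same stream names.
#' @export
write_cruise <- function(cruise, dir) {
  stopifnot(inherits(cruise, "synthetic_cruise"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(d, f) {
    d <- as.data.frame(d)
    for (cl in names(d)) {
      if (inherits(d[[cl]], "POSIXct"))
        d[[cl]] <- format(d[[cl]], "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
    }
    utils::write.csv(d, file.path(dir, f), row.names = FALSE, quote = FALSE)
  }
  wr(cruise$underway, "underway.csv")
  wr(cruise$populations, "populations.csv")
  wr(cruise$nutrients, "nutrients.csv")
  wr(cruise$events, "events.csv")
  wr(cruise$daily_truth, "truth_daily.csv")
  meta <- data.frame(
    key = c("front_km", "front_width_km", "refractive_index", "noise_sigma",
            "seed"),
    value = c(cruise$truth$front_km, cruise$truth$front_width_km,
              cruise$truth$refractive_index, cruise$truth$noise_sigma,
              cruise$truth$seed)
  )
  utils::write.csv(meta, file.path(dir, "truth_meta.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(dir)
}

#' @rdname write_cruise
#' @export
read_cruise <- function(dir) {
  rd <- function(f) {
    d <- tibble::as_tibble(utils::read.csv(file.path(dir, f)))
    if ("timestamp" %in% names(d))
      d$timestamp <- as.POSIXct(d$timestamp, format = "%Y-%m-%dT%H:%M:%SZ",
                                tz = "UTC")
    if ("date" %in% names(d)) d$date <- as.Date(d$date)
    d
  }
  meta <- utils::read.csv(file.path(dir, "truth_meta.csv"))
  list(underway = rd("underway.csv"),
       populations = rd("populations.csv"),
       nutrients = rd("nutrients.csv"),
       events = rd("events.csv"),
       daily_truth = rd("truth_daily.csv"),
       truth_meta = stats::setNames(as.numeric(meta$value), meta$key))
}
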