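pop_short <- function(population) {
  map <- c(Prochlorococcus = "pro", Synechococcus = "syn",
           picoeukaryote = "pico", nanoeukaryote = "nano", bead = "bead")
  unname(map[population])
}

#' Pipeline configuration
#'
#' Central home for the analysis constants: the PAR daytime threshold
#' (10 umol photons m-2 s-1), the hourly abundance floor (0.02 x 10^6
#' cells/L), the 24-h decomposition window, the 35-PSU front reference
#' salinity, the transition-zone gradient fraction, the 24-h / 100-km bin
#' widths, and the 0.01 significance and false-discovery-rate levels.
#'
#' @param par_threshold PAR threshold defining daytime.
#' @param abundance_floor Minimum hourly abundance (10^6 cells/L) for a
#'   growth-fit observation.
#' @param decomposition_window Moving-average window (hours).
#' @param front_reference_salinity Reference gyre salinity (PSU).
#' @param transition_alpha Gradient fraction defining the transition zone.
#' @param time_bin_hours Temporal bin width (hours).
#' @param space_bin_km Spatial bin width (km).
#' @param fdr False discovery rate for the correlation screen.
#' @param significance Test significance level.
#' @param esd_reference Reference Prochlorococcus ESD (um) for
#'   refractive-index selection.
#' @param prominence Front-candidate floor (fraction of max |dS/dx|).
#' @param gyre_side Side convention passed to [signed_distance()].
#' @param allometric An [allometric_model()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(par_threshold = 10,
                            abundance_floor = 0.02,
                            decomposition_window = 24L,
                            front_reference_salinity = 35,
                            transition_alpha = 0.5,
                            time_bin_hours = 24,
                            space_bin_km = 100,
                            fdr = 0.01,
                            significance = 0.01,
                            esd_reference = 0.6,
                            prominence = 0.1,
                            gyre_side = "auto",
                            allometric = allometric_model()) {
  if (par_threshold < 0) stop("par_threshold must be non-negative")
  for (nm in c("abundance_floor", "decomposition_window", "time_bin_hours",
               "space_bin_km", "esd_reference", "transition_alpha"))
    if (get(nm) <= 0) stop(nm, " must be positive")
  if (fdr <= 0 || fdr >= 1) stop("fdr must be in (0, 1)")
  if (significance <= 0 || significance >= 1)
    stop("significance must be in (0, 1)")
  structure(as.list(environment()), class = "pipeline_config")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full transect analysis pipeline
#'
#' Executes the stages end to end: scatter reduction (refractive-index
#' selection, ESD, volume, carbon quota, biomass), diel detrending and
#' daily growth-rate fits, salinity-front detection and signed distances
#' from the gyre boundary, 24-h and 100-km binning, inside/outside Welch
#' contrasts, and the FDR-controlled correlation screen. Every filter
#' decision is counted in the report's `log`.
#'
#' @param underway Tibble of hourly underway records: `timestamp`,
#'   `latitude`, `longitude`, `salinity`, `temperature`, `par` (and
#'   optionally `along_track_km`).
#' @param populations Tibble of hourly per-population observations:
#'   `timestamp`, `population`, `scatter`, `abundance` (10^6 cells/L).
#' @param nutrients Optional tibble with `timestamp`, `din`, `dip`.
#' @param tables Candidate [calibration_table()] list.
#' @param config A [pipeline_config()].
#' @return A list of class `cruise_report` with elements
#'   `index_selection`, `reduced`, `growth_fits`, `front`,
#'   `transition_width_km`, `signed_km`, `time_bins`, `space_bins`,
#'   `tests`, `correlations`, `summary`, `log`, `config`.
#' @export
run_pipeline <- function(underway, populations, nutrients = NULL,
                         tables = default_calibration_tables(),
                         config = pipeline_config()) {
  if (missing(underway) || is.null(underway))
    stop("input stream 'underway' is missing")
  if (missing(populations) || is.null(populations))
    stop("input stream 'populations' is missing")
  stopifnot(inherits(config, "pipeline_config"))
  log <- list()
  note <- function(stage, reason, n) {
    log[[length(log) + 1L]] <<- tibble::tibble(stage = stage,
                                               reason = reason, n = n)
  }

  ## --- reduction ---------------------------------------------------------
  reduced <- with_stage("reduce", reduce_populations(
    populations, tables, reference = config$esd_reference,
    model = config$allometric))
  sel <- attr(reduced, "index_selection")
  note("reduce", "observations reduced", nrow(reduced))
  note("reduce", "scatter values clamped to table support",
       attr(reduced, "n_clamped"))

  ## --- growth ------------------------------------------------------------
  fits <- with_stage("growth", estimate_growth(
    reduced, underway,
    par_threshold = config$par_threshold,
    window = config$decomposition_window,
    abundance_floor = config$abundance_floor))
  note("growth", "fits attempted", nrow(fits))
  note("growth", "fits accepted", sum(fits$accepted))
  note("growth", "rejected: fewer than 2 usable hours",
       sum(is.na(fits$r_daily)))
  note("growth", "rejected: 6 or fewer usable hours",
       sum(!is.na(fits$r_daily) & fits$n_obs <= 6))
  note("growth", "rejected: slope p-value above 0.01",
       sum(!fits$accepted & !is.na(fits$r_daily) & fits$n_obs > 6))

  ## --- front geometry ----------------------------------------------------
  km <- if ("along_track_km" %in% names(underway)) {
    underway$along_track_km
  } else {
    with_stage("front", along_track_distance(underway$latitude,
                                             underway$longitude))
  }
  spline <- with_stage("front", smooth_salinity(km, underway$salinity))
  front <- with_stage("front", detect_front(
    spline, reference = config$front_reference_salinity,
    prominence = config$prominence))
  if (is.null(front$selected)) {
    note("front", "no front above prominence floor", 1L)
    signed <- rep(NA_real_, length(km))
    width <- NA_real_
  } else {
    note("front", "front candidates", nrow(front$candidates))
    signed <- with_stage("front", signed_distance(
      km, front, spline,
      gyre_side = config$gyre_side))
    width <- with_stage("front", transition_zone_width(
      spline, front, alpha = config$transition_alpha))
  }

  ## --- hourly wide table and bins ----------------------------------------
  wide <- tibble::tibble(timestamp = underway$timestamp,
                         temperature = underway$temperature,
                         salinity = underway$salinity,
                         along_track_km = km,
                         signed_km = signed)
  if (!is.null(nutrients)) {
    nx <- nutrients[, intersect(c("timestamp", "din", "dip"),
                                names(nutrients))]
    wide <- dplyr::left_join(wide, nx, by = "timestamp")
  }
  for (pop in unique(reduced$population)) {
    sub <- reduced[reduced$population == pop, c("timestamp", "biomass")]
    names(sub)[2] <- paste0("biomass_", pop_short(pop))
    wide <- dplyr::left_join(wide, sub, by = "timestamp")
  }
  time_bins <- with_stage("bins", bin_series(
    wide, "timestamp", width = config$time_bin_hours))
  space_bins <- with_stage("bins", bin_series(
    wide[, setdiff(names(wide), "timestamp")],
    "signed_km", width = config$space_bin_km, origin = 0))
  note("bins", "24-h bins emitted", nrow(time_bins))
  note("bins", "spatial bins emitted", nrow(space_bins))

  ## daily growth joined onto the 24-h bins (accepted fits only)
  acc <- fits[fits$accepted, , drop = FALSE]
  time_bins$date <- as.Date(time_bins$bin)
  for (pop in unique(fits$population)) {
    sub <- acc[acc$population == pop, c("date", "r_daily")]
    names(sub)[2] <- paste0("growth_", pop_short(pop))
    time_bins <- dplyr::left_join(time_bins, sub, by = "date")
  }
  time_bins$region <- ifelse(is.na(time_bins$signed_km_mean), NA_character_,
                             ifelse(time_bins$signed_km_mean < 0,
                                    "inside", "outside"))

  ## --- regional tests ----------------------------------------------------
  tests <- list()
  run_test <- function(var, alternative) {
    a <- time_bins[[var]][time_bins$region %in% "inside"]
    b <- time_bins[[var]][time_bins$region %in% "outside"]
    tryCatch({
      tt <- welch_t_test(a, b, alternative = alternative)
      tt$variable <- var
      tt
    }, error = function(e) {
      note("tests", sprintf("%s: %s", var, conditionMessage(e)), 1L)
      NULL
    })
  }
  tests$temperature <- run_test("temperature_mean", "two.sided")
  tests$salinity <- run_test("salinity_mean", "two.sided")
  if ("growth_pro" %in% names(time_bins))
    tests$growth_pro <- run_test("growth_pro", "greater")
  tests <- dplyr::bind_rows(tests)

  ## --- correlation screen ------------------------------------------------
  cor_vars <- intersect(
    c("temperature_mean", "salinity_mean", "din_mean", "dip_mean",
      grep("^biomass_.*_mean$", names(time_bins), value = TRUE),
      grep("^growth_", names(time_bins), value = TRUE)),
    names(time_bins))
  correlations <- with_stage("correlations", correlation_matrix(
    time_bins[, cor_vars], fdr = config$fdr))
  note("correlations", "pairs screened", nrow(correlations))
  note("correlations", "pairs omitted (too few complete pairs)",
       nrow(attr(correlations, "omitted")))

  ## --- regional summary ---------------------------------------------------
  if (all(is.na(signed))) {
    acc$region <- NA_character_
    reduced$region <- NA_character_
  } else {
    region_of_date <- stats::aggregate(
      signed ~ date, data = data.frame(signed = signed,
                                       date = as.Date(underway$timestamp)),
      FUN = mean)
    acc$region <- ifelse(
      region_of_date$signed[match(acc$date, region_of_date$date)] < 0,
      "inside", "outside")
    reduced$region <- ifelse(signed[match(reduced$timestamp,
                                          underway$timestamp)] < 0,
                             "inside", "outside")
  }
  summarise_region <- function(df, value) {
    stats::aggregate(stats::reformulate(c("population", "region"),
                                        response = value),
                     data = df, FUN = mean, na.rm = TRUE)
  }
  biomass_summary <- if (all(is.na(signed))) NULL else
    tibble::as_tibble(summarise_region(as.data.frame(reduced), "biomass"))
  growth_summary <- if (nrow(acc) == 0 || all(is.na(signed))) NULL else
    tibble::as_tibble(summarise_region(as.data.frame(acc), "r_daily"))
  fraction_inside <- NULL
  if (!is.null(biomass_summary)) {
    ins <- biomass_summary[biomass_summary$region == "inside", ]
    if (nrow(ins) > 0)
      fraction_inside <- tibble::tibble(
        population = ins$population,
        biomass = ins$biomass,
        fraction = ins$biomass / sum(ins$biomass))
  }

  structure(list(
    index_selection = sel,
    reduced = reduced,
    growth_fits = fits,
    front = front,
    transition_width_km = width,
    signed_km = signed,
    time_bins = time_bins,
    space_bins = space_bins,
    tests = tests,
    correlations = correlations,
    summary = list(biomass_by_region = biomass_summary,
                   growth_by_region = growth_summary,
                   biomass_fraction_inside = fraction_inside),
    log = dplyr::bind_rows(log),
    config = config
  ), class = "cruise_report")
}

#' @export
print.cruise_report <- function(x, ...) {
  cat("<cruise_report>\n")
  cat(sprintf("  refractive index: %.2f\n",
              x$index_selection$refractive_index))
  if (!is.null(x$front$selected)) {
    cat(sprintf("  gyre boundary: %.1f km along track (transition zone %.1f km)\n",
                x$front$selected$along_track_km, x$transition_width_km))
  } else {
    cat("  gyre boundary: not detected\n")
  }
  cat(sprintf("  growth fits: %d attempted, %d accepted\n",
              nrow(x$growth_fits), sum(x$growth_fits$accepted)))
  cat(sprintf("  24-h bins: %d; correlation pairs: %d (%d significant)\n",
              nrow(x$time_bins), nrow(x$correlations),
              sum(x$correlations$significant)))
  invisible(x)
}

#' Write the report tables to delimited text
#'
#' Emits the growth-fit table, the long-format correlation table, the 24-h
#' bin table, and a structured-text front report (candidates, selected
#' front, sign convention, transition zone).
#'
#' @param report A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "cruise_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$growth_fits, file.path(dir, "growth_fits.csv"),
                   row.names = FALSE)
  utils::write.csv(report$correlations, file.path(dir, "correlations.csv"),
                   row.names = FALSE)
  utils::write.csv(report$time_bins, file.path(dir, "time_bins.csv"),
                   row.names = FALSE)
  f <- report$front
  lines <- c("front report",
             sprintf("reference_salinity_psu: %.2f", f$reference),
             sprintf("transition_alpha: %.2f",
                     report$config$transition_alpha),
             sprintf("transition_width_km: %.3f",
                     report$transition_width_km),
             "sign_convention: negative inside the gyre",
             "candidates (along_track_km, salinity, gradient):")
  if (nrow(f$candidates) > 0)
    lines <- c(lines, sprintf("  %.3f, %.4f, %.6g",
                              f$candidates$along_track_km,
                              f$candidates$salinity, f$candidates$gradient))
  lines <- c(lines, if (is.null(f$selected)) "selected: none" else
    sprintf("selected: %.3f km", f$selected$along_track_km))
  writeLines(lines, file.path(dir, "front_report.txt"))
  invisible(dir)
}
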