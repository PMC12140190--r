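#' Population labels used throughout the pipeline
#'
#' @return Character vector of the fixed population label set.
#' @export
population_labels <- function() {
  c("Prochlorococcus", "Synechococcus", "picoeukaryote", "nanoeukaryote",
    "bead")
}

#' Allometric carbon model
#'
#' Cell carbon content scales with cell volume as Q_C = a * V^b, with
#' defaults a = 0.261 and b = 0.86 (Q_C in pgC per cell, V in cubic
#' micrometres).
#'
#' @param a Scale coefficient (> 0), default 0.261.
#' @param b Exponent (0 < b <= 1), default 0.86.
#' @return An object of class `allometric_model`.
#' @export
allometric_model <- function(a = 0.261, b = 0.86) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) == 1L, length(b) == 1L)
  if (!(a > 0)) stop("allometric scale 'a' must be positive")
  if (!(b > 0 && b <= 1)) stop("allometric exponent 'b' must be in (0, 1]")
  structure(list(a = a, b = b), class = "allometric_model")
}

#' Convert equivalent spherical diameter to cell volume
#'
#' Assumes spherical morphology: V = (pi/6) * ESD^3.
#'
#' @param esd ESD in micrometres (> 0).
#' @return Volume in cubic micrometres.
#' @export
esd_to_volume <- function(esd) {
  if (any(!is.na(esd) & esd <= 0)) stop("ESD must be positive")
  (pi / 6) * esd^3
}

#' @rdname esd_to_volume
#' @param volume Cell volume in cubic micrometres (> 0).
#' @export
volume_to_esd <- function(volume) {
  if (any(!is.na(volume) & volume <= 0)) stop("volume must be positive")
  (6 * volume / pi)^(1 / 3)
}

#' Carbon quota from cell volume
#'
#' @param volume Cell volume in cubic micrometres (> 0).
#' @param model An [allometric_model()].
#' @return Carbon quota in pgC per cell.
#' @examples
#' carbon_quota(1)            # 0.261 pgC
#' carbon_quota(esd_to_volume(0.6))
#' @export
carbon_quota <- function(volume, model = allometric_model()) {
  stopifnot(inherits(model, "allometric_model"))
  if (any(!is.na(volume) & volume <= 0)) stop("volume must be positive")
  model$a * volume^model$b
}

#' Population carbon biomass
#'
#' Biomass (ugC per litre) is the product of cell abundance and per-cell
#' carbon quota. Abundance is accepted either in cells per litre or in the
#' community's customary 10^6 cells per litre; the unit must be declared so
#' the pg-to-ug rescaling is applied exactly once.
#'
#' @param abundance Cell abundance (>= 0).
#' @param quota Carbon quota, pgC per cell (> 0).
#' @param unit Unit of `abundance`: `"cells_per_l"` or `"1e6_cells_per_l"`.
#' @return Biomass in ugC per litre.
#' @examples
#' carbon_biomass(2e8, 0.04)                      # 8 ugC/L
#' carbon_biomass(200, 0.04, "1e6_cells_per_l")   # same
#' @export
carbon_biomass <- function(abundance, quota,
                           unit = c("cells_per_l", "1e6_cells_per_l")) {
  unit <- match.arg(unit)
  if (any(!is.na(abundance) & abundance < 0))
    stop("abundance must be non-negative")
  if (any(!is.na(quota) & quota <= 0))
    stop("carbon quota must be positive")
  cells_per_l <- if (unit == "cells_per_l") abundance else abundance * 1e6
  cells_per_l * quota * 1e-6
}

#' Split small eukaryotes into pico and nano size classes
#'
#' Picoeukaryotes are < 2 um ESD; small nanoeukaryotes span 2-5 um
#' (boundary assigned to the nano class). Cells above 5 um fall outside the
#' small-phytoplankton scope and are flagged.
#'
#' @param esd ESD in micrometres (> 0).
#' @return Character vector: `"picoeukaryote"`, `"nanoeukaryote"`, or
#'   `"out_of_range"`.
#' @export
split_eukaryotes <- function(esd) {
  if (any(!is.na(esd) & esd <= 0)) stop("ESD must be positive")
  out <- ifelse(esd < 2, "picoeukaryote",
                ifelse(esd <= 5, "nanoeukaryote", "out_of_range"))
  out[is.na(esd)] <- NA_character_
  out
}

#' Gate configuration for event classification
#'
#' Rectangular per-population boundaries on the scatter and two fluorescence
#' channels (chlorophyll, phycoerythrin). Events are labeled in a fixed
#' precedence order -- beads, then phycoerythrin-positive Synechococcus,
#' then Prochlorococcus, then eukaryotes -- so overlapping rectangles
#' resolve deterministically.
#'
#' @param gates Named list (in precedence order) of per-population gates;
#'   each gate is a list with numeric `scatter`, `chlorophyll`,
#'   `phycoerythrin` elements giving finite `c(min, max)` bounds.
#' @return An object of class `gate_config`.
#' @export
gate_config <- function(gates) {
  stopifnot(is.list(gates), length(gates) >= 1L, !is.null(names(gates)))
  for (nm in names(gates)) {
    g <- gates[[nm]]
    for (ch in c("scatter", "chlorophyll", "phycoerythrin")) {
      if (is.null(g[[ch]]) || length(g[[ch]]) != 2L || any(!is.finite(g[[ch]])))
        stop(sprintf("gate '%s': channel '%s' needs finite c(min, max)", nm, ch))
      if (g[[ch]][1] > g[[ch]][2])
        stop(sprintf("gate '%s': channel '%s' has min > max", nm, ch))
    }
  }
  structure(gates, class = "gate_config")
}

#' Default gate configuration matching the synthetic event generator
#'
#' @return A [gate_config()] with bead, Synechococcus, Prochlorococcus and
#'   eukaryote rectangles in precedence order.
#' @export
default_gate_config <- function() {
  gate_config(list(
    bead = list(scatter = c(0.8, 1.2), chlorophyll = c(0, 100),
                phycoerythrin = c(1, 5)),
    Synechococcus = list(scatter = c(0.02, 0.5), chlorophyll = c(0.2, 3),
                         phycoerythrin = c(0.2, 3)),
    Prochlorococcus = list(scatter = c(0.001, 0.08), chlorophyll = c(0.05, 1),
                           phycoerythrin = c(0, 0.1)),
    eukaryote = list(scatter = c(0.1, 20), chlorophyll = c(1, 100),
                     phycoerythrin = c(0, 0.5))
  ))
}

#' Label flow-cytometry events by population gate
#'
#' @param events Data frame with numeric columns `scatter`, `chlorophyll`,
#'   `phycoerythrin` (one row per particle).
#' @param gates A [gate_config()].
#' @return The events as a tibble with a `label` column; events matched by
#'   no gate are `"unclassified"`.
#' @export
gate_events <- function(events, gates = default_gate_config()) {
  stopifnot(inherits(gates, "gate_config"))
  events <- tibble::as_tibble(events)
  for (ch in c("scatter", "chlorophyll", "phycoerythrin")) {
    if (is.null(events[[ch]]))
      stop(sprintf("event table is missing channel '%s'", ch))
  }
  label <- rep("unclassified", nrow(events))
  unset <- rep(TRUE, nrow(events))
  for (nm in names(gates)) {
    g <- gates[[nm]]
    inside <- unset &
      events$scatter >= g$scatter[1] & events$scatter <= g$scatter[2] &
      events$chlorophyll >= g$chlorophyll[1] &
      events$chlorophyll <= g$chlorophyll[2] &
      events$phycoerythrin >= g$phycoerythrin[1] &
      events$phycoerythrin <= g$phycoerythrin[2]
    inside[is.na(inside)] <- FALSE
    label[inside] <- nm
    unset <- unset & !inside
  }
  events$label <- label
  events
}

#' Reduce a gated population table to size, carbon and biomass
#'
#' Applies the per-cruise refractive-index selection (from the
#' Prochlorococcus scatter sample), then converts scatter to ESD, volume,
#' allometric carbon quota, and biomass for every observation.
#'
#' @param populations Tibble with columns `timestamp`, `population`,
#'   `scatter` (bead-normalized), `abundance` (10^6 cells per litre).
#' @param tables List of candidate [calibration_table()] objects.
#' @param reference Reference Prochlorococcus ESD (um) for index selection.
#' @param model [allometric_model()] for the carbon conversion.
#' @return The input tibble augmented with `esd`, `volume`, `quota`,
#'   `biomass` columns; the selection report is attached as attribute
#'   `"index_selection"`.
#' @export
reduce_populations <- function(populations,
                               tables = default_calibration_tables(),
                               reference = 0.6,
                               model = allometric_model()) {
  populations <- tibble::as_tibble(populations)
  need <- c("timestamp", "population", "scatter", "abundance")
  miss <- setdiff(need, names(populations))
  if (length(miss))
    stop("population table is missing column(s): ", paste(miss, collapse = ", "))
  pro <- populations$scatter[populations$population == "Prochlorococcus"]
  sel <- select_refractive_index(pro, tables, reference = reference)
  esd <- scatter_to_esd(populations$scatter, sel$table)
  n_clamped <- sum(attr(esd, "clamped"))
  populations$esd <- as.numeric(esd)
  populations$volume <- esd_to_volume(populations$esd)
  populations$quota <- carbon_quota(populations$volume, model)
  populations$biomass <- carbon_biomass(populations$abundance,
                                        populations$quota,
                                        unit = "1e6_cells_per_l")
  attr(populations, "index_selection") <-
    sel[c("refractive_index", "medians")]
  attr(populations, "n_clamped") <- n_clamped
  populations
}
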