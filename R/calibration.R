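#' Scatter-to-size calibration tables
#'
#' A calibration table maps bead-normalized forward light scatter to
#' equivalent spherical diameter (ESD, micrometres) for one candidate
#' refractive index. Tables are interpolated log-log between nodes because
#' scatter spans several decades.
#'
#' @param scatter Numeric vector of bead-normalized scatter values at the
#'   nodes (dimensionless, strictly increasing, > 0).
#' @param esd Numeric vector of ESD values at the nodes (micrometres,
#'   strictly increasing, > 0).
#' @param refractive_index Scalar refractive index this table was computed
#'   for (e.g. 1.35, 1.38, 1.41).
#' @return An object of class `calibration_table`.
#' @examples
#' tab <- calibration_table(c(0.01, 0.1, 1), c(0.3, 0.8, 2.0), 1.38)
#' scatter_to_esd(0.1, tab)
#' @export
calibration_table <- function(scatter, esd, refractive_index) {
  stopifnot(is.numeric(scatter), is.numeric(esd),
            length(scatter) == length(esd))
  if (length(scatter) < 2L)
    stop("calibration table needs at least 2 nodes")
  if (any(!is.finite(scatter)) || any(!is.finite(esd)))
    stop("calibration nodes must be finite")
  if (any(scatter <= 0) || any(esd <= 0))
    stop("calibration nodes must be positive")
  if (any(diff(scatter) <= 0) || any(diff(esd) <= 0))
    stop("calibration table must be strictly increasing in scatter and ESD")
  structure(
    list(refractive_index = as.numeric(refractive_index),
         scatter = as.numeric(scatter),
         esd = as.numeric(esd)),
    class = "calibration_table"
  )
}

#' @export
print.calibration_table <- function(x, ...) {
  cat(sprintf("<calibration_table> n = %.2f, %d nodes, ESD %.3g-%.3g um\n",
              x$refractive_index, length(x$esd), min(x$esd), max(x$esd)))
  invisible(x)
}

#' Default synthetic calibration-table family
#'
#' A power-law stand-in for Mie-theory lookup tables: scatter = c * ESD^k
#' with a per-index exponent k and scale c chosen so that a higher
#' refractive index scatters more light at the same cell size. These tables
#' are synthetic; real analyses should supply instrument-specific tables via
#' [read_calibration_table()].
#'
#' @param esd_range Range of ESD covered by the nodes (micrometres).
#' @param n_nodes Number of log-spaced nodes.
#' @return Named list of [calibration_table()] objects keyed by refractive
#'   index ("1.35", "1.38", "1.41").
#' @export
default_calibration_tables <- function(esd_range = c(0.2, 8), n_nodes = 25L) {
  # scales spaced so adjacent candidates disagree by ~11% in recovered ESD
  # at Prochlorococcus sizes, comparable to Mie tables at these indices
  idx <- c(1.35, 1.38, 1.41)
  k <- c(3.45, 3.5, 3.55)
  scale <- c(0.70, 1.00, 1.44)
  esd <- exp(seq(log(esd_range[1]), log(esd_range[2]), length.out = n_nodes))
  tabs <- lapply(seq_along(idx), function(i) {
    calibration_table(scale[i] * esd^k[i], esd, idx[i])
  })
  names(tabs) <- format(idx, nsmall = 2)
  tabs
}

#' Convert bead-normalized scatter to equivalent spherical diameter
#'
#' Interpolates log-log linearly between calibration nodes. Scatter outside
#' the table support is clamped to the end nodes and flagged via the
#' `"clamped"` attribute of the result.
#'
#' @param scatter Numeric vector of bead-normalized scatter values (> 0).
#' @param table A [calibration_table()].
#' @return Numeric vector of ESD (micrometres) with a logical attribute
#'   `"clamped"` marking out-of-range inputs.
#' @export
scatter_to_esd <- function(scatter, table) {
  stopifnot(inherits(table, "calibration_table"))
  if (any(scatter[!is.na(scatter)] <= 0))
    stop("scatter values must be positive")
  clamped <- !is.na(scatter) &
    (scatter < table$scatter[1] | scatter > table$scatter[length(table$scatter)])
  out <- exp(stats::approx(log(table$scatter), log(table$esd),
                           xout = log(scatter), rule = 2)$y)
  attr(out, "clamped") <- clamped
  out
}

#' Invert a calibration table: ESD to scatter
#'
#' Inverse of [scatter_to_esd()] on the same log-log piecewise-linear
#' curve; used by the synthetic-cruise generator to emit scatter values that
#' round-trip exactly through the table.
#'
#' @inheritParams scatter_to_esd
#' @param esd Numeric vector of ESD values (micrometres, > 0).
#' @return Numeric vector of bead-normalized scatter.
#' @export
esd_to_scatter <- function(esd, table) {
  stopifnot(inherits(table, "calibration_table"))
  if (any(esd[!is.na(esd)] <= 0))
    stop("esd values must be positive")
  exp(stats::approx(log(table$esd), log(table$scatter),
                    xout = log(esd), rule = 2)$y)
}

#' Select the refractive index matching a reference cell size
#'
#' Scatter intensity drifts with instrument alignment, so the working
#' refractive index is chosen per cruise: the candidate table whose median
#' Prochlorococcus ESD is closest to a reference measurement (0.6 um at
#' Station ALOHA) wins.
#'
#' @param scatter Bead-normalized scatter sample for Prochlorococcus.
#' @param tables List of candidate [calibration_table()] objects.
#' @param reference Reference ESD in micrometres (default 0.6).
#' @return A list with elements `table` (the chosen table),
#'   `refractive_index`, and `medians` (tibble of per-candidate median ESD
#'   and distance to the reference).
#' @export
select_refractive_index <- function(scatter, tables, reference = 0.6) {
  scatter <- scatter[is.finite(scatter)]
  if (length(scatter) < 1L)
    stop("need at least one finite Prochlorococcus scatter value")
  if (length(tables) < 1L)
    stop("need at least one candidate calibration table")
  stopifnot(all(vapply(tables, inherits, logical(1), "calibration_table")))
  med <- vapply(tables, function(tab) {
    stats::median(scatter_to_esd(scatter, tab))
  }, numeric(1))
  dist <- abs(med - reference)
  pick <- which.min(dist)
  medians <- tibble::tibble(
    refractive_index = vapply(tables, `[[`, numeric(1), "refractive_index"),
    median_esd = unname(med),
    distance = unname(dist)
  )
  list(table = tables[[pick]],
       refractive_index = tables[[pick]]$refractive_index,
       medians = medians)
}

#' Read / write a calibration table
#'
#' Plain two-column delimited text (`scatter,esd`) with a `# refractive_index:`
#' header comment naming the index.
#'
#' @param path File path.
#' @return [read_calibration_table()] returns a [calibration_table()].
#' @export
read_calibration_table <- function(path) {
  header <- readLines(path, n = 1L)
  ri <- as.numeric(sub(".*refractive_index:\\s*", "", header))
  if (!is.finite(ri))
    stop("first line must be a '# refractive_index: <value>' comment")
  d <- utils::read.csv(path, comment.char = "#")
  calibration_table(d$scatter, d$esd, ri)
}

#' @rdname read_calibration_table
#' @param table A [calibration_table()] to write.
#' @export
write_calibration_table <- function(table, path) {
  stopifnot(inherits(table, "calibration_table"))
  writeLines(c(
    sprintf("# refractive_index: %s", table$refractive_index),
    "scatter,esd",
    paste(format(table$scatter, digits = 15, scientific = FALSE, trim = TRUE),
          format(table$esd, digits = 15, scientific = FALSE, trim = TRUE),
          sep = ",")
  ), path)
  invisible(path)
}
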