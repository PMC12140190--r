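#' Cumulative along-track distance
#'
#' Haversine great-circle distance (Earth radius 6371.0 km) between
#' successive positions, accumulated from zero at the first position.
#'
#' @param latitude,longitude Position vectors in decimal degrees.
#' @return Numeric vector of cumulative km, starting at 0.
#' @export
along_track_distance <- function(latitude, longitude) {
  stopifnot(length(latitude) == length(longitude), length(latitude) >= 2L)
  if (any(!is.finite(latitude)) || any(!is.finite(longitude)))
    stop("positions must be finite")
  if (any(latitude < -90 | latitude > 90))
    stop("latitudes must lie in [-90, 90]")
  p <- cbind(longitude, latitude)
  seg <- geosphere::distHaversine(p[-nrow(p), , drop = FALSE],
                                  p[-1, , drop = FALSE], r = 6371.0)
  c(0, cumsum(seg))
}

#' Smoothing spline of salinity along the track
#'
#' Fits a smoothing spline to salinity as a function of along-track
#' distance so the salinity gradient can be evaluated analytically anywhere
#' on the track. The smoothing parameter is chosen by generalized
#' cross-validation unless `spar` is supplied.
#'
#' @param along_track_km Along-track coordinate (km).
#' @param salinity Salinity (PSU) aligned with `along_track_km`.
#' @param spar Optional smoothing parameter passed to
#'   [stats::smooth.spline()]; `NULL` (default) uses GCV.
#' @return An object of class `salinity_spline`.
#' @export
smooth_salinity <- function(along_track_km, salinity, spar = NULL) {
  ok <- is.finite(along_track_km) & is.finite(salinity)
  if (sum(ok) < 4L) stop("need at least 4 finite (distance, salinity) points")
  x <- along_track_km[ok]; y <- salinity[ok]
  # every unique location is a knot: hydrographic fronts can be narrower
  # than the default knot spacing, which would smear the gradient peak
  fit <- if (is.null(spar)) {
    stats::smooth.spline(x, y, cv = FALSE, all.knots = TRUE)
  } else {
    stats::smooth.spline(x, y, spar = spar, all.knots = TRUE)
  }
  structure(list(fit = fit, x = sort(unique(x)), range = range(x)),
            class = "salinity_spline")
}

#' Evaluate a salinity spline or its derivative
#'
#' @param object A [smooth_salinity()] fit.
#' @param x Along-track km at which to evaluate.
#' @param deriv Derivative order (0 = salinity, 1 = dS/dx).
#' @param ... Unused.
#' @return Numeric vector.
#' @export
predict.salinity_spline <- function(object, x = object$x, deriv = 0, ...) {
  stats::predict(object$fit, x = x, deriv = deriv)$y
}

#' Detect the salinity front bounding the gyre
#'
#' Candidate fronts are local maxima of the absolute along-track salinity
#' gradient |dS/dx| above a prominence floor (a fraction of the global
#' maximum gradient). When several candidates survive, the one whose spline
#' salinity is closest to the reference gyre salinity (35 PSU) is selected
#' as the gyre boundary.
#'
#' @param spline A [smooth_salinity()] fit.
#' @param grid Along-track evaluation grid (km); defaults to the data
#'   locations used for the fit.
#' @param reference Reference salinity in PSU (default 35).
#' @param prominence Candidate floor as a fraction of the global maximum
#'   |dS/dx| (default 0.1).
#' @return An object of class `front_estimate`: a list with `candidates`
#'   (tibble of `along_track_km`, `salinity`, `gradient`), `selected`
#'   (one-row tibble or `NULL` when no candidate clears the floor),
#'   `reference`, `grid_step`.
#' @export
detect_front <- function(spline, grid = NULL, reference = 35,
                         prominence = 0.1) {
  stopifnot(inherits(spline, "salinity_spline"))
  if (is.null(grid)) grid <- spline$x
  grid <- sort(grid)
  if (diff(range(grid)) <= 0) stop("spline must span a positive track length")
  g <- abs(predict(spline, grid, deriv = 1))
  n <- length(g)
  floor_val <- prominence * max(g)
  # a small rise tolerance so numerical ripple on a flat gradient does not
  # masquerade as a candidate front
  tol <- 1e-3 * max(g)
  is_peak <- c(FALSE, g[2:(n - 1)] > g[1:(n - 2)] + tol &
                 g[2:(n - 1)] >= g[3:n] - tol, FALSE) & g >= floor_val
  cand_idx <- which(is_peak)
  candidates <- tibble::tibble(
    along_track_km = grid[cand_idx],
    salinity = predict(spline, grid[cand_idx]),
    gradient = g[cand_idx]
  )
  selected <- NULL
  if (nrow(candidates) > 0) {
    pick <- which.min(abs(candidates$salinity - reference))
    selected <- candidates[pick, ]
  }
  structure(list(candidates = candidates, selected = selected,
                 reference = reference,
                 grid_step = stats::median(diff(grid))),
            class = "front_estimate")
}

#' @export
print.front_estimate <- function(x, ...) {
  if (is.null(x$selected)) {
    cat("<front_estimate> no front above the prominence floor\n")
  } else {
    cat(sprintf(
      "<front_estimate> front at %.1f km (S = %.2f PSU, |dS/dx| = %.4g), %d candidate(s)\n",
      x$selected$along_track_km, x$selected$salinity, x$selected$gradient,
      nrow(x$candidates)))
  }
  invisible(x)
}

#' Signed distance from the gyre boundary
#'
#' Distance from the selected front, negative inside the gyre. Which side
#' of the front is "inside" is decided by spline salinity: the side whose
#' median salinity is closer to the reference gyre salinity. The
#' convention can be overridden when a transect is known to start outside
#' the gyre.
#'
#' @param along_track_km Along-track coordinates (km).
#' @param front A [detect_front()] result with a selected front.
#' @param spline The [smooth_salinity()] fit used for the detection.
#' @param gyre_side `"auto"` (default), `"before"` (gyre on the low-km
#'   side), or `"after"`.
#' @return Numeric vector of signed km (negative inside the gyre).
#' @export
signed_distance <- function(along_track_km, front, spline,
                            gyre_side = c("auto", "before", "after")) {
  gyre_side <- match.arg(gyre_side)
  stopifnot(inherits(front, "front_estimate"))
  if (is.null(front$selected))
    stop("no selected front: signed distances are undefined")
  f <- front$selected$along_track_km
  if (gyre_side == "auto") {
    x <- spline$x
    before <- stats::median(predict(spline, x[x < f]))
    after <- stats::median(predict(spline, x[x > f]))
    gyre_side <- if (abs(before - front$reference) <=
                       abs(after - front$reference)) "before" else "after"
  }
  d <- along_track_km - f
  if (gyre_side == "before") d else -d
}

#' Width of the transition zone around the front
#'
#' The transition zone is the contiguous interval around the selected front
#' where the salinity gradient magnitude stays at or above a fraction
#' `alpha` of its peak value at the front. For a noiseless logistic front
#' of scale `l` km and `alpha = 0.5` the width is `2 * acosh(3) * l`
#' (about `3.53 * l`).
#'
#' @param spline A [smooth_salinity()] fit.
#' @param front A [detect_front()] result with a selected front.
#' @param alpha Gradient fraction defining the zone (default 0.5).
#' @param n_grid Evaluation grid resolution (default 2000 points).
#' @return Width in km (boundaries refined by linear interpolation).
#' @export
transition_zone_width <- function(spline, front, alpha = 0.5,
                                  n_grid = 2000L) {
  stopifnot(inherits(front, "front_estimate"))
  if (is.null(front$selected))
    stop("no selected front: transition zone undefined")
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  f <- front$selected$along_track_km
  grid <- seq(spline$range[1], spline$range[2], length.out = n_grid)
  g <- abs(predict(spline, grid, deriv = 1))
  peak <- abs(predict(spline, f, deriv = 1))
  thr <- alpha * peak
  i0 <- which.min(abs(grid - f))
  lo <- i0
  while (lo > 1L && g[lo - 1L] >= thr) lo <- lo - 1L
  hi <- i0
  while (hi < n_grid && g[hi + 1L] >= thr) hi <- hi + 1L
  # refine both boundaries by linear interpolation of g across the crossing
  x_lo <- grid[lo]
  if (lo > 1L) {
    x_lo <- grid[lo - 1L] + (thr - g[lo - 1L]) / (g[lo] - g[lo - 1L]) *
      (grid[lo] - grid[lo - 1L])
  }
  x_hi <- grid[hi]
  if (hi < n_grid) {
    x_hi <- grid[hi] + (thr - g[hi]) / (g[hi + 1L] - g[hi]) *
      (grid[hi + 1L] - grid[hi])
  }
  x_hi - x_lo
}
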