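#' Multiplicative moving-average decomposition
#'
#' Splits a strictly positive hourly series into a slowly varying trend and
#' a dimensionless diel component, `observed = trend * detrended`. The
#' trend is the classic centered moving average over the diel period: for
#' an even window of w hours, a (w+1)-point window with half-weight
#' endpoints (the 2 x w convention), so a 24-hour periodic signal averages
#' to its period mean. The trend -- and hence the detrended ratio -- is
#' undefined in the half-window edges and wherever the window contains a
#' missing value.
#'
#' @param x Strictly positive numeric series at regular (hourly) spacing;
#'   `NA`s are allowed and propagate into the trend.
#' @param window Moving-window length in samples (default 24).
#' @return A tibble with columns `observed`, `trend`, `detrended` and a
#'   `"window"` attribute.
#' @export
decompose_multiplicative <- function(x, window = 24L) {
  x <- as.numeric(x)
  if (any(!is.na(x) & x <= 0))
    stop("multiplicative decomposition requires a strictly positive series")
  if (length(x) < 2L * window)
    stop("series must span at least two windows")
  if (window %% 2 == 0) {
    w <- c(0.5, rep(1, window - 1), 0.5) / window
  } else {
    w <- rep(1, window) / window
  }
  trend <- as.numeric(stats::filter(x, w, sides = 2))
  out <- tibble::tibble(observed = x, trend = trend,
                        detrended = x / trend)
  attr(out, "window") <- window
  out
}

#' Daily daylight windows from a PAR series
#'
#' Daytime is defined by PAR above a threshold (default 10 umol photons
#' m-2 s-1). Crossing times are linearly interpolated between consecutive
#' samples; within each calendar date, sunrise is the first upward crossing
#' and sunset the last downward crossing (a first-up/last-down rule, so
#' transient cloud-induced dips do not split the day). Days without a
#' complete window yield no row.
#'
#' @param timestamps POSIXct vector, strictly increasing.
#' @param par PAR series aligned with `timestamps` (>= 0).
#' @param threshold PAR threshold (default 10).
#' @return Tibble with `date`, `sunrise`, `sunset`, `daylight_hours`.
#' @export
daylight_windows <- function(timestamps, par, threshold = 10) {
  ok <- !is.na(par)
  if (!any(ok)) stop("PAR series is entirely missing")
  stopifnot(length(timestamps) == length(par))
  t <- as.numeric(timestamps)
  n <- length(par)
  i <- seq_len(n - 1L)
  p0 <- par[i]; p1 <- par[i + 1L]
  both <- !is.na(p0) & !is.na(p1)
  up <- both & p0 <= threshold & p1 > threshold
  down <- both & p0 > threshold & p1 <= threshold
  cross_time <- function(j) {
    frac <- (threshold - par[j]) / (par[j + 1L] - par[j])
    t[j] + frac * (t[j + 1L] - t[j])
  }
  ups <- vapply(which(up), cross_time, numeric(1))
  downs <- vapply(which(down), cross_time, numeric(1))
  origin <- as.POSIXct("1970-01-01", tz = "UTC")
  up_dates <- as.Date(as.POSIXct(ups, origin = origin, tz = "UTC"))
  down_dates <- as.Date(as.POSIXct(downs, origin = origin, tz = "UTC"))
  dates <- sort(unique(c(up_dates, down_dates)))
  rows <- lapply(dates, function(d) {
    sr <- ups[up_dates == d]
    ss <- downs[down_dates == d]
    if (!length(sr) || !length(ss)) return(NULL)
    sr <- min(sr)
    ss <- ss[ss > sr]
    if (!length(ss)) return(NULL)
    ss <- max(ss)
    tibble::tibble(
      date = d,
      sunrise = as.POSIXct(sr, origin = origin, tz = "UTC"),
      sunset = as.POSIXct(ss, origin = origin, tz = "UTC"),
      daylight_hours = (ss - sr) / 3600
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L)
    out <- tibble::tibble(date = as.Date(character()),
                          sunrise = as.POSIXct(character(), tz = "UTC"),
                          sunset = as.POSIXct(character(), tz = "UTC"),
                          daylight_hours = numeric())
  attr(out, "threshold") <- threshold
  out
}

#' Fit one population-day growth rate
#'
#' Ordinary least squares of the natural log of the rescaled detrended
#' carbon quota on hours since sunrise, using only daytime hours whose cell
#' abundance clears the detection floor. The detrended ratio is multiplied
#' by the day's mean trend before the log transform so the intercept
#' `exp(b0)` is an interpretable sunrise quota in pgC; the slope is
#' unaffected by any positive rescaling. The hourly rate is converted to a
#' daily rate by multiplying by the daylight duration. A fit is accepted
#' when it uses more than 6 hourly observations and its slope p-value
#' (two-sided t test against zero slope) is at most 0.01.
#'
#' @param data Tibble for one population with columns `timestamp`,
#'   `detrended`, `trend`, `abundance` (10^6 cells/L).
#' @param window One row of [daylight_windows()] (a `date`, `sunrise`,
#'   `sunset`, `daylight_hours` record).
#' @param population Population label carried into the result.
#' @param abundance_floor Minimum abundance (10^6 cells/L) for an hourly
#'   observation to count (default 0.02).
#' @return One-row tibble: `population`, `date`, `r_hourly`, `r_daily`,
#'   `q_c0`, `n_obs`, `p_value`, `daylight_hours`, `accepted`. Fits with
#'   fewer than 2 usable points are reported with `NA` estimates rather
#'   than raising an error.
#' @export
fit_daily_growth <- function(data, window, population = NA_character_,
                             abundance_floor = 0.02) {
  stopifnot(all(c("timestamp", "detrended", "trend", "abundance") %in%
                  names(data)))
  day <- data[data$timestamp >= window$sunrise &
                data$timestamp <= window$sunset, , drop = FALSE]
  usable <- !is.na(day$detrended) & !is.na(day$abundance) &
    day$abundance >= abundance_floor
  day <- day[usable, , drop = FALSE]
  n_obs <- nrow(day)
  empty <- tibble::tibble(
    population = population, date = window$date,
    r_hourly = NA_real_, r_daily = NA_real_, q_c0 = NA_real_,
    n_obs = n_obs, p_value = NA_real_,
    daylight_hours = window$daylight_hours, accepted = FALSE
  )
  if (n_obs < 2L) return(empty)
  t <- as.numeric(difftime(day$timestamp, window$sunrise, units = "hours"))
  q <- day$detrended * mean(day$trend)
  y <- log(q)
  if (stats::var(t) == 0) return(empty)
  xm <- t - mean(t); ym <- y - mean(y)
  sxx <- sum(xm^2)
  slope <- sum(xm * ym) / sxx
  intercept <- mean(y) - slope * mean(t)
  resid <- ym - slope * xm
  df <- n_obs - 2L
  if (df > 0) {
    se <- sqrt(sum(resid^2) / df / sxx)
    p <- if (se == 0) {
      if (slope == 0) 1 else 0
    } else {
      2 * stats::pt(-abs(slope / se), df)
    }
  } else {
    p <- NA_real_
  }
  accepted <- isTRUE(n_obs > 6 && !is.na(p) && p <= 0.01)
  tibble::tibble(
    population = population, date = window$date,
    r_hourly = slope,
    r_daily = slope * window$daylight_hours,
    q_c0 = exp(intercept),
    n_obs = n_obs, p_value = p,
    daylight_hours = window$daylight_hours,
    accepted = accepted
  )
}

#' Estimate daily growth rates for every population and day
#'
#' Chains the diel machinery: per population, the hourly carbon-quota
#' series is detrended by [decompose_multiplicative()], daylight windows
#' are derived from the underway PAR series, and each population-day is fit
#' with [fit_daily_growth()].
#'
#' @param populations Tibble with columns `timestamp`, `population`,
#'   `quota` (pgC per cell), `abundance` (10^6 cells/L), hourly.
#' @param underway Tibble with `timestamp` and `par`.
#' @param par_threshold PAR threshold defining daytime (default 10).
#' @param window Decomposition window in hours (default 24).
#' @param abundance_floor Hourly abundance floor (default 0.02).
#' @return Tibble of growth fits (one row per population-day).
#' @export
estimate_growth <- function(populations, underway, par_threshold = 10,
                            window = 24L, abundance_floor = 0.02) {
  stopifnot(all(c("timestamp", "population", "quota", "abundance") %in%
                  names(populations)))
  windows <- daylight_windows(underway$timestamp, underway$par,
                              threshold = par_threshold)
  fits <- lapply(split(populations, populations$population), function(d) {
    d <- d[order(d$timestamp), , drop = FALSE]
    dec <- decompose_multiplicative(d$quota, window = window)
    dd <- tibble::tibble(timestamp = d$timestamp,
                         detrended = dec$detrended,
                         trend = dec$trend,
                         abundance = d$abundance)
    dplyr::bind_rows(lapply(seq_len(nrow(windows)), function(i) {
      fit_daily_growth(dd, windows[i, ], population = d$population[1],
                       abundance_floor = abundance_floor)
    }))
  })
  out <- dplyr::bind_rows(fits)
  rownames(out) <- NULL
  out
}
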