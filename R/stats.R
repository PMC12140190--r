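#' Bin a table of variables over time or distance
#'
#' Aggregates every numeric variable into fixed-width bins of the key
#' (24-hour periods for the temporal binning that damps diel
#' autocorrelation, or 100-km intervals for spatial summaries), reporting
#' per-bin mean, standard deviation and count. Empty bins are omitted.
#'
#' @param data Data frame holding the key column and numeric variables.
#' @param key Name of the binning key column (POSIXct, Date, or numeric).
#' @param width Bin width: hours when the key is a timestamp, days when it
#'   is a Date, key units otherwise. Must be positive.
#' @param origin Bin origin; defaults to the minimum key (timestamps are
#'   floored to the day so 24-h bins align with calendar days).
#' @return Tibble with `bin` (left edge, key units), `n`, and
#'   `<var>_mean` / `<var>_sd` columns for each numeric variable.
#' @export
bin_series <- function(data, key, width, origin = NULL) {
  stopifnot(width > 0, key %in% names(data))
  k <- data[[key]]
  if (inherits(k, "POSIXct")) {
    kx <- as.numeric(k) / 3600          # hours
    if (is.null(origin))
      origin <- as.numeric(as.POSIXct(format(min(k), "%Y-%m-%d"),
                                      tz = "UTC")) / 3600
  } else if (inherits(k, "Date")) {
    kx <- as.numeric(k)
    if (is.null(origin)) origin <- min(kx)
  } else {
    kx <- as.numeric(k)
    if (is.null(origin)) origin <- min(kx, na.rm = TRUE)
  }
  idx <- floor((kx - origin) / width)
  vars <- names(data)[vapply(data, is.numeric, logical(1))]
  vars <- setdiff(vars, key)
  groups <- split(seq_along(kx), idx)
  rows <- lapply(names(groups), function(b) {
    g <- groups[[b]]
    row <- list(bin = origin + as.numeric(b) * width, n = length(g))
    for (v in vars) {
      vals <- data[[v]][g]
      row[[paste0(v, "_mean")]] <- mean(vals, na.rm = TRUE)
      row[[paste0(v, "_sd")]] <- stats::sd(vals, na.rm = TRUE)
    }
    tibble::as_tibble(row)
  })
  if (!length(rows)) {
    empty <- c(list(bin = numeric(), n = integer()),
               stats::setNames(rep(list(numeric()), 2 * length(vars)),
                               c(paste0(vars, "_mean"), paste0(vars, "_sd"))))
    return(tibble::as_tibble(empty))
  }
  out <- dplyr::bind_rows(rows)
  out <- out[order(out$bin), , drop = FALSE]
  if (inherits(k, "POSIXct")) {
    out$bin <- as.POSIXct(out$bin * 3600,
                          origin = as.POSIXct("1970-01-01", tz = "UTC"),
                          tz = "UTC")
  } else if (inherits(k, "Date")) {
    out$bin <- as.Date(out$bin, origin = as.Date("1970-01-01"))
  }
  out
}

#' Welch two-sample t test
#'
#' Location test for two groups without assuming equal variances
#' (Satterthwaite degrees of freedom). A thin, validated wrapper used for
#' the inside- versus outside-gyre contrasts.
#'
#' @param a,b Numeric samples (each n >= 2, not both zero-variance).
#' @param alternative `"two.sided"`, `"greater"` (a > b), or `"less"`.
#' @return One-row tibble: `statistic`, `df`, `p_value`, `alternative`,
#'   `n_a`, `n_b`, `mean_a`, `mean_b`.
#' @export
welch_t_test <- function(a, b,
                         alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 finite observations")
  if (stats::var(a) == 0 && stats::var(b) == 0)
    stop("both groups have zero variance; the Welch statistic is undefined")
  ht <- stats::t.test(a, b, alternative = alternative, var.equal = FALSE)
  tibble::tibble(
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value,
    alternative = alternative,
    n_a = length(a), n_b = length(b),
    mean_a = mean(a), mean_b = mean(b)
  )
}

#' Pairwise Pearson correlation screen with FDR control
#'
#' Computes Pearson correlations between all pairs of numeric variables on
#' pairwise-complete observations (casewise deletion per pair), then
#' applies the Benjamini-Hochberg step-up adjustment across the whole
#' family of pairs and flags significance at the requested false discovery
#' rate. Pairs with fewer complete observations than `min_n` are omitted
#' and listed in the `"omitted"` attribute.
#'
#' @param data Data frame of numeric variables (typically 24-h bin means).
#' @param fdr False discovery rate for the significance flag (default
#'   0.01).
#' @param min_n Minimum complete pairs per entry (default 3).
#' @return Tibble with `var1`, `var2`, `r`, `n`, `p_raw`, `p_adj`,
#'   `significant`; omitted pairs recorded in `attr(., "omitted")`.
#' @export
correlation_matrix <- function(data, fdr = 0.01, min_n = 3L) {
  stopifnot(fdr > 0, fdr < 1)
  vars <- names(data)[vapply(data, is.numeric, logical(1))]
  if (length(vars) < 2L) stop("need at least two numeric variables")
  pairs <- utils::combn(vars, 2, simplify = FALSE)
  rows <- list(); omitted <- list()
  for (pr in pairs) {
    x <- data[[pr[1]]]; y <- data[[pr[2]]]
    ok <- is.finite(x) & is.finite(y)
    n <- sum(ok)
    if (n < min_n) {
      omitted[[length(omitted) + 1L]] <- tibble::tibble(
        var1 = pr[1], var2 = pr[2], n = n,
        reason = sprintf("fewer than %d complete pairs", min_n))
      next
    }
    if (stats::var(x[ok]) == 0 || stats::var(y[ok]) == 0) {
      omitted[[length(omitted) + 1L]] <- tibble::tibble(
        var1 = pr[1], var2 = pr[2], n = n,
        reason = "zero variance on complete pairs")
      next
    }
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    rows[[length(rows) + 1L]] <- tibble::tibble(
      var1 = pr[1], var2 = pr[2],
      r = unname(ct$estimate), n = n, p_raw = ct$p.value)
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) > 0) {
    out$p_adj <- stats::p.adjust(out$p_raw, method = "BH")
    out$significant <- out$p_adj <= fdr
  } else {
    out <- tibble::tibble(var1 = character(), var2 = character(),
                          r = numeric(), n = integer(), p_raw = numeric(),
                          p_adj = numeric(), significant = logical())
  }
  attr(out, "omitted") <- dplyr::bind_rows(omitted)
  out
}

#' Redfield bound on nutrients released by complete cell lysis
#'
#' Upper bound, via Redfield stoichiometry (C:N:P = 106:16:1, C = 12.011
#' g/mol), on the dissolved nitrogen and phosphorus that complete lysis of
#' a given standing phytoplankton carbon biomass could contribute to an
#' unfiltered seawater sample.
#'
#' @param biomass Carbon biomass in ugC per litre (>= 0).
#' @return Tibble with `n_bound_nmol` and `p_bound_nmol` (nmol/L).
#' @export
redfield_lysis_bound <- function(biomass) {
  if (any(!is.na(biomass) & biomass < 0))
    stop("biomass must be non-negative")
  c_umol <- biomass / 12.011
  tibble::tibble(
    n_bound_nmol = c_umol * 16 / 106 * 1000,
    p_bound_nmol = c_umol * 1 / 106 * 1000
  )
}
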