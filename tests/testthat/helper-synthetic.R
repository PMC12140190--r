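# shared fixtures: all built in code at test time

# a cruise whose per-population growth rates are spatially constant, so the
# diel quota signal is exactly 24-h periodic and rate recovery can be exact
constant_rate_config <- function(rates = c(0.43, 0.26, 0.20, 0.11), ...) {
  pops <- default_population_truth()
  pops$rate_inside <- rates
  pops$rate_outside <- rates
  cruise_config(populations = pops, ...)
}

noiseless_config <- function(...) {
  constant_rate_config(noise_sigma = 0, salinity_noise_sd = 0,
                       nutrient_sigma = 0, ...)
}

# textbook Welch formulas, kept independent of welch_t_test()
welch_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# literal Benjamini-Hochberg step-up: reject H_(1..k) for the largest k
# with p_(k) <= k * q / m
bh_stepup_oracle <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= seq_len(m) * q / m)
  reject_sorted <- rep(FALSE, m)
  if (length(k)) reject_sorted[seq_len(max(k))] <- TRUE
  reject <- logical(m)
  reject[o] <- reject_sorted
  reject
}
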