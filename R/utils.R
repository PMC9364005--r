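# Internal numeric helpers shared across modules.

# Wrap angles (radians) into [0, 2*pi).
wrap_2pi <- function(theta) {
  out <- theta %% (2 * pi)
  out[out < 0] <- out[out < 0] + 2 * pi
  out
}

# Circular mean of angles in radians, NA-aware; NA when no finite input.
circ_mean <- function(theta) {
  theta <- theta[is.finite(theta)]
  if (length(theta) == 0L) return(NA_real_)
  wrap_2pi(atan2(mean(sin(theta)), mean(cos(theta))))
}

# Centred moving average with a window that shrinks at the record edges, so
# that the complement (raw - smooth) is exact everywhere.  `halfwidth` is in
# samples; the full window is 2 * halfwidth + 1.
rolling_mean_shrink <- function(x, halfwidth) {
  n <- length(x)
  if (n == 0L) return(numeric(0))
  idx <- seq_len(n)
  lo <- pmax(idx - halfwidth, 1L)
  hi <- pmin(idx + halfwidth, n)
  cs <- cumsum(c(0, x))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Sample skewness; 0 for constant or short series.
sample_skewness <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3L) return(0)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 <= 0) return(0)
  mean((x - m)^3) / s2^1.5
}

# Gain of a centred discrete boxcar (length n_win samples) at frequency
# `freq` Hz for data sampled at `rate` Hz (Dirichlet kernel).
boxcar_gain <- function(freq, rate, n_win) {
  r <- pi * freq / rate
  if (abs(sin(r)) < 1e-12) return(1)
  sin(n_win * r) / (n_win * sin(r))
}

# E|a * sin(phase) + eps| for eps ~ N(0, sigma), averaged over a uniform
# phase; used to calibrate planted wingbeat amplitudes against a target
# rectified mean.
expected_abs_sine_noise <- function(a, sigma, n_phase = 128L) {
  phi <- (seq_len(n_phase) - 0.5) / n_phase * 2 * pi
  c_ <- a * sin(phi)
  if (sigma <= 0) return(mean(abs(c_)))
  mean(sigma * sqrt(2 / pi) * exp(-c_^2 / (2 * sigma^2)) +
         c_ * (2 * pnorm(c_ / sigma) - 1))
}

# Linear interpolation that errors (rather than extrapolates) outside the
# support, with a caller-supplied message fragment.
interp_strict <- function(x, y, xout, what = "value") {
  if (any(xout < min(x) - 1e-9 | xout > max(x) + 1e-9)) {
    bad <- which(xout < min(x) - 1e-9 | xout > max(x) + 1e-9)[1L]
    abort(sprintf("%s at t = %.1f lies outside the series coverage [%.1f, %.1f]",
                  what, xout[bad], min(x), max(x)))
  }
  approx(x, y, xout = xout, rule = 2)$y
}

# The 16 dive-variable column names, in canonical order.
dive_variable_names <- function() {
  c("dur.desc", "dur.bott", "dur.asc", "dur.pdsi",
    "bottdist", "bottdep", "maxdep",
    "odba.desc", "odba.bott", "odba.asc",
    "angle.desc", "angle.bott", "angle.asc",
    "circ.var.desc", "circ.var.bott", "circ.var.asc")
}
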