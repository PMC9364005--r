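#' Simulate an hourly tide-gauge sea-level series
#'
#' Generates a semidiurnal sinusoidal sea level on an hourly grid, optionally
#' modulated by a spring/neap envelope, rescaled so that the realised
#' minimum-to-maximum excursion equals `range_m` exactly. The series emulates
#' a macro-tidal embayment gauge (two highs and two lows per lunar day,
#' excursions of order 10 m).
#'
#' @param duration_h Length of the series in hours (> 0).
#' @param range_m Full tidal range in metres (max minus min); 0 gives a
#'   constant series at `msl_m`.
#' @param period_h Tidal period in hours; the semidiurnal lunar constituent
#'   is 12.42 h. Must be positive.
#' @param phase Phase offset in radians at `t = 0`.
#' @param seed Optional integer seed (reserved for stochastic envelopes;
#'   the default generator is deterministic).
#' @param neap_depth Spring/neap modulation depth in `[0, 1)`; 0 disables the
#'   envelope. The envelope period is 354 h (half a synodic month).
#' @param msl_m Mean sea level in metres; levels are centred here. Defaults
#'   to `range_m / 2` so the series stays non-negative, as gauge data are
#'   usually reported above datum.
#'
#' @return A tibble with columns `time_s` (seconds, hourly steps) and
#'   `sea_level_m`.
#' @examples
#' tide <- simulate_tide(48, range_m = 10)
#' max(tide$sea_level_m) - min(tide$sea_level_m)
#' @export
simulate_tide <- function(duration_h, range_m = 10, period_h = 12.42,
                          phase = 0, seed = NULL, neap_depth = 0,
                          msl_m = range_m / 2) {
  if (!is.numeric(duration_h) || duration_h <= 0) {
    abort("`duration_h` must be positive")
  }
  if (range_m < 0) abort("`range_m` must be non-negative")
  if (period_h <= 0) abort("`period_h` must be positive")
  if (neap_depth < 0 || neap_depth >= 1) abort("`neap_depth` must be in [0, 1)")
  hours <- seq(0, ceiling(duration_h))
  if (range_m == 0) {
    return(tibble::tibble(time_s = hours * 3600, sea_level_m = rep(msl_m, length(hours))))
  }
  env <- 1 - neap_depth * (1 - cos(2 * pi * hours / 354)) / 2
  raw <- env * sin(2 * pi * hours / period_h + phase)
  span <- max(raw) - min(raw)
  level <- if (span > 0) (raw - (max(raw) + min(raw)) / 2) * (range_m / span) + msl_m
           else rep(msl_m, length(raw))
  tibble::tibble(time_s = hours * 3600, sea_level_m = level)
}

# Sea level (m) at arbitrary times (s), linearly interpolated.
tide_height_at <- function(tide, time_s) {
  interp_strict(tide$time_s, tide$sea_level_m, time_s, what = "tide height")
}

# Hourly forward-difference tide rate (m/h) interpolated to arbitrary times.
tide_diff_at <- function(tide, time_s) {
  n <- nrow(tide)
  if (n < 2L) abort("tide series needs at least two hourly values")
  d <- diff(tide$sea_level_m) / diff(tide$time_s / 3600)
  if (length(d) == 1L) return(rep(d, length(time_s)))
  approx(tide$time_s[-n], d, xout = time_s, rule = 2)$y
}
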