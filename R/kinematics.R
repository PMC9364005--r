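#' Zero-offset correct a depth record
#'
#' Pressure sensors drift, so raw depth rarely reads 0 m at the surface.
#' This removes the drift with a rolling surface baseline: the record is cut
#' into consecutive windows of `window_s`, the `surface_quantile` of each
#' window (default 0.02, i.e. close to the shallowest readings) is taken as
#' the local surface pressure, the per-window baselines are linearly
#' interpolated between window centres and subtracted. Corrected values are
#' clipped at a floor of -0.5 m and remaining negatives set to 0.
#'
#' @param depth Numeric depth vector (m, positive down), regularly sampled.
#' @param window_s Baseline window length in seconds (>= 60). If longer than
#'   the record a single global offset is used, with a warning.
#' @param surface_quantile Within-window quantile taken as surface level.
#' @param sample_rate Sampling rate of `depth` in Hz (default 1).
#' @return Corrected depth vector, same length.
#' @examples
#' d <- c(rep(0.4, 100), 0.4 + seq(0, 5, length.out = 50), rep(0.4, 100))
#' zero_offset_correct(d, window_s = 60)[1:5]
#' @export
zero_offset_correct <- function(depth, window_s = 3600, surface_quantile = 0.02,
                                sample_rate = 1) {
  if (window_s < 60) abort("`window_s` must be >= 60 s")
  n <- length(depth)
  if (n == 0L) return(depth)
  win <- round(window_s * sample_rate)
  if (win >= n) {
    warn("ZOC window longer than record; applying a single global offset")
    base <- quantile(depth, surface_quantile, na.rm = TRUE, names = FALSE)
    out <- depth - base
  } else {
    grp <- (seq_len(n) - 1L) %/% win
    centres <- tapply(seq_len(n), grp, mean)
    bases <- tapply(depth, grp, quantile, probs = surface_quantile,
                    na.rm = TRUE, names = FALSE)
    baseline <- approx(as.numeric(centres), as.numeric(bases),
                       xout = seq_len(n), rule = 2)$y
    out <- depth - baseline
  }
  out <- pmax(out, -0.5)
  out[out < 0] <- 0
  out
}

#' Resample a timestamped series to a uniform rate by bin means
#'
#' Averages samples within each output interval aligned to integer multiples
#' of the output step (for 1 Hz: the bin `[t, t+1)` is stamped `t`). Empty
#' bins inside gaps of at most `max_gap_s` are filled by linear
#' interpolation; longer gaps are left as `NA`. Circular channels (heading)
#' use the circular mean and sin/cos interpolation.
#'
#' @param time Sample timestamps, seconds, strictly increasing.
#' @param value Sample values (radians when `circular = TRUE`).
#' @param target_rate Output rate in Hz (default 1).
#' @param circular Treat `value` as an angle in radians.
#' @param max_gap_s Longest gap (s) bridged by interpolation.
#' @return A tibble with columns `time` and `value`.
#' @examples
#' resample_uniform(seq(0, 9.9, 0.1), rep(3, 100))
#' @export
resample_uniform <- function(time, value, target_rate = 1, circular = FALSE,
                             max_gap_s = 5) {
  if (length(time) == 0L) {
    return(tibble::tibble(time = numeric(0), value = numeric(0)))
  }
  dt <- 1 / target_rate
  bin <- floor(time / dt + 1e-9)
  grid <- seq(min(bin), max(bin))
  if (circular) {
    sx <- tapply(sin(value), bin, mean)
    cx <- tapply(cos(value), bin, mean)
    out <- rep(NA_real_, length(grid))
    m <- match(as.numeric(names(sx)), grid)
    out[m] <- wrap_2pi(atan2(as.numeric(sx), as.numeric(cx)))
  } else {
    means <- tapply(value, bin, mean)
    out <- rep(NA_real_, length(grid))
    out[match(as.numeric(names(means)), grid)] <- as.numeric(means)
  }
  out <- fill_short_gaps(grid, out, max_gap_s / dt, circular)
  tibble::tibble(time = grid * dt, value = out)
}

# Interpolate across NA runs no longer than `max_len` bins.
fill_short_gaps <- function(grid, x, max_len, circular) {
  na <- is.na(x)
  if (!any(na) || all(na)) return(x)
  r <- rle(na)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(!na)
  for (j in seq_along(r$lengths)) {
    if (!r$values[j] || r$lengths[j] > max_len) next
    idx <- starts[j]:ends[j]
    if (starts[j] == 1L || ends[j] == length(x)) next
    if (circular) {
      s <- approx(grid[ok], sin(x[ok]), xout = grid[idx])$y
      c_ <- approx(grid[ok], cos(x[ok]), xout = grid[idx])$y
      x[idx] <- wrap_2pi(atan2(s, c_))
    } else {
      x[idx] <- approx(grid[ok], x[ok], xout = grid[idx])$y
    }
  }
  x
}

#' Split raw acceleration into gravitational and dynamic components
#'
#' The gravitational (static) component is estimated per axis with a centred
#' box smoother whose window shrinks at the record edges, so the dynamic
#' component (`raw - static`) is the exact elementwise complement
#' everywhere.
#'
#' @param acc Data frame or matrix with three acceleration columns (surge,
#'   sway, heave, in g) at the native sampling rate.
#' @param window_s Smoother window in seconds (default 4).
#' @param sample_rate Native sampling rate in Hz.
#' @return A list with tibbles `static` and `dynamic` (same column names).
#' @examples
#' a <- data.frame(ax = rep(0, 100), ay = rep(0, 100), az = rep(1, 100))
#' split_acceleration(a, sample_rate = 20)$dynamic[1, ]
#' @export
split_acceleration <- function(acc, window_s = 4, sample_rate) {
  acc <- as.data.frame(acc)
  if (ncol(acc) != 3L) abort("`acc` must have exactly three axis columns")
  halfwidth <- floor(window_s * sample_rate / 2 + 1e-8)
  if (2L * halfwidth + 1L < 3L) {
    abort("smoother window must span at least 3 samples")
  }
  static <- lapply(acc, rolling_mean_shrink, halfwidth = halfwidth)
  static <- tibble::as_tibble(static)
  dynamic <- tibble::as_tibble(as.data.frame(acc) - as.data.frame(static))
  list(static = static, dynamic = dynamic)
}

#' Dynamic body acceleration metrics (ODBA and VeDBA)
#'
#' ODBA is the sum of the absolute dynamic accelerations over the three body
#' axes (an activity / energy-expenditure proxy); VeDBA is their Euclidean
#' norm (used here as a locomotion-speed proxy for dead-reckoning).
#'
#' @param dynamic Data frame or matrix of three dynamic-acceleration columns
#'   (g), e.g. `split_acceleration(...)$dynamic`.
#' @return A tibble with columns `odba_g` and `vedba_g`.
#' @examples
#' body_acceleration_metrics(data.frame(0.1, -0.2, 0.3))
#' @export
body_acceleration_metrics <- function(dynamic) {
  m <- as.matrix(as.data.frame(dynamic))
  if (ncol(m) != 3L) abort("`dynamic` must have exactly three axis columns")
  tibble::tibble(odba_g = rowSums(abs(m)),
                 vedba_g = sqrt(rowSums(m^2)))
}

#' Pitch angle from raw acceleration
#'
#' Body pitch (degrees, positive head-up) from the raw tri-axial
#' acceleration: `atan(AccX / sqrt(AccY^2 + AccZ^2)) * 180 / pi`, minus a
#' tag-placement correction offset, clamped to `[-90, 90]`. When the
#' lateral/dorsoventral components are both zero the sample maps to +/-90 by
#' the sign of the surge axis.
#'
#' @param ax,ay,az Raw acceleration components (g): surge, sway, heave.
#' @param correction_offset Mounting-angle offset in degrees subtracted from
#'   every sample (see [estimate_pitch_offset()]).
#' @return Pitch in degrees, same length as the inputs.
#' @examples
#' pitch_from_acceleration(-0.5, 0, 0.866)
#' @export
pitch_from_acceleration <- function(ax, ay, az, correction_offset = 0) {
  denom <- sqrt(ay^2 + az^2)
  pitch <- ifelse(denom == 0, 90 * sign(ax),
                  atan(ax / denom) * 180 / pi)
  pmin(pmax(pitch - correction_offset, -90), 90)
}

#' Estimate the tag-placement pitch offset
#'
#' A tag can rarely be mounted exactly parallel to the animal's body axis,
#' so measured pitch carries a constant offset. Following the convention of
#' calibrating against level swimming, the offset is the median measured
#' pitch over all samples in runs of at least `min_run_s` seconds where the
#' animal holds constant depth (|vertical velocity| below
#' `vv_threshold_mps`) while submerged (depth > 1 m).
#'
#' @param pitch Uncorrected 1 Hz pitch (deg).
#' @param depth Aligned 1 Hz depth (m).
#' @param vv_threshold_mps Vertical-velocity threshold (m/s).
#' @param min_run_s Minimum qualifying run length (s).
#' @return The offset in degrees, to be passed as `correction_offset`.
#' @export
estimate_pitch_offset <- function(pitch, depth, vv_threshold_mps = 0.05,
                                  min_run_s = 10) {
  if (length(pitch) != length(depth)) abort("`pitch` and `depth` lengths differ")
  vv <- c(0, diff(depth))
  flat <- abs(vv) < vv_threshold_mps & depth > 1 & !is.na(depth) & !is.na(pitch)
  flat[is.na(flat)] <- FALSE
  r <- rle(flat)
  ends <- cumsum(r$lengths)
  keep <- rep(FALSE, length(pitch))
  for (j in seq_along(r$lengths)) {
    if (r$values[j] && r$lengths[j] >= min_run_s) {
      keep[(ends[j] - r$lengths[j] + 1L):ends[j]] <- TRUE
    }
  }
  if (!any(keep)) {
    abort(paste("no level constant-depth swimming found;",
                "supply `correction_offset` manually"))
  }
  median(pitch[keep])
}

#' Tilt-compensated heading from static acceleration and magnetometer
#'
#' Roll and pitch derived from the gravitational (static) acceleration
#' rotate the magnetometer vector into the horizontal plane; heading is the
#' angle of the horizontal field component, in radians clockwise from
#' magnetic North (`0 = North`, `pi/2 = East`), wrapped to `[0, 2*pi)`.
#' Samples with pitch within 2 degrees of +/-90 are gimbal-degenerate: their
#' heading is interpolated from the neighbours and flagged.
#'
#' @param static_acc Three-column static acceleration (surge, sway, heave).
#' @param mag Three-column magnetometer in the same axis convention.
#' @return A tibble with `heading_rad` and logical `degenerate`.
#' @export
heading_from_sensors <- function(static_acc, mag) {
  a <- as.matrix(as.data.frame(static_acc))
  m <- as.matrix(as.data.frame(mag))
  if (ncol(a) != 3L || ncol(m) != 3L || nrow(a) != nrow(m)) {
    abort("`static_acc` and `mag` must be aligned with three columns each")
  }
  norm_a <- sqrt(rowSums(a^2))
  if (any(norm_a == 0)) abort("zero-norm static acceleration sample")
  theta <- atan2(a[, 1], sqrt(a[, 2]^2 + a[, 3]^2))   # pitch, rad
  phi <- atan2(-a[, 2], a[, 3])                       # roll, rad
  # De-tilt the field: body (right, fwd, up) = (Y, X, Z) sensor order.
  bx <- m[, 2]; by <- m[, 1]; bz <- m[, 3]
  m1x <- cos(phi) * bx + sin(phi) * bz
  m1z <- -sin(phi) * bx + cos(phi) * bz
  hx <- m1x
  hy <- cos(theta) * by - sin(theta) * m1z
  heading <- unname(wrap_2pi(atan2(-hx, hy)))
  degen <- unname(abs(abs(theta) - pi / 2) < 2 * pi / 180)
  if (any(degen) && !all(degen)) {
    ok <- which(!degen)
    s <- approx(ok, sin(heading[ok]), xout = which(degen), rule = 2)$y
    c_ <- approx(ok, cos(heading[ok]), xout = which(degen), rule = 2)$y
    heading[degen] <- wrap_2pi(atan2(s, c_))
  }
  tibble::tibble(heading_rad = heading, degenerate = degen)
}

#' Circular variance of headings
#'
#' `V = 1 - ||mean unit vector||`, in `[0, 1]`: 0 for a fixed bearing
#' (straight or stationary travel), values near 1 for maximally dispersed
#' bearings (tortuous paths). Used as the per-phase tortuosity measure.
#'
#' @param headings Angles in radians (at least one).
#' @return The circular variance, a single number in `[0, 1]`.
#' @examples
#' circular_variance(c(0, pi / 2))
#' @export
circular_variance <- function(headings) {
  headings <- headings[is.finite(headings)]
  if (length(headings) == 0L) abort("`headings` must contain at least one angle")
  1 - sqrt(mean(cos(headings))^2 + mean(sin(headings))^2)
}

#' Dead-reckoned 3-D track from heading, pitch and VeDBA
#'
#' Reconstructs a swim path from an anchor point: per-second speed is
#' `speed_scale * max(vedba - speed_floor, 0)` (VeDBA as a locomotion-speed
#' proxy), horizontal steps are `speed * cos(pitch)` decomposed along the
#' heading, and depth is taken from the (corrected) depth sensor rather than
#' integrated.
#'
#' @param heading 1 Hz heading, radians clockwise from North.
#' @param pitch 1 Hz pitch, degrees.
#' @param vedba 1 Hz VeDBA, g.
#' @param depth 1 Hz depth, m.
#' @param anchor Length-2 origin `(easting, northing)` in metres.
#' @param speed_scale Speed per unit VeDBA above the floor, m/s per g.
#' @param speed_floor VeDBA level below which speed is 0, g.
#' @return A tibble `time_s`, `easting_m`, `northing_m`, `depth_m`; the
#'   first row sits at the anchor.
#' @export
dead_reckon_track <- function(heading, pitch, vedba, depth,
                              anchor = c(0, 0), speed_scale = 1.6,
                              speed_floor = 0.05) {
  n <- length(heading)
  if (length(pitch) != n || length(vedba) != n || length(depth) != n) {
    abort("all inputs must be aligned 1 Hz series of equal length")
  }
  speed <- speed_scale * pmax(vedba - speed_floor, 0)
  horiz <- speed * cos(pitch * pi / 180)
  de <- horiz * sin(heading)
  dn <- horiz * cos(heading)
  tibble::tibble(
    time_s = seq_len(n) - 1,
    easting_m = anchor[1] + cumsum(c(0, de[-n])),
    northing_m = anchor[2] + cumsum(c(0, dn[-n])),
    depth_m = depth
  )
}

#' Derive the 1 Hz kinematic series from a raw sensor table
#'
#' Runs the full pre-processing chain on one deployment: depth is resampled
#' to 1 Hz and zero-offset corrected; acceleration is split into static and
#' dynamic parts with the box smoother; ODBA/VeDBA, pitch (tag-offset
#' corrected) and tilt-compensated heading are computed at the native rate
#' and resampled to 1 Hz (headings by circular mean).
#'
#' @param sensors Tibble with columns `timestamp_s`, `ax_g`, `ay_g`, `az_g`,
#'   `mx`, `my`, `mz`, `depth_m` (and optionally `temp_c`), as written by
#'   [simulate_deployment()] or read from a tag CSV.
#' @param smooth_window_s Static/dynamic box-smoother window (s).
#' @param zoc_window_s,surface_quantile Zero-offset correction parameters.
#' @param pitch_offset Tag mounting pitch offset in degrees; `NULL` (the
#'   default) estimates it with [estimate_pitch_offset()].
#' @return A tibble `time_s`, `depth_m`, `odba_g`, `vedba_g`, `pitch_deg`,
#'   `heading_rad`, with the estimated `pitch_offset` as an attribute.
#' @export
compute_kinematics <- function(sensors, smooth_window_s = 4,
                               zoc_window_s = 3600, surface_quantile = 0.02,
                               pitch_offset = NULL) {
  need <- c("timestamp_s", "ax_g", "ay_g", "az_g", "mx", "my", "mz", "depth_m")
  if (!all(need %in% names(sensors))) {
    abort(paste("`sensors` must contain columns:", paste(need, collapse = ", ")))
  }
  ts <- sensors$timestamp_s
  rate <- round(1 / median(diff(ts)), 6)

  depth1 <- resample_uniform(ts, sensors$depth_m)
  depth1$value <- zero_offset_correct(depth1$value, window_s = zoc_window_s,
                                      surface_quantile = surface_quantile)

  dec <- split_acceleration(sensors[, c("ax_g", "ay_g", "az_g")],
                            window_s = smooth_window_s, sample_rate = rate)
  dba <- body_acceleration_metrics(dec$dynamic)
  odba1 <- resample_uniform(ts, dba$odba_g)
  vedba1 <- resample_uniform(ts, dba$vedba_g)

  pitch_raw <- pitch_from_acceleration(sensors$ax_g, sensors$ay_g,
                                       sensors$az_g)
  pitch1 <- resample_uniform(ts, pitch_raw)
  if (is.null(pitch_offset)) {
    pitch_offset <- estimate_pitch_offset(pitch1$value, depth1$value)
  }
  pitch1$value <- pmin(pmax(pitch1$value - pitch_offset, -90), 90)

  hd <- heading_from_sensors(dec$static, sensors[, c("mx", "my", "mz")])
  heading1 <- resample_uniform(ts, hd$heading_rad, circular = TRUE)

  out <- tibble::tibble(
    time_s = depth1$time, depth_m = depth1$value,
    odba_g = odba1$value, vedba_g = vedba1$value,
    pitch_deg = pitch1$value, heading_rad = heading1$value
  )
  attr(out, "pitch_offset") <- pitch_offset
  out
}
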