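#' Simulate one multi-sensor tag deployment with ground truth
#'
#' Generates a full sensor record for one deployment of the emulated study:
#' a 1 Hz depth trace with planted trapezoid/V dives separated by surface
#' intervals, tri-axial acceleration at `accel_rate` (gravity rotated through
#' the planted pitch plus a wingbeat sinusoid on the sway axis scaled so the
#' expected measured phase-mean ODBA equals the planted target, plus noise),
#' a tri-axial magnetometer consistent with the planted heading and pitch
#' (fixed geomagnetic field, 45 deg inclination, zero declination), and a
#' tide-gauge series. A constant pitch mounting offset and a constant depth
#' sensor offset are injected per deployment and recorded in the truth.
#'
#' Planted per-phase statistics in the returned ground truth are computed
#' from the noise-free truth series over the analytic phase windows (the
#' 1 m dive threshold and the 80% -of-max-depth bottom rule), so recovery by
#' the analysis pipeline can be scored exactly.
#'
#' @param config A [sim_config()] object.
#' @param deployment_index Which deployment to generate (1-based; must be
#'   `<= config$n_deployments`).
#' @param channels Render the sensor channels (default). `FALSE` skips the
#'   accelerometer/magnetometer/depth synthesis (returning `sensors = NULL`
#'   and planted-level ODBA truth), which is much faster when only the
#'   ground-truth dive table is needed.
#'
#' @return A list with elements:
#'   * `sensors`: tibble at `accel_rate` with `timestamp_s`, `ax_g`, `ay_g`,
#'     `az_g`, `mx`, `my`, `mz`, `depth_m`, `temp_c`,
#'   * `tide`: hourly tide tibble (`time_s`, `sea_level_m`),
#'   * `truth`: one row per planted dive (boundaries, archetype, planted
#'     per-phase ODBA/pitch/circular variance, max depth, covariates),
#'   * `truth_series`: noise-free 1 Hz truth (`time_s`, `depth_m`,
#'     `pitch_deg`, `heading_rad`, `odba_g`),
#'   * `deployment`: one-row metadata tibble (season, start hour, injected
#'     offsets).
#' @examples
#' dep <- simulate_deployment(sim_config(seed = 1, deployment_hours = 1), 1)
#' nrow(dep$truth)
#' @export
simulate_deployment <- function(config, deployment_index, channels = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (deployment_index < 1 || deployment_index > config$n_deployments) {
    abort(sprintf("`deployment_index` must be in 1..%d", config$n_deployments))
  }
  seed_i <- deployment_seeds(config)[deployment_index]
  set.seed(seed_i)

  season <- config$season_labels[deployment_index]
  hours <- config$deployment_hours
  n_sec <- as.integer(round(hours * 3600))
  start_hour <- runif(1, 0, 24)
  pitch_offset <- runif(1, -8, 8)
  depth_offset <- runif(1, 0.1, 0.5)
  tide <- simulate_tide(hours + 2, range_m = config$tide_range_m,
                        period_h = config$tide_period_h,
                        phase = runif(1, 0, 2 * pi))

  plan <- plan_dives(config, season, start_hour, tide, n_sec)
  tr <- build_truth_series(config, plan, n_sec)
  sensors <- NULL
  if (channels) {
    syn <- synthesize_sensors(config, tr, season, pitch_offset, depth_offset)
    sensors <- syn$sensors
    # planted ODBA is defined as the expected measured 1 Hz ODBA, computed
    # deterministically from the noise-free channels through the same box
    # decomposition (so smoother leak at phase transitions is part of truth)
    tr$series$odba_g <- syn$odba_expected
  }
  truth <- dive_ground_truth(config, plan, tr, season)

  deployment <- tibble::tibble(
    deployment = deployment_index, season = season,
    start_hour = start_hour, duration_h = hours,
    pitch_offset_deg = pitch_offset, depth_offset_m = depth_offset,
    accel_rate = config$accel_rate, depth_rate = config$depth_rate
  )
  truth$deployment <- deployment_index
  list(sensors = sensors, tide = tide, truth = truth,
       truth_series = tr$series, deployment = deployment)
}

#' Assemble the 16 dive variables directly from simulator ground truth
#'
#' Bypasses the sensor layer: converts the planted per-dive truth (phase
#' boundaries and per-phase statistics) into the same 16-variable table
#' that the measurement pipeline produces, for fast noise-free fixtures in
#' clustering and ordination experiments.
#'
#' @param truth Pooled ground-truth tibble (from [simulate_study()]`$truth`
#'   or a single deployment's `truth`).
#' @return A tibble with `deployment`, `season`, `midpoint_s` and the 16
#'   dive variables; rows without a following dive have `dur.pdsi = NA`.
#' @export
truth_dive_variables <- function(truth) {
  tibble::tibble(
    deployment = truth$deployment,
    dive = truth$dive,
    season = truth$season,
    midpoint_s = (truth$start_s + truth$end_s) / 2,
    dur.desc = (truth$t1_s - truth$start_s) / 60,
    dur.bott = (truth$t2_s - truth$t1_s) / 60,
    dur.asc = (truth$end_s - truth$t2_s) / 60,
    dur.pdsi = (truth$next_start_s - truth$end_s) / 60,
    bottdist = truth$bottdist_m,
    bottdep = truth$bottdep_m,
    maxdep = truth$maxdep_m,
    odba.desc = truth$odba.desc, odba.bott = truth$odba.bott,
    odba.asc = truth$odba.asc,
    angle.desc = truth$angle.desc, angle.bott = truth$angle.bott,
    angle.asc = truth$angle.asc,
    circ.var.desc = truth$circ.var.desc, circ.var.bott = truth$circ.var.bott,
    circ.var.asc = truth$circ.var.asc
  )
}

#' Simulate all deployments of a study
#'
#' @param config A [sim_config()] object.
#' @param channels Render sensor channels per deployment (see
#'   [simulate_deployment()]).
#' @return A list with `deployments` (list of [simulate_deployment()]
#'   outputs), `metadata` (one row per deployment) and `truth` (all planted
#'   dives, pooled).
#' @export
simulate_study <- function(config, channels = TRUE) {
  deps <- lapply(seq_len(config$n_deployments),
                 function(i) simulate_deployment(config, i, channels = channels))
  list(deployments = deps,
       metadata = dplyr::bind_rows(lapply(deps, `[[`, "deployment")),
       truth = dplyr::bind_rows(lapply(deps, `[[`, "truth")))
}

# ---- internal generator stages -------------------------------------------

# Draw the sequence of dives for one deployment: archetypes, planted feature
# values (with covariate effects evaluated at the projected dive midpoint)
# and integer-second segment boundaries.
plan_dives <- function(config, season, start_hour, tide, n_sec) {
  arch <- config$archetypes
  amp <- config$effect_amplitudes
  vsp <- config$vertical_speed_mps
  w <- as.numeric(season == "winter")
  mix <- config$archetype_mix[arch$archetype]
  exp_dur <- sum(mix * (2 * arch$maxdep_m / vsp + arch$bottom_dur_s))
  pdsi_mean <- max(30, 3600 / config$dive_rate_per_h - exp_dur)

  dives <- list()
  cursor <- round_pos(stats::rgamma(1, shape = 3, scale = 20))
  while (TRUE) {
    a <- arch[sample.int(nrow(arch), 1, prob = mix), ]
    t_mid0 <- cursor + (a$maxdep_m / vsp + a$bottom_dur_s / 2)
    hr <- (start_hour + t_mid0 / 3600) %% 24
    hs <- diel_shape(hr)
    th <- tide_height_at(tide, min(t_mid0, max(tide$time_s)))
    td <- tide_diff_at(tide, min(t_mid0, max(tide$time_s)))
    th_anom <- th - mean(tide$sea_level_m)

    maxdep <- max(1.5, a$maxdep_m + amp$season_depth * w +
                    amp$diel_depth * hs + amp$tide_depth * th_anom)
    bott_dur <- max(60, round(a$bottom_dur_s + amp$season_duration_s * w +
                                amp$diel_duration_s * hs))
    # vertical speeds vary dive-to-dive (and descent independently of
    # ascent), as in real animals
    desc_dur <- max(4, round(maxdep / (vsp * runif(1, 0.85, 1.15))))
    asc_dur <- max(4, round(maxdep / (vsp * runif(1, 0.85, 1.15))))
    odba <- c(a$odba_desc, a$odba_bott, a$odba_asc) *
      exp(amp$diel_activity * hs + amp$tide_activity * td)
    wander <- pmax(0, c(a$wander_desc, a$wander_bott, a$wander_asc) +
                     amp$diel_tortuosity * pmax(-hs, 0))
    total <- desc_dur + bott_dur + asc_dur
    if (cursor + total + 40 > n_sec) break
    dives[[length(dives) + 1L]] <- tibble::tibble(
      archetype = a$archetype, t0 = cursor,
      desc_dur = desc_dur, bott_dur = bott_dur, asc_dur = asc_dur,
      maxdep = maxdep, undulation = a$undulation_m,
      odba_desc = odba[1], odba_bott = odba[2], odba_asc = odba[3],
      pitch_desc = a$pitch_desc, pitch_bott = a$pitch_bott,
      pitch_asc = a$pitch_asc,
      wander_desc = wander[1], wander_bott = wander[2],
      wander_asc = wander[3],
      hour = hr, tide_height = th, tide_diff = td
    )
    pdsi <- max(20, round(stats::rgamma(1, shape = 4, scale = pdsi_mean / 4)))
    cursor <- cursor + total + pdsi
  }
  dplyr::bind_rows(dives)
}

round_pos <- function(x) max(1, round(x))

# Build the 1 Hz noise-free truth series from the dive plan.
build_truth_series <- function(config, plan, n_sec) {
  tt <- seq_len(n_sec) - 1L
  depth <- numeric(n_sec)
  pitch <- numeric(n_sec)
  odba <- rep(0.02, n_sec)       # quiet surface paddling
  wander <- rep(0.5, n_sec)      # headings wander freely at the surface
  for (i in seq_len(nrow(plan))) {
    d <- plan[i, ]
    k_desc_end <- d$t0 + d$desc_dur
    k_bott_end <- k_desc_end + d$bott_dur
    k_end <- k_bott_end + d$asc_dur
    i_desc <- (d$t0 + 1):k_desc_end
    i_bott <- (k_desc_end + 1):k_bott_end
    i_asc <- (k_bott_end + 1):k_end
    depth[i_desc + 1L] <- d$maxdep * seq_along(i_desc) / d$desc_dur
    und <- if (d$undulation > 0) {
      d$undulation * (1 - cos(2 * pi * seq_along(i_bott) / 30)) / 2
    } else 0
    depth[i_bott + 1L] <- d$maxdep - und
    depth[i_bott[length(i_bott)] + 1L] <- d$maxdep  # end knot at max depth
    depth[i_asc + 1L] <- d$maxdep * rev(seq_along(i_asc) - 1) / d$asc_dur
    pitch[i_desc + 1L] <- d$pitch_desc
    pitch[i_bott + 1L] <- d$pitch_bott
    pitch[i_asc + 1L] <- d$pitch_asc
    odba[i_desc + 1L] <- d$odba_desc
    odba[i_bott + 1L] <- d$odba_bott
    odba[i_asc + 1L] <- d$odba_asc
    wander[i_desc + 1L] <- d$wander_desc
    wander[i_bott + 1L] <- d$wander_bott
    wander[i_asc + 1L] <- d$wander_asc
  }
  # Linear ramps (~7 s) at pitch transitions: piecewise-linear attitude keeps
  # the boxcar decomposition leak negligible inside phases.
  pitch_sm <- rolling_mean_shrink(pitch, 3L)
  heading <- wrap_2pi(runif(1, 0, 2 * pi) + cumsum(rnorm(n_sec, 0, wander)))
  list(series = tibble::tibble(time_s = as.numeric(tt), depth_m = depth,
                               pitch_deg = pitch_sm, heading_rad = heading,
                               odba_g = odba),
       plan = plan)
}

# Per-dive ground truth: analytic phase windows on the sample grid plus
# planted phase statistics computed from the truth series.
dive_ground_truth <- function(config, plan, tr, season) {
  s <- tr$series
  if (nrow(plan) == 0L) {
    return(tibble::tibble(dive = integer(), archetype = character(),
                          start_s = numeric(), next_start_s = numeric(),
                          season = character()))
  }
  out <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    d <- plan[i, ]
    k_end <- d$t0 + d$desc_dur + d$bott_dur + d$asc_dur
    idx <- (d$t0 + 1L):(k_end + 1L)     # row indices of the dive span
    dep <- s$depth_m[idx]
    above <- which(dep >= 1)
    start_s <- s$time_s[idx[above[1]]]
    end_s <- s$time_s[idx[above[length(above)]]]
    bott <- which(dep >= 0.8 * d$maxdep)
    t1_s <- s$time_s[idx[bott[1]]]
    t2_s <- s$time_s[idx[bott[length(bott)]]]
    win <- function(a, b, incl_b = FALSE) {
      sel <- s$time_s >= a & (if (incl_b) s$time_s <= b else s$time_s < b)
      which(sel)
    }
    i_desc <- win(start_s, t1_s)
    i_bott <- win(t1_s, t2_s, incl_b = TRUE)
    i_asc <- which(s$time_s > t2_s & s$time_s <= end_s)
    out[[i]] <- tibble::tibble(
      dive = i, archetype = d$archetype,
      start_s = start_s, t1_s = t1_s, t2_s = t2_s, end_s = end_s,
      desc_end_s = d$t0 + d$desc_dur, asc_start_s = d$t0 + d$desc_dur + d$bott_dur,
      maxdep_m = d$maxdep,
      odba.desc = mean(s$odba_g[i_desc]), odba.bott = mean(s$odba_g[i_bott]),
      odba.asc = mean(s$odba_g[i_asc]),
      angle.desc = mean(s$pitch_deg[i_desc]), angle.bott = mean(s$pitch_deg[i_bott]),
      angle.asc = mean(s$pitch_deg[i_asc]),
      circ.var.desc = circular_variance(s$heading_rad[i_desc]),
      circ.var.bott = circular_variance(s$heading_rad[i_bott]),
      circ.var.asc = circular_variance(s$heading_rad[i_asc]),
      bottdep_m = mean(s$depth_m[i_bott]),
      bottdist_m = sum(abs(diff(s$depth_m[i_bott]))),
      hour = d$hour, tide_height = d$tide_height, tide_diff = d$tide_diff,
      season = season
    )
  }
  truth <- dplyr::bind_rows(out)
  truth$next_start_s <- c(truth$start_s[-1], NA_real_)
  truth
}

# Render the accelerometer/magnetometer/depth/temperature channels.
synthesize_sensors <- function(config, tr, season, pitch_offset, depth_offset) {
  s <- tr$series
  fa <- config$accel_rate
  fd <- config$depth_rate
  ns <- config$noise_sd
  n_sec <- nrow(s)
  t_a <- seq(0, n_sec * fa - 1) / fa

  pitch_a <- approx(s$time_s, s$pitch_deg, xout = t_a, rule = 2)$y + pitch_offset
  hx <- approx(s$time_s, cos(s$heading_rad), xout = t_a, rule = 2)$y
  hy <- approx(s$time_s, sin(s$heading_rad), xout = t_a, rule = 2)$y
  head_a <- atan2(hy, hx)

  # Wingbeat amplitude calibrated so the expected measured 1 Hz ODBA (after
  # the default 4 s decomposition, including noise folding on all three
  # axes) equals the planted target.
  n_win <- 2L * floor(2 * fa) + 1L
  gain <- abs(1 - boxcar_gain(config$wingbeat_hz, fa, n_win))
  sigma_d <- ns$accel * sqrt(1 - 1 / n_win)
  amp_1hz <- calibrate_wingbeat(s$odba_g, sigma_d) / gain
  amp_a <- approx(s$time_s, amp_1hz, xout = t_a, rule = 2)$y
  dyn_sway <- amp_a * sin(2 * pi * config$wingbeat_hz * t_a + runif(1, 0, 2 * pi))

  th <- pitch_a * pi / 180
  ax <- sin(th) + rnorm(length(t_a), 0, ns$accel)
  ay <- dyn_sway + rnorm(length(t_a), 0, ns$accel)
  az <- cos(th) + rnorm(length(t_a), 0, ns$accel)

  incl <- 45 * pi / 180
  ch <- cos(incl); sv <- sin(incl)
  mx <- ch * cos(head_a) * cos(th) - sv * sin(th) + rnorm(length(t_a), 0, ns$mag)
  my <- -ch * sin(head_a) + rnorm(length(t_a), 0, ns$mag)
  mz <- -ch * cos(head_a) * sin(th) - sv * cos(th) + rnorm(length(t_a), 0, ns$mag)

  t_d <- seq(0, n_sec * fd - 1) / fd
  depth_d <- approx(s$time_s, s$depth_m, xout = t_d, rule = 2)$y +
    depth_offset + rnorm(length(t_d), 0, ns$depth)
  temp_mean <- if (season == "winter") 22.1 else 31.9
  temp_d <- temp_mean + rnorm(length(t_d), 0, ns$temp)
  hold <- floor(t_a * fd) + 1L

  sensors <- tibble::tibble(timestamp_s = t_a, ax_g = ax, ay_g = ay,
                            az_g = az, mx = mx, my = my, mz = mz,
                            depth_m = depth_d[hold], temp_c = temp_d[hold])
  odba_expected <- expected_odba_1hz(
    cbind(sin(th), dyn_sway, cos(th)), fa, n_win, sigma_d)
  list(sensors = sensors, odba_expected = odba_expected)
}

# Expected measured 1 Hz ODBA of noise-free channels: pass each channel
# through the same shrinking boxcar decomposition, fold in the Gaussian
# noise analytically (E|d + eps|), sum over axes and bin-average to 1 Hz.
expected_odba_1hz <- function(channels, fa, n_win, sigma_d) {
  halfwidth <- (n_win - 1L) %/% 2L
  e_total <- 0
  for (j in seq_len(ncol(channels))) {
    d <- channels[, j] - rolling_mean_shrink(channels[, j], halfwidth)
    e <- if (sigma_d > 0) {
      sigma_d * sqrt(2 / pi) * exp(-d^2 / (2 * sigma_d^2)) +
        d * (2 * pnorm(d / sigma_d) - 1)
    } else abs(d)
    e_total <- e_total + e
  }
  colMeans(matrix(e_total, nrow = fa))
}

# Solve E|A sin(phi) + eps| + cross-axis noise floor = target for A, per
# unique target (cached); targets at or below the pure-noise floor get A = 0.
calibrate_wingbeat <- function(target, sigma_d) {
  floor_noise <- 2 * sigma_d * sqrt(2 / pi)
  uq <- unique(round(target, 7))
  amp_uq <- vapply(uq, function(m) {
    residual <- m - floor_noise
    base <- expected_abs_sine_noise(0, sigma_d)
    if (residual <= base) return(0)
    uniroot(function(a) expected_abs_sine_noise(a, sigma_d) - residual,
            lower = 0, upper = (residual + 5 * sigma_d) * pi / 2 + 1e-6,
            tol = 1e-10)$root
  }, numeric(1))
  amp_uq[match(round(target, 7), uq)]
}
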