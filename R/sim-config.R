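#' Configure the multi-sensor deployment simulator
#'
#' Builds the configuration for [simulate_deployment()] and
#' [simulate_study()]. Defaults describe the emulated study system: a
#' macro-tidal bay with ~10 m semidiurnal tides, tag deployments spanning
#' both Austral seasons, trapezoid/V dives separated by surface intervals,
#' wingbeat-modulated dynamic acceleration, and phase-dependent pitch and
#' heading structure. Dive features (depth, duration, activity, tortuosity)
#' respond to hour-of-day, tide and season through planted additive effect
#' functions, so downstream recovery is testable against known truth.
#'
#' @param seed Integer master seed. Every deployment draws its own substream
#'   seed from this, so deployment `i` is reproducible independently of the
#'   others.
#' @param n_deployments Number of tagged-animal deployments.
#' @param deployment_hours Record length per deployment, hours.
#' @param accel_rate Accelerometer/magnetometer sampling rate, Hz (20-50 on
#'   the emulated tags).
#' @param depth_rate Depth/temperature sampling rate, Hz (>= 1); must divide
#'   `accel_rate`.
#' @param season_labels Character vector, one of `"summer"`/`"winter"` per
#'   deployment; recycled to `n_deployments`.
#' @param tide_range_m,tide_period_h Tidal range (m) and period (h) passed to
#'   [simulate_tide()]; each deployment gets a random tide phase.
#' @param dive_rate_per_h Target dive rate; surface-interval durations are
#'   drawn so the expected dive cycle matches it.
#' @param archetype_mix Named proportions over the two planted dive
#'   archetypes (`active`: short, high-activity; `resting`: long, quiet).
#'   Must sum to 1.
#' @param effect_amplitudes Named list of planted effect amplitudes tying
#'   dive features to covariates evaluated at the dive midpoint:
#'   `diel_depth` (m), `diel_duration_s` (s), `diel_tortuosity`
#'   (heading-wander rad/s), `season_depth` (m, winter deeper),
#'   `season_duration_s` (s, winter longer), `tide_depth` (m per m of
#'   tide-height anomaly). Activity effects are multiplicative on the
#'   planted ODBA levels (so quiet phases never drop below the sensor noise
#'   floor): `diel_activity` (log-scale amplitude) and `tide_activity`
#'   (log-scale per m/h of tide rate). Setting all to 0 makes dive features
#'   exchangeable across hour/tide strata.
#' @param noise_sd Named list of per-channel Gaussian noise SDs:
#'   `accel` (g), `mag` (field units), `depth` (m), `temp` (degC).
#' @param wingbeat_hz Flipper-beat frequency of the planted dynamic
#'   acceleration, Hz.
#' @param vertical_speed_mps Descent/ascent vertical speed, m/s.
#' @param archetypes Data frame of per-archetype planted parameters; see
#'   `default_archetypes()` for the columns. Override to create degenerate
#'   or exaggerated scenarios (e.g. well-separated clusters).
#'
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(seed = 1, n_deployments = 2, deployment_hours = 2)
#' @export
sim_config <- function(seed = 1L,
                       n_deployments = 24L,
                       deployment_hours = 6,
                       accel_rate = 20,
                       depth_rate = 1,
                       season_labels = rep(c("summer", "winter"),
                                           length.out = n_deployments),
                       tide_range_m = 10,
                       tide_period_h = 12.42,
                       dive_rate_per_h = 7,
                       archetype_mix = c(active = 0.6, resting = 0.4),
                       effect_amplitudes = list(),
                       noise_sd = list(),
                       wingbeat_hz = 0.4,
                       vertical_speed_mps = 0.25,
                       archetypes = default_archetypes()) {
  amp <- utils::modifyList(default_effect_amplitudes(), effect_amplitudes)
  ns <- utils::modifyList(list(accel = 0.002, mag = 0.003, depth = 0.005,
                               temp = 0.1), noise_sd)
  if (accel_rate <= 0 || depth_rate <= 0 || dive_rate_per_h <= 0 ||
      tide_period_h <= 0 || wingbeat_hz <= 0 || vertical_speed_mps <= 0) {
    abort("all rates and speeds must be positive")
  }
  if (depth_rate > accel_rate || accel_rate %% depth_rate != 0) {
    abort("`depth_rate` must divide `accel_rate`")
  }
  if (abs(sum(archetype_mix) - 1) > 1e-9) {
    abort("`archetype_mix` must sum to 1")
  }
  if (!all(names(archetype_mix) %in% archetypes$archetype)) {
    abort("`archetype_mix` names must match `archetypes$archetype`")
  }
  if (deployment_hours * dive_rate_per_h < 1) {
    abort("expected dive count (deployment_hours * dive_rate_per_h) must be >= 1")
  }
  season_labels <- rep(season_labels, length.out = n_deployments)
  if (!all(season_labels %in% c("summer", "winter"))) {
    abort("`season_labels` must be 'summer' or 'winter'")
  }
  structure(list(
    seed = as.integer(seed), n_deployments = as.integer(n_deployments),
    deployment_hours = deployment_hours, accel_rate = accel_rate,
    depth_rate = depth_rate, season_labels = season_labels,
    tide_range_m = tide_range_m, tide_period_h = tide_period_h,
    dive_rate_per_h = dive_rate_per_h, archetype_mix = archetype_mix,
    effect_amplitudes = amp, noise_sd = ns, wingbeat_hz = wingbeat_hz,
    vertical_speed_mps = vertical_speed_mps,
    archetypes = tibble::as_tibble(archetypes)
  ), class = "sim_config")
}

#' Default planted dive archetypes
#'
#' Two archetypes: a short, high-activity "active" dive (travel/forage-like)
#' and a long, quiet "resting" dive with a tortuous bottom phase. Columns:
#' per-archetype base maximum depth (m), bottom duration (s), per-phase mean
#' ODBA targets (g), per-phase pitch (deg, head-up positive), per-phase
#' heading wander SD (rad/s) and bottom depth undulation (m).
#'
#' @return A tibble with one row per archetype.
#' @export
default_archetypes <- function() {
  tibble::tibble(
    archetype = c("active", "resting"),
    maxdep_m = c(6, 10),
    bottom_dur_s = c(150, 420),
    odba_desc = c(0.20, 0.08),
    odba_bott = c(0.25, 0.05),
    odba_asc = c(0.22, 0.10),
    pitch_desc = c(-40, -30),
    pitch_bott = c(0, 0),
    pitch_asc = c(45, 35),
    wander_desc = c(0.05, 0.05),
    wander_bott = c(0.30, 0.60),
    wander_asc = c(0.10, 0.08),
    undulation_m = c(0.2, 0)
  )
}

#' Default planted effect amplitudes
#'
#' The named list of effect amplitudes used by [sim_config()] when no
#' overrides are supplied; see that help page for units and meaning.
#' Setting every entry to 0 removes all covariate structure from the
#' planted dives.
#'
#' @return A named list of amplitudes.
#' @export
default_effect_amplitudes <- function() {
  list(diel_depth = 2, diel_activity = 0.3, diel_duration_s = 60,
       diel_tortuosity = 0.15, season_depth = 3, season_duration_s = 120,
       tide_depth = 0.4, tide_activity = 0.08)
}

# Diel effect shape shared by all planted diel effects: peaks at 14:00.
diel_shape <- function(hour) cos(2 * pi * (hour - 14) / 24)

# Per-deployment substream seeds drawn once from the master seed, so each
# deployment is reproducible in isolation.
deployment_seeds <- function(config) {
  set.seed(config$seed)
  sample.int(.Machine$integer.max - 1L, config$n_deployments)
}
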