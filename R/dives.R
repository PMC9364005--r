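#' Detect dives in a corrected 1 Hz depth record
#'
#' A dive is a maximal run of consecutive samples at or below the surface
#' threshold: depth `>= min_depth_m` (default 1 m, separating diving from
#' surface behaviour) lasting more than `min_dur_s` (default 30 s). Runs
#' interrupted by any sub-threshold sample are separate candidates and are
#' never merged. Each dive's post-dive surface interval (PDSI) runs from its
#' end to the start of the next dive; the last dive has no PDSI.
#'
#' @param kin Tibble with `time_s` and zero-offset-corrected `depth_m` at
#'   1 Hz (e.g. from [compute_kinematics()]).
#' @param min_depth_m Depth threshold (m).
#' @param min_dur_s Minimum dive duration (s); a run qualifies when it spans
#'   more than this many samples at 1 Hz.
#' @return A tibble with one row per dive: `dive`, `start_s`, `end_s`,
#'   `duration_s`, `max_depth_m`, `midpoint_s`, `next_start_s`,
#'   `pdsi_s` (NA for the last dive).
#' @export
detect_dives <- function(kin, min_depth_m = 1, min_dur_s = 30) {
  depth <- kin$depth_m
  time_s <- kin$time_s
  under <- !is.na(depth) & depth >= min_depth_m
  if (length(under) == 0L || !any(under)) return(empty_dive_tbl())
  r <- rle(under)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths > min_dur_s)
  if (length(keep) == 0L) return(empty_dive_tbl())
  out <- tibble::tibble(
    dive = seq_along(keep),
    start_s = time_s[starts[keep]],
    end_s = time_s[ends[keep]],
    max_depth_m = vapply(keep, function(j) {
      max(depth[starts[j]:ends[j]])
    }, numeric(1))
  )
  out$duration_s <- out$end_s - out$start_s + 1
  out$midpoint_s <- (out$start_s + out$end_s) / 2
  out$next_start_s <- c(out$start_s[-1], NA_real_)
  out$pdsi_s <- out$next_start_s - out$end_s
  out
}

empty_dive_tbl <- function() {
  tibble::tibble(dive = integer(), start_s = numeric(), end_s = numeric(),
                 max_depth_m = numeric(), duration_s = numeric(),
                 midpoint_s = numeric(), next_start_s = numeric(),
                 pdsi_s = numeric())
}

#' Segment dives into descent, bottom and ascent phases
#'
#' The bottom phase is delimited by the first and last times the dive
#' reaches `bottom_fraction` of its maximum depth (default 0.80): descent is
#' `[start, t1)`, bottom `[t1, t2]`, ascent `(t2, end]`. A V-shaped dive
#' with no flat section collapses to a 1-sample bottom at the deepest
#' sample. Every dive always carries all three phases.
#'
#' @param dives Output of [detect_dives()].
#' @param kin The 1 Hz kinematic tibble the dives were detected in.
#' @param bottom_fraction Fraction of maximum dive depth delimiting the
#'   bottom phase, in (0, 1].
#' @return `dives` with added `t1_s` and `t2_s` phase boundary columns.
#' @export
segment_phases <- function(dives, kin, bottom_fraction = 0.8) {
  if (bottom_fraction <= 0 || bottom_fraction > 1) {
    abort("`bottom_fraction` must be in (0, 1]")
  }
  bounds <- purrr::map(seq_len(nrow(dives)), function(i) {
    sel <- kin$time_s >= dives$start_s[i] & kin$time_s <= dives$end_s[i]
    tt <- kin$time_s[sel]
    dd <- kin$depth_m[sel]
    thr <- bottom_fraction * max(dd)
    at <- which(dd >= thr - 1e-12)
    c(t1 = tt[at[1]], t2 = tt[at[length(at)]])
  })
  dives$t1_s <- purrr::map_dbl(bounds, "t1")
  dives$t2_s <- purrr::map_dbl(bounds, "t2")
  dives
}

#' Compute the 16 per-dive descriptive variables
#'
#' For each segmented dive: phase and PDSI durations (minutes); bottom-phase
#' depth statistics (`bottdist` = summed absolute depth change, `bottdep` =
#' mean bottom depth, `maxdep` = maximum bottom depth, metres); per-phase
#' mean ODBA (g); per-phase mean pitch (degrees); and per-phase circular
#' variance of heading (tortuosity V). Phase membership: descent
#' `[start, t1)`, bottom `[t1, t2]`, ascent `(t2, end]`.
#'
#' @param dives Output of [segment_phases()].
#' @param kin The matching 1 Hz kinematic tibble (`depth_m`, `odba_g`,
#'   `pitch_deg`, `heading_rad`).
#' @return `dives` with the 16 variable columns appended (`dur.desc` ...
#'   `circ.var.asc`). `dur.pdsi` is `NA` for the last dive of a record.
#' @export
compute_dive_variables <- function(dives, kin) {
  vars <- purrr::map(seq_len(nrow(dives)), function(i) {
    d <- dives[i, ]
    i_desc <- which(kin$time_s >= d$start_s & kin$time_s < d$t1_s)
    i_bott <- which(kin$time_s >= d$t1_s & kin$time_s <= d$t2_s)
    i_asc <- which(kin$time_s > d$t2_s & kin$time_s <= d$end_s)
    if (length(i_desc) == 0L) i_desc <- i_bott[1]
    if (length(i_asc) == 0L) i_asc <- i_bott[length(i_bott)]
    bdep <- kin$depth_m[i_bott]
    tibble::tibble(
      dur.desc = (d$t1_s - d$start_s) / 60,
      dur.bott = (d$t2_s - d$t1_s) / 60,
      dur.asc = (d$end_s - d$t2_s) / 60,
      dur.pdsi = d$pdsi_s / 60,
      bottdist = sum(abs(diff(bdep))),
      bottdep = mean(bdep),
      maxdep = max(bdep),
      odba.desc = mean(kin$odba_g[i_desc], na.rm = TRUE),
      odba.bott = mean(kin$odba_g[i_bott], na.rm = TRUE),
      odba.asc = mean(kin$odba_g[i_asc], na.rm = TRUE),
      angle.desc = mean(kin$pitch_deg[i_desc], na.rm = TRUE),
      angle.bott = mean(kin$pitch_deg[i_bott], na.rm = TRUE),
      angle.asc = mean(kin$pitch_deg[i_asc], na.rm = TRUE),
      circ.var.desc = circular_variance(kin$heading_rad[i_desc]),
      circ.var.bott = circular_variance(kin$heading_rad[i_bott]),
      circ.var.asc = circular_variance(kin$heading_rad[i_asc])
    )
  })
  dplyr::bind_cols(dives, dplyr::bind_rows(vars))
}

#' Pool dive variables across deployments into a feature matrix
#'
#' Combines per-deployment dive-variable tables, drops dives with an
#' undefined post-dive surface interval (the last dive of each deployment)
#' and optionally standardizes the 16 variables over the pooled matrix
#' (per-column mean 0, SD 1) - pooled, not per individual, so deployments
#' remain comparable.
#'
#' @param dive_vars A tibble (or list of tibbles) of dive variables with a
#'   `deployment` column, as produced by [compute_dive_variables()].
#' @param standardize Standardize the pooled matrix (default `TRUE`).
#' @return A tibble of metadata columns plus the 16 variables; when
#'   standardized, the column centres and scales are stored in attributes
#'   `center` and `scale` (see [destandardize_features()]).
#' @export
assemble_feature_matrix <- function(dive_vars, standardize = TRUE) {
  if (is.list(dive_vars) && !is.data.frame(dive_vars)) {
    dive_vars <- dplyr::bind_rows(dive_vars)
  }
  vars <- dive_variable_names()
  missing_cols <- setdiff(vars, names(dive_vars))
  if (length(missing_cols) > 0L) {
    abort(paste("missing dive-variable columns:",
                paste(missing_cols, collapse = ", ")))
  }
  out <- dplyr::filter(dive_vars, !is.na(.data$dur.pdsi))
  if (nrow(out) < 2L) abort("need at least 2 dives with a defined PDSI")
  if (standardize) {
    m <- as.matrix(out[, vars])
    ctr <- colMeans(m)
    scl <- apply(m, 2, sd)
    if (any(scl == 0)) {
      abort(paste("cannot standardize zero-variance column(s):",
                  paste(vars[scl == 0], collapse = ", ")))
    }
    out[, vars] <- sweep(sweep(m, 2, ctr), 2, scl, "/")
    attr(out, "center") <- ctr
    attr(out, "scale") <- scl
  }
  attr(out, "standardized") <- standardize
  out
}

#' Undo feature-matrix standardization
#'
#' @param features A standardized feature matrix from
#'   [assemble_feature_matrix()].
#' @return The tibble with the 16 variables back on their raw scales.
#' @export
destandardize_features <- function(features) {
  ctr <- attr(features, "center")
  scl <- attr(features, "scale")
  if (is.null(ctr)) abort("`features` carries no standardization attributes")
  vars <- dive_variable_names()
  m <- as.matrix(features[, vars])
  features[, vars] <- sweep(sweep(m, 2, scl, "*"), 2, ctr, "+")
  attr(features, "center") <- NULL
  attr(features, "scale") <- NULL
  attr(features, "standardized") <- FALSE
  features
}

#' Per-deployment dive summary
#'
#' Deployment-level summary in the style of a field-study dive table: number
#' of dives, dive frequency per day, and mean +/- SD and maximum of dive
#' depth, dive duration and PDSI duration, plus pooled per-season and
#' overall rows.
#'
#' @param dives Dive-variable tibble with `deployment`, `season`, `maxdep`
#'   (m), `duration_s` and `pdsi_s` columns.
#' @param metadata Tibble with `deployment` and `duration_h` giving each
#'   deployment's record length (used for dives/day); alternatively a
#'   single number of days applied to all.
#' @return A tibble with one row per deployment plus `season:` and
#'   `overall` rows (`level` column distinguishes them). Single-dive
#'   deployments report `sd = 0` and are flagged by `n_flag`.
#' @export
summarize_deployment <- function(dives, metadata) {
  if (is.numeric(metadata)) {
    metadata <- tibble::tibble(deployment = unique(dives$deployment),
                               duration_h = metadata * 24)
  }
  if (any(metadata$duration_h <= 0)) abort("deployment duration must be positive")
  if (nrow(dives) == 0L) abort("need at least one dive")
  sd0 <- function(x) if (sum(is.finite(x)) < 2) 0 else sd(x, na.rm = TRUE)
  stats_row <- function(d, days) {
    tibble::tibble(
      n_dives = nrow(d),
      dives_per_day = nrow(d) / days,
      mean_depth_m = mean(d$maxdep), sd_depth_m = sd0(d$maxdep),
      max_depth_m = max(d$maxdep),
      mean_duration_min = mean(d$duration_s) / 60,
      sd_duration_min = sd0(d$duration_s) / 60,
      max_duration_min = max(d$duration_s) / 60,
      mean_pdsi_min = mean(d$pdsi_s, na.rm = TRUE) / 60,
      sd_pdsi_min = sd0(d$pdsi_s) / 60,
      max_pdsi_min = if (all(is.na(d$pdsi_s))) NA_real_
                     else max(d$pdsi_s, na.rm = TRUE) / 60,
      n_flag = nrow(d) == 1L
    )
  }
  per_dep <- dives |>
    dplyr::group_by(.data$deployment, .data$season) |>
    dplyr::group_modify(function(d, g) {
      days <- metadata$duration_h[metadata$deployment == g$deployment] / 24
      stats_row(d, days)
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(level = "deployment")
  pool <- function(d, label) {
    days <- sum(metadata$duration_h[metadata$deployment %in% d$deployment]) / 24
    dplyr::mutate(stats_row(d, days), level = label)
  }
  seas <- dives |>
    dplyr::group_by(.data$season) |>
    dplyr::group_modify(function(d, g) {
      dd <- dives[dives$season == g$season, ]
      pool(dd, "season")
    }) |>
    dplyr::ungroup()
  dplyr::bind_rows(per_dep, seas, pool(dives, "overall"))
}
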