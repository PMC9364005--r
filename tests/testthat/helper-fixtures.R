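# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

cached_fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# One fully rendered 2 h deployment plus its measured kinematics and dives.
small_deployment <- function() {
  cached_fixture("small_dep", {
    cfg <- sim_config(seed = 101, n_deployments = 2, deployment_hours = 2)
    dep <- simulate_deployment(cfg, 1)
    kin <- compute_kinematics(dep$sensors)
    dives <- detect_dives(kin) |>
      segment_phases(kin) |>
      compute_dive_variables(kin)
    list(cfg = cfg, dep = dep, kin = kin, dives = dives)
  })
}

# Fast ground-truth-only study (no sensor rendering) for feature-level work.
truth_feature_study <- function(seed = 7, n_deployments = 8, hours = 4, ...) {
  cfg <- sim_config(seed = seed, n_deployments = n_deployments,
                    deployment_hours = hours, ...)
  study <- simulate_study(cfg, channels = FALSE)
  list(cfg = cfg, study = study,
       vars = truth_dive_variables(study$truth))
}

# Medium pooled feature matrix used by PCA and clustering tests.
medium_features <- function() {
  cached_fixture("medium_features", {
    ts <- truth_feature_study(seed = 7, n_deployments = 10, hours = 5)
    assemble_feature_matrix(ts$vars)
  })
}

# Exaggerated two-archetype parameters: well-separated planted clusters.
# Tortuosity and undulation are kept equal so within-cluster scatter stays
# small relative to the planted contrasts.
separated_archetypes <- function() {
  arch <- default_archetypes()
  arch$maxdep_m <- c(3, 30)
  arch$bottom_dur_s <- c(60, 600)
  arch$odba_desc <- c(0.45, 0.05)
  arch$odba_bott <- c(0.5, 0.03)
  arch$odba_asc <- c(0.45, 0.05)
  arch$pitch_desc <- c(-60, -15)
  arch$pitch_asc <- c(60, 15)
  arch$wander_bott <- c(0.3, 0.3)
  arch$undulation_m <- c(0.1, 0.1)
  arch
}

# Overlapping archetypes: the defaults pulled halfway towards their common
# mean, emulating a continuum of dive styles with no discrete types.
overlapping_archetypes <- function() {
  arch <- default_archetypes()
  for (cn in setdiff(names(arch), "archetype")) {
    mid <- mean(arch[[cn]])
    arch[[cn]] <- mid + 0.5 * (arch[[cn]] - mid)
  }
  arch
}

overlapping_features <- function() {
  cached_fixture("overlapping_features", {
    ts <- truth_feature_study(seed = 19, n_deployments = 10, hours = 5,
                              archetype_mix = c(active = 0.5, resting = 0.5),
                              archetypes = overlapping_archetypes())
    assemble_feature_matrix(ts$vars)
  })
}

# The study-scale rendered fixture behind the segmentation-recovery
# acceptance checks: 24 deployments x 6 h at 20 Hz, processed through the
# measurement pipeline and joined to ground truth.
acceptance_fixture <- function() {
  cached_fixture("acceptance_fixture", {
    cfg <- sim_config(seed = 20240601)
    per_dep <- lapply(seq_len(cfg$n_deployments), function(i) {
      dep <- simulate_deployment(cfg, i)
      kin <- compute_kinematics(dep$sensors)
      dives <- detect_dives(kin)
      dives <- segment_phases(dives, kin)
      dives <- compute_dive_variables(dives, kin)
      dives$deployment <- i
      dives$season <- dep$deployment$season
      list(dives = dives, truth = dep$truth, tide = dep$tide,
           metadata = dep$deployment)
    })
    list(cfg = cfg,
         dives = dplyr::bind_rows(lapply(per_dep, `[[`, "dives")),
         truth = dplyr::bind_rows(lapply(per_dep, `[[`, "truth")),
         metadata = dplyr::bind_rows(lapply(per_dep, `[[`, "metadata")))
  })
}
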