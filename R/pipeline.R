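#' Configure an end-to-end pipeline run
#'
#' Collects every stage parameter with defaults matching the analysis as a
#' whole: 1 m / 30 s dive definition, 4 s acceleration smoother, 1 h
#' zero-offset window, 0.80 bottom fraction, k = 1..10 cluster scan,
#' eigenvalue > 1 retention, +/-0.4 loading cutoff, 1000 bootstrap
#' replicates. Unknown keys are rejected.
#'
#' @param sim A [sim_config()] describing the deployments to simulate.
#' @param ... Stage parameter overrides; see the defaults in the function
#'   definition (`zoc_window_s`, `surface_quantile`, `smooth_window_s`,
#'   `min_depth_m`, `min_dur_s`, `bottom_fraction`, `k_max`, `restarts`,
#'   `linkage`, `retention_threshold`, `loading_cutoff`, `bootstrap_B`,
#'   `ci`, `k_hour`, `k_tide`, `seed`).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), ...) {
  defaults <- list(
    zoc_window_s = 3600, surface_quantile = 0.02, smooth_window_s = 4,
    min_depth_m = 1, min_dur_s = 30, bottom_fraction = 0.8,
    k_max = 10, restarts = 25, linkage = "complete",
    retention_threshold = 1, loading_cutoff = 0.4,
    bootstrap_B = 1000, ci = 0.95, k_hour = 8, k_tide = 5,
    seed = sim$seed
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0L) {
    abort(paste("unknown pipeline config keys:", paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, overrides)
  cfg$sim <- sim
  structure(cfg, class = "pipeline_config")
}

#' Run the full dive-analysis pipeline
#'
#' Chains all stages on simulated deployments: sensor simulation,
#' kinematic pre-processing, dive detection and phase segmentation, the 16
#' dive variables and deployment summaries, the pooled standardized feature
#' matrix, cluster scans (both methods), correlation-matrix PCA with
#' retention/orientation/bootstrap, and AICc-selected environmental models
#' for each retained component. All tabular outputs are written as CSV (and
#' selected summaries as JSON) under `out_dir`, together with the resolved
#' configuration and a run manifest (file list, row counts, stage timings,
#' seed, package version). Identical config and seed give identical
#' outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing); `NULL` skips all
#'   file output.
#' @return A list with the in-memory stage results (`features`, `dives`,
#'   `summary`, `scan`, `pca`, `loading_ci`, `models`, `truth`, `manifest`),
#'   invisibly writable via `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  t_all <- list()
  tick <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    t_all[[name]] <<- proc.time()[["elapsed"]] - t0
    val
  }

  study <- tick("simulate", simulate_study(config$sim))
  dives_all <- list()
  kin_all <- list()
  for (i in seq_along(study$deployments)) {
    dep <- study$deployments[[i]]
    kin <- compute_kinematics(dep$sensors,
                              smooth_window_s = config$smooth_window_s,
                              zoc_window_s = config$zoc_window_s,
                              surface_quantile = config$surface_quantile)
    dv <- detect_dives(kin, config$min_depth_m, config$min_dur_s)
    if (nrow(dv) > 0L) {
      dv <- segment_phases(dv, kin, config$bottom_fraction)
      dv <- compute_dive_variables(dv, kin)
      dv$deployment <- dep$deployment$deployment
      dv$season <- dep$deployment$season
      dives_all[[length(dives_all) + 1L]] <- dv
    }
    kin_all[[i]] <- kin
  }
  t_all[["kinematics_dives"]] <- NA_real_
  dives <- dplyr::bind_rows(dives_all)
  summary_tbl <- summarize_deployment(dives, study$metadata)
  features <- tick("features", assemble_feature_matrix(dives))

  scan <- tick("cluster", {
    km <- cluster_scan(features, "kmeans", k_max = config$k_max,
                       seed = config$seed, restarts = config$restarts)
    hc <- cluster_scan(features, "hierarchical", k_max = config$k_max,
                       seed = config$seed, linkage = config$linkage)
    structure(list(scan = dplyr::bind_rows(km$scan, hc$scan),
                   labels = dplyr::bind_rows(km$labels, hc$labels),
                   k_max = config$k_max, seed = config$seed,
                   restarts = config$restarts, linkage = config$linkage,
                   n = km$n),
              class = "cluster_scan")
  })

  pca <- tick("pca", {
    p <- fit_pca(features)
    postprocess_components(p, config$retention_threshold,
                           config$loading_cutoff)
  })
  loading_ci <- tick("bootstrap",
                     bootstrap_loadings(features, B = config$bootstrap_B,
                                        seed = config$seed, ci = config$ci))

  tide_all <- dplyr::bind_rows(lapply(study$deployments, function(d) {
    dplyr::mutate(d$tide, deployment = d$deployment$deployment)
  }))
  # covariates for the modelled rows only (the feature matrix drops each
  # deployment's last dive, which has no PDSI)
  covs <- build_covariates(features, tide_all, study$metadata)
  models <- tick("models", {
    lapply(pca$retained, function(j) {
      tr <- maybe_transform_scores(pca$scores[, j])
      sel <- select_model(covs, tr$scores, k_hour = config$k_hour,
                          k_tide = config$k_tide, transform = tr$record)
      sel
    })
  })
  names(models) <- paste0("PC", pca$retained)

  result <- list(features = features, dives = dives, summary = summary_tbl,
                 scan = scan, pca = pca, loading_ci = loading_ci,
                 models = models, truth = study$truth,
                 metadata = study$metadata, covariates = covs)
  result$manifest <- write_pipeline_outputs(result, config, out_dir, t_all)
  result
}

# Write stage outputs + manifest; returns the manifest list.
write_pipeline_outputs <- function(result, config, out_dir, timings) {
  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, name) {
      path <- file.path(out_dir, name)
      utils::write.csv(df, path, row.names = FALSE)
      files <<- c(files, name)
    }
    wr(result$dives, "dives.csv")
    wr(result$summary, "summary.csv")
    wr(result$scan$scan, "cluster_scan.csv")
    wr(result$scan$labels, "cluster_labels.csv")
    wr(tidy(result$pca, "eigenvalues"), "pca_eigenvalues.csv")
    wr(tidy(result$pca, "loadings"), "pca_loadings.csv")
    wr(tidy(result$pca, "scores"), "pca_scores.csv")
    wr(result$loading_ci$ci, "pca_bootstrap_ci.csv")
    wr(result$covariates, "covariates.csv")
    for (nm in names(result$models)) {
      wr(result$models[[nm]]$ranking, sprintf("model_ranking_%s.csv", nm))
      eff <- predict_effects(result$models[[nm]]$winner)
      if (nrow(eff) > 0L) wr(eff, sprintf("model_effects_%s.csv", nm))
    }
    model_summary <- lapply(result$models, function(m) {
      as.list(glance(m$winner))
    })
    jsonlite::write_json(model_summary,
                         file.path(out_dir, "model_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    files <- c(files, "model_summary.json")
    cfg_out <- unclass(config)
    cfg_out$sim <- unclass(cfg_out$sim)
    cfg_out$sim$archetypes <- NULL
    jsonlite::write_json(cfg_out, file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
    files <- c(files, "config.json")
  }
  manifest <- list(
    files = files,
    rows = list(dives = nrow(result$dives),
                features = nrow(result$features),
                deployments = nrow(result$metadata),
                retained_components = length(result$pca$retained)),
    timings_s = timings[!is.na(unlist(timings))],
    seed = config$seed,
    package_version = as.character(utils::packageVersion("divekin"))
  )
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  manifest
}
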