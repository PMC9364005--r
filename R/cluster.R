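#' Scan cluster counts with elbow and silhouette diagnostics
#'
#' Evaluates candidate dive-type structure in the standardized feature
#' matrix over `k = 1..k_max`, for k-means (Lloyd's algorithm, best
#' within-cluster sum of squares over `restarts` seeded starts) and/or
#' agglomerative hierarchical clustering (Euclidean distance, tree cut at
#' each `k`). For every `k >= 2` the mean silhouette width (Euclidean) is
#' recorded; `k = 1` has no silhouette. Together the within-cluster
#' sum-of-squares ("elbow") profile and the silhouette profile diagnose
#' whether distinct dive types exist at all.
#'
#' @param features Standardized feature matrix from
#'   [assemble_feature_matrix()], or any data frame containing the 16 dive
#'   variables (non-variable columns are ignored).
#' @param method `"kmeans"`, `"hierarchical"`, or both (default).
#' @param k_max Largest cluster count scanned; must be below the number of
#'   dives.
#' @param seed Integer seed for the k-means restarts.
#' @param restarts Number of random k-means starts per `k`.
#' @param linkage Hierarchical agglomeration rule (passed to
#'   [stats::hclust()]; default `"complete"`).
#' @return An object of class `cluster_scan`: list with `scan` (tibble
#'   `method`, `k`, `wss`, `mean_silhouette`), `labels` (tibble of per-dive
#'   labels for each method and `k`), and the call parameters.
#' @export
cluster_scan <- function(features, method = c("kmeans", "hierarchical"),
                         k_max = 10, seed = 1, restarts = 25,
                         linkage = "complete") {
  method <- match.arg(method, several.ok = TRUE)
  x <- feature_columns(features)
  n <- nrow(x)
  if (k_max >= n) abort("`k_max` must be smaller than the number of dives")
  if (k_max < 1) abort("`k_max` must be at least 1")
  d_euc <- dist(x)
  rows <- list(); labs <- list()
  for (m in method) {
    if (m == "hierarchical") tree <- hclust(d_euc, method = linkage)
    for (k in seq_len(k_max)) {
      if (m == "kmeans") {
        if (k == 1L) {
          lab <- rep(1L, n)
          wss <- sum(scale(x, scale = FALSE)^2)
        } else {
          set.seed(seed + k)
          # Lloyd restarts occasionally hit an empty cluster and retry;
          # that warning is noise given `restarts` seeded starts
          km <- suppressWarnings(
            kmeans(x, centers = k, nstart = restarts,
                   algorithm = "Lloyd", iter.max = 200))
          lab <- km$cluster
          wss <- km$tot.withinss
        }
      } else {
        lab <- if (k == 1L) rep(1L, n) else cutree(tree, k = k)
        wss <- sum(vapply(split(seq_len(n), lab), function(idx) {
          sum(scale(x[idx, , drop = FALSE], scale = FALSE)^2)
        }, numeric(1)))
      }
      sil <- if (k >= 2L && length(unique(lab)) >= 2L) {
        mean(cluster::silhouette(lab, d_euc)[, "sil_width"])
      } else NA_real_
      rows[[length(rows) + 1L]] <- tibble::tibble(
        method = m, k = k, wss = wss, mean_silhouette = sil)
      labs[[length(labs) + 1L]] <- tibble::tibble(
        method = m, k = k, dive = seq_len(n), cluster = as.integer(lab))
    }
  }
  structure(list(scan = dplyr::bind_rows(rows),
                 labels = dplyr::bind_rows(labs),
                 k_max = k_max, seed = seed, restarts = restarts,
                 linkage = linkage, n = n),
            class = "cluster_scan")
}

# Pull the 16 dive-variable columns as a numeric matrix.
feature_columns <- function(features) {
  vars <- dive_variable_names()
  if (all(vars %in% names(features))) {
    as.matrix(features[, vars])
  } else {
    m <- as.matrix(dplyr::select(tibble::as_tibble(features),
                                 dplyr::where(is.numeric)))
    if (ncol(m) == 0L) abort("no numeric feature columns found")
    m
  }
}

#' @export
#' @method tidy cluster_scan
tidy.cluster_scan <- function(x, ...) x$scan

#' @export
#' @method glance cluster_scan
glance.cluster_scan <- function(x, ...) {
  best <- x$scan |>
    dplyr::filter(!is.na(.data$mean_silhouette)) |>
    dplyr::group_by(.data$method) |>
    dplyr::slice_max(.data$mean_silhouette, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  tibble::tibble(
    method = best$method, best_k = best$k,
    best_silhouette = best$mean_silhouette, n = x$n
  )
}

#' @export
#' @method print cluster_scan
print.cluster_scan <- function(x, ...) {
  cat("Cluster scan over k = 1..", x$k_max, " (", x$n, " dives)\n", sep = "")
  print(x$scan, n = Inf)
  invisible(x)
}

#' Elbow and silhouette plot for a cluster scan
#'
#' @param object A [cluster_scan()] result.
#' @param ... Unused.
#' @return A ggplot with within-cluster sum of squares and mean silhouette
#'   width against `k`, one panel row per diagnostic.
#' @export
#' @method autoplot cluster_scan
autoplot.cluster_scan <- function(object, ...) {
  long <- object$scan |>
    tidyr::pivot_longer(c("wss", "mean_silhouette"),
                        names_to = "diagnostic", values_to = "value") |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::mutate(diagnostic = dplyr::recode(.data$diagnostic,
      wss = "within-cluster SS", mean_silhouette = "mean silhouette"))
  ggplot2::ggplot(long, ggplot2::aes(.data$k, .data$value,
                                     colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~diagnostic, scales = "free_y", ncol = 1) +
    ggplot2::scale_x_continuous(breaks = seq_len(object$k_max)) +
    ggplot2::labs(x = "number of clusters k", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
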