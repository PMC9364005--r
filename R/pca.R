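#' Correlation-matrix PCA of the dive feature matrix
#'
#' Spectral decomposition of the 16 x 16 correlation matrix of the dive
#' variables. Because the input is standardized, the eigenvalues sum to the
#' number of variables and each component's "unscaled eigenvalue" is its
#' variance; scores are the standardized data projected on the
#' eigenvectors. Components are ordered by decreasing eigenvalue (ties kept
#' in first-occurrence order) and each loading vector is canonicalized so
#' its largest-magnitude entry is positive, making results deterministic
#' across numerical libraries.
#'
#' @param features Feature matrix from [assemble_feature_matrix()] (or any
#'   data frame containing the 16 dive variables); columns are
#'   (re-)standardized internally, so raw or standardized input give the
#'   same result.
#' @return An object of class `dive_pca`: eigenvalues, loadings
#'   (variables x components, orthonormal columns), scores
#'   (dives x components), proportion of variance, and the metadata columns
#'   of `features`. Components beyond the matrix rank get eigenvalue 0 (with
#'   a warning).
#' @export
fit_pca <- function(features) {
  x <- feature_columns(features)
  p <- ncol(x)
  if (nrow(x) < p + 1L) {
    abort(sprintf("need at least %d dives for a %d-variable PCA", p + 1L, p))
  }
  scl <- apply(x, 2, sd)
  if (any(scl == 0)) {
    abort(paste("zero-variance column(s):",
                paste(colnames(x)[scl == 0], collapse = ", ")))
  }
  xs <- scale(x)
  eig <- eigen(cor(x), symmetric = TRUE)
  vals <- eig$values
  if (any(vals < -1e-8)) warn("negative eigenvalues truncated to 0")
  rank_tol <- max(vals) * 1e-10
  if (any(vals < rank_tol)) {
    warn("feature matrix is rank deficient; trailing eigenvalues set to 0")
  }
  vals <- pmax(vals, 0)
  vecs <- eig$vectors
  # canonical orientation: strongest-|loading| entry positive, per component
  flips <- vapply(seq_len(p), function(j) {
    s <- sign(vecs[which.max(abs(vecs[, j])), j])
    if (s == 0) 1 else s
  }, numeric(1))
  vecs <- sweep(vecs, 2, flips, "*")
  dimnames(vecs) <- list(colnames(x), paste0("PC", seq_len(p)))
  scores <- xs %*% vecs
  meta <- dplyr::select(tibble::as_tibble(features),
                        -dplyr::any_of(dive_variable_names()))
  structure(list(
    eigenvalues = vals, loadings = vecs, scores = scores,
    prop_var = vals / sum(vals), variables = colnames(x),
    n = nrow(x), meta = meta, retained = integer(0),
    orientation = rep(1, p), interpretation = NULL
  ), class = "dive_pca")
}

#' Retain, orient and interpret principal components
#'
#' Applies the latent-root criterion (keep components whose eigenvalue
#' exceeds `retention_threshold`, default 1 for a correlation-matrix PCA),
#' then orients each retained component: if its strongest-magnitude loading
#' is negative, all loadings of that component are multiplied by -1 and its
#' scores recalculated. Variables with `|loading| >= loading_cutoff`
#' (default 0.4) form the component's interpretation table.
#'
#' @param pca A [fit_pca()] result.
#' @param retention_threshold Eigenvalue cutoff for retention.
#' @param loading_cutoff Magnitude above which a variable is deemed to
#'   contribute to a component.
#' @return The `dive_pca` object with `retained`, `orientation` and an
#'   `interpretation` tibble (`component`, `variable`, `loading`, `sign`)
#'   filled in.
#' @export
postprocess_components <- function(pca, retention_threshold = 1,
                                   loading_cutoff = 0.4) {
  stopifnot(inherits(pca, "dive_pca"))
  retained <- which(pca$eigenvalues > retention_threshold)
  if (length(retained) == 0L) {
    abort("no component exceeds the retention threshold; review the threshold")
  }
  for (j in retained) {
    strongest <- which.max(abs(pca$loadings[, j]))
    if (pca$loadings[strongest, j] < 0) {
      pca$loadings[, j] <- -pca$loadings[, j]
      pca$scores[, j] <- -pca$scores[, j]
      pca$orientation[j] <- -pca$orientation[j]
    }
  }
  interp <- purrr::map_dfr(retained, function(j) {
    l <- pca$loadings[, j]
    sel <- abs(l) >= loading_cutoff
    tibble::tibble(component = paste0("PC", j),
                   variable = names(l)[sel],
                   loading = unname(l[sel]),
                   sign = c("-", "+")[(l[sel] >= 0) + 1L])
  })
  pca$retained <- retained
  pca$interpretation <- interp
  pca$retention_threshold <- retention_threshold
  pca$loading_cutoff <- loading_cutoff
  pca
}

#' Bootstrap stability of PCA loadings
#'
#' Resamples dives (rows) with replacement `B` times; each resample is
#' re-standardized and refit, replicate components are matched to the
#' original components by maximal absolute cosine similarity of their
#' loading vectors (greedy, eigenvalue order, without replacement), and the
#' absolute loadings are accumulated. Working with absolute loadings
#' sidesteps the residual sign ambiguity of eigenvectors. Resamples that
#' produce a zero-variance column are redrawn (at most 10 attempts each).
#'
#' @param features Feature matrix (as for [fit_pca()]).
#' @param B Number of bootstrap replicates (>= 100 for usable intervals).
#' @param seed Integer seed.
#' @param ci Central interval mass for the percentile bounds (default 0.95).
#' @return An object of class `loading_ci`: tibble `ci` with per
#'   component x variable the original `|loading|`, bootstrap mean and
#'   percentile interval, plus `B`, `seed` and the redraw count.
#' @export
bootstrap_loadings <- function(features, B = 1000, seed = 1, ci = 0.95) {
  if (B < 1) abort("`B` must be at least 1")
  x <- feature_columns(features)
  n <- nrow(x)
  p <- ncol(x)
  orig <- fit_pca(features)
  set.seed(seed)
  acc <- array(NA_real_, dim = c(B, p, p),
               dimnames = list(NULL, colnames(orig$loadings), orig$variables))
  redraws <- 0L
  for (b in seq_len(B)) {
    for (attempt in seq_len(11L)) {
      idx <- sample.int(n, n, replace = TRUE)
      xb <- x[idx, , drop = FALSE]
      if (all(apply(xb, 2, sd) > 0)) break
      redraws <- redraws + 1L
      if (attempt == 11L) abort("resample kept producing zero-variance columns")
    }
    eb <- eigen(cor(xb), symmetric = TRUE)
    match_j <- match_components(orig$loadings, eb$vectors)
    acc[b, , ] <- t(abs(eb$vectors[, match_j, drop = FALSE]))
  }
  alpha <- (1 - ci) / 2
  grid <- expand.grid(component = colnames(orig$loadings),
                      variable = orig$variables, stringsAsFactors = FALSE)
  ci_tbl <- tibble::as_tibble(grid) |>
    dplyr::mutate(
      loading = abs(orig$loadings)[cbind(.data$variable, .data$component)],
      boot_mean = purrr::map2_dbl(.data$component, .data$variable,
                                  ~ mean(acc[, .x, .y])),
      lower = purrr::map2_dbl(.data$component, .data$variable,
                              ~ quantile(acc[, .x, .y], alpha, names = FALSE)),
      upper = purrr::map2_dbl(.data$component, .data$variable,
                              ~ quantile(acc[, .x, .y], 1 - alpha,
                                         names = FALSE))
    ) |>
    dplyr::arrange(match(.data$component, colnames(orig$loadings)),
                   match(.data$variable, orig$variables))
  structure(list(ci = ci_tbl, B = as.integer(B), seed = seed,
                 level = ci, redraws = redraws),
            class = "loading_ci")
}

# Greedy matching of replicate components to original components by
# absolute cosine similarity, in original eigenvalue order.
match_components <- function(ref, rep_vecs) {
  p <- ncol(ref)
  sim <- abs(crossprod(ref, rep_vecs))   # columns orthonormal -> |cosine|
  taken <- rep(FALSE, p)
  out <- integer(p)
  for (j in seq_len(p)) {
    cand <- which(!taken)
    out[j] <- cand[which.max(sim[j, cand])]
    taken[out[j]] <- TRUE
  }
  out
}

#' @export
#' @method tidy loading_ci
tidy.loading_ci <- function(x, ...) x$ci

#' @export
#' @method tidy dive_pca
tidy.dive_pca <- function(x, matrix = c("loadings", "eigenvalues", "scores"),
                          ...) {
  matrix <- match.arg(matrix)
  switch(matrix,
    eigenvalues = tibble::tibble(
      component = colnames(x$loadings),
      eigenvalue = x$eigenvalues,
      prop_var = x$prop_var,
      cum_var = cumsum(x$prop_var),
      retained = seq_along(x$eigenvalues) %in% x$retained
    ),
    loadings = tibble::as_tibble(x$loadings, rownames = "variable") |>
      tidyr::pivot_longer(-"variable", names_to = "component",
                          values_to = "loading"),
    scores = dplyr::bind_cols(
      x$meta, tibble::as_tibble(x$scores, .name_repair = "minimal"))
  )
}

#' @export
#' @method glance dive_pca
glance.dive_pca <- function(x, ...) {
  tibble::tibble(
    n = x$n, p = length(x$variables),
    n_retained = length(x$retained),
    retained_var = sum(x$prop_var[x$retained])
  )
}

#' @export
#' @method print dive_pca
print.dive_pca <- function(x, ...) {
  cat("Correlation-matrix PCA of", length(x$variables), "dive variables,",
      x$n, "dives\n")
  ev <- tidy(x, "eigenvalues")
  print(ev, n = Inf)
  if (length(x$retained) > 0L) {
    cat("Retained:", paste0("PC", x$retained, collapse = ", "),
        sprintf("(%.1f%% of variance)\n", 100 * sum(x$prop_var[x$retained])))
  }
  invisible(x)
}

#' Scree plot of a dive PCA
#'
#' @param object A [fit_pca()] result.
#' @param ... Unused.
#' @return A ggplot of eigenvalues against component rank with the
#'   latent-root threshold line.
#' @export
#' @method autoplot dive_pca
autoplot.dive_pca <- function(object, ...) {
  ev <- tidy(object, "eigenvalues") |>
    dplyr::mutate(rank = dplyr::row_number())
  ggplot2::ggplot(ev, ggplot2::aes(.data$rank, .data$eigenvalue)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$retained)) +
    ggplot2::geom_hline(yintercept = object$retention_threshold %||% 1,
                        linetype = 2) +
    ggplot2::labs(x = "component", y = "eigenvalue", colour = "retained") +
    ggplot2::theme_minimal()
}
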