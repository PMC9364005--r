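#' Build per-dive environmental covariates
#'
#' For each dive, evaluated at its midpoint time: local decimal hour of day,
#' tide height (linear interpolation of the hourly gauge series), tide
#' strength and direction (forward difference of the hourly series, m/h,
#' negative on ebb and positive on flood, interpolated to the midpoint),
#' season and animal identity from the deployment metadata.
#'
#' @param dives Tibble with `deployment` and `midpoint_s` columns (e.g.
#'   from [detect_dives()] / [compute_dive_variables()]).
#' @param tide Hourly tide tibble (`time_s`, `sea_level_m`), optionally with
#'   a `deployment` column when each deployment has its own gauge record.
#' @param metadata Deployment metadata with `deployment`, `season` and
#'   `start_hour` (decimal hour of day at `time_s = 0`).
#' @return A tibble with `turtle_id` (factor), `season` (factor
#'   summer/winter), `dive`, `midpoint_s`, `hour`, `tide_height`,
#'   `tide_diff`. Errors if any dive midpoint falls outside tide coverage.
#' @export
build_covariates <- function(dives, tide, metadata) {
  if (!all(c("deployment", "midpoint_s") %in% names(dives))) {
    abort("`dives` needs `deployment` and `midpoint_s` columns")
  }
  has_dep_tide <- "deployment" %in% names(tide)
  out <- dives |>
    dplyr::group_by(.data$deployment) |>
    dplyr::group_modify(function(d, g) {
      md <- metadata[metadata$deployment == g$deployment, ]
      if (nrow(md) != 1L) {
        abort(sprintf("metadata missing for deployment %s", g$deployment))
      }
      td <- if (has_dep_tide) tide[tide$deployment == g$deployment, ] else tide
      tibble::tibble(
        dive = d$dive %||% seq_len(nrow(d)),
        midpoint_s = d$midpoint_s,
        season = md$season,
        hour = (md$start_hour + d$midpoint_s / 3600) %% 24,
        tide_height = tide_height_at(td, d$midpoint_s),
        tide_diff = tide_diff_at(td, d$midpoint_s)
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::rename(turtle_id = "deployment")
  out$turtle_id <- factor(out$turtle_id)
  out$season <- factor(out$season, levels = c("summer", "winter"))
  out
}

#' Conditionally log-transform component scores
#'
#' Component scores are used as Gaussian responses; strongly skewed score
#' distributions are shifted-log transformed first:
#' `log(x - min(x) + 1)` when `|sample skewness| > 1`, identity otherwise.
#' Constant series have skewness 0 and pass through unchanged.
#'
#' @param scores Numeric score vector (finite).
#' @return A list with `scores` (possibly transformed) and `record`, a
#'   one-row tibble (`applied`, `shift`, `skew_before`, `skew_after`).
#' @export
maybe_transform_scores <- function(scores) {
  if (any(!is.finite(scores))) abort("`scores` must be finite")
  sk <- sample_skewness(scores)
  if (abs(sk) > 1) {
    shift <- -min(scores) + 1
    out <- log(scores + shift)
    record <- tibble::tibble(applied = TRUE, shift = shift,
                             skew_before = sk,
                             skew_after = sample_skewness(out))
  } else {
    out <- scores
    record <- tibble::tibble(applied = FALSE, shift = 0,
                             skew_before = sk, skew_after = sk)
  }
  list(scores = out, record = record)
}

#' Describe an additive-model term set
#'
#' The candidate grammar for the environmental models: each of the three
#' continuous covariates can be absent, enter as a single smooth, or enter
#' as separate by-season smooths; season can enter as a parametric main
#' effect (forced on whenever a by-season smooth is present, since
#' by-smooths are centred); every model carries a per-animal random
#' intercept.
#'
#' @param hour,tide_height,tide_diff One of `"none"`, `"plain"`,
#'   `"by_season"`.
#' @param season Include the parametric season effect.
#' @return A list of class `term_set`.
#' @export
term_set <- function(hour = "none", tide_height = "none", tide_diff = "none",
                     season = FALSE) {
  states <- c("none", "plain", "by_season")
  hour <- match.arg(hour, states)
  tide_height <- match.arg(tide_height, states)
  tide_diff <- match.arg(tide_diff, states)
  if (any(c(hour, tide_height, tide_diff) == "by_season")) season <- TRUE
  structure(list(hour = hour, tide_height = tide_height,
                 tide_diff = tide_diff, season = season),
            class = "term_set")
}

term_set_label <- function(ts) {
  parts <- character(0)
  smooths <- c(hour = ts$hour, tide_height = ts$tide_height,
               tide_diff = ts$tide_diff)
  for (v in names(smooths)) {
    if (smooths[[v]] == "plain") parts <- c(parts, sprintf("s(%s)", v))
    if (smooths[[v]] == "by_season") {
      parts <- c(parts, sprintf("s(%s x season)", v))
    }
  }
  if (ts$season) parts <- c(parts, "season")
  if (length(parts) == 0L) "null" else paste(parts, collapse = " + ")
}

term_set_size <- function(ts) {
  sum(c(ts$hour, ts$tide_height, ts$tide_diff) != "none") + as.integer(ts$season)
}

# All 35 candidates of the grammar (null included; season main effect is
# optional only when no by-season smooth is present).
candidate_term_sets <- function() {
  states <- c("none", "plain", "by_season")
  out <- list()
  for (h in states) for (th in states) for (td in states) {
    any_by <- any(c(h, th, td) == "by_season")
    for (s in if (any_by) TRUE else c(FALSE, TRUE)) {
      out[[length(out) + 1L]] <- term_set(h, th, td, s)
    }
  }
  out
}

build_gam_formula <- function(ts, k_hour, k_tide) {
  rhs <- character(0)
  smooth <- function(var, state, bs, k) {
    if (state == "none") return(character(0))
    if (state == "plain") {
      sprintf("s(%s, bs = '%s', k = %d)", var, bs, k)
    } else {
      sprintf("s(%s, bs = '%s', k = %d, by = season)", var, bs, k)
    }
  }
  rhs <- c(rhs, smooth("hour", ts$hour, "cc", k_hour),
           smooth("tide_height", ts$tide_height, "cr", k_tide),
           smooth("tide_diff", ts$tide_diff, "cr", k_tide))
  if (ts$season) rhs <- c(rhs, "season")
  rhs <- c(rhs, "s(turtle_id, bs = 're')")
  as.formula(paste(".response ~", paste(rhs, collapse = " + ")))
}

#' Fit one penalized additive model of dive-feature scores
#'
#' Gaussian identity-link additive model of a component score against
#' environmental covariates: hour of day through a cyclic cubic spline
#' (endpoints tied at 0/24 h), tide height and tide rate through cubic
#' regression splines, season as a parametric factor, "x season"
#' interactions as separate by-season smooths, and a ridge-penalized random
#' intercept per animal against pseudo-replication. Smoothing parameters
#' are estimated by fast REML. When `rho` is supplied the model is
#' re-expressed on AR(1)-whitened data within each animal's dive sequence
#' (feasible GLS), mirroring a post-hoc first-order autoregressive residual
#' term.
#'
#' @param covariates Tibble from [build_covariates()] (needs `turtle_id`,
#'   `season`, `hour`, `tide_height`, `tide_diff`, and a time order column
#'   `midpoint_s` or `time_s`).
#' @param response Numeric response aligned with `covariates` rows
#'   (typically a retained component's scores, possibly transformed).
#' @param terms A [term_set()].
#' @param rho AR(1) coefficient for residual whitening; `NULL` or 0 fits an
#'   independent-residual model.
#' @param k_hour,k_tide Spline basis dimensions (defaults 8 and 5).
#' @param gamma Inflation of the effective-degrees-of-freedom cost during
#'   smoothing-parameter estimation (default 1.4, the usual guard against
#'   smoothing-selection overfit; 1 disables it).
#' @param transform Optional transform record (from
#'   [maybe_transform_scores()]) carried along for reporting.
#' @return An object of class `dive_gamm` with the fitted `mgcv` model,
#'   AICc, effective degrees of freedom, AR(1) coefficient and deviance
#'   explained by the full model and by the fixed effects alone (%).
#' @export
fit_additive_model <- function(covariates, response, terms = term_set(),
                               rho = NULL, k_hour = 8, k_tide = 5,
                               gamma = 1.4, transform = NULL) {
  if (!inherits(terms, "term_set")) abort("`terms` must be a term_set()")
  if (length(response) != nrow(covariates)) {
    abort("`response` must align with `covariates` rows")
  }
  if (any(!is.finite(response))) abort("`response` must be finite")
  rho <- rho %||% 0
  dat <- tibble::as_tibble(covariates)
  dat$.response <- response
  ord_col <- intersect(c("midpoint_s", "time_s"), names(dat))[1]
  if (is.na(ord_col)) abort("`covariates` needs a `midpoint_s` or `time_s` column")
  dat <- dplyr::arrange(dat, .data$turtle_id, .data[[ord_col]])
  dat$turtle_id <- droplevels(factor(dat$turtle_id))
  dat$season <- factor(dat$season, levels = c("summer", "winter"))
  dat$.ar_start <- !duplicated(dat$turtle_id)

  f <- build_gam_formula(terms, k_hour, k_tide)
  fit <- mgcv::bam(f, data = dat, method = "fREML", rho = rho,
                   AR.start = .ar_start, knots = list(hour = c(0, 24)),
                   gamma = gamma)
  n <- nrow(dat)
  edf <- sum(fit$edf)
  ll <- as.numeric(logLik(fit))
  aicc <- aicc_from(ll, edf, n)
  y <- dat$.response
  pred_fixed <- predict(fit, newdata = dat, exclude = "s(turtle_id)")
  de_fixed <- max(0, 100 * (1 - sum((y - pred_fixed)^2) / sum((y - mean(y))^2)))
  de_full <- max(0, 100 * summary(fit)$dev.expl)
  structure(list(
    fit = fit, data = dat, terms = terms, rho = rho,
    n = n, edf = edf, loglik = ll, aicc = aicc,
    de_full = de_full, de_fixed = de_fixed,
    n_variables = term_set_size(terms),
    label = term_set_label(terms),
    k_hour = k_hour, k_tide = k_tide,
    transform = transform
  ), class = "dive_gamm")
}

# Small-sample corrected AIC; p is the total effective degrees of freedom.
aicc_from <- function(ll, p, n) {
  -2 * ll + 2 * p + 2 * p * (p + 1) / (n - p - 1)
}

#' Estimate the lag-1 residual autocorrelation within animals
#'
#' Pools the lag-1 autocorrelation of each animal's residual sequence (in
#' dive order), weighting by sequence length. Animals with fewer than three
#' dives contribute nothing; if none qualify the estimate is 0 with a
#' warning. For a whitened fit (`rho > 0`) the standardized residuals are
#' used, so the estimate checks what correlation remains after whitening.
#'
#' @param fit A `dive_gamm`, or a numeric residual vector (then `group`
#'   must give the animal of each residual, in sequence order).
#' @param group Grouping factor when `fit` is a plain vector.
#' @return The pooled lag-1 autocorrelation estimate (a single number).
#' @export
estimate_ar1 <- function(fit, group = NULL) {
  if (inherits(fit, "dive_gamm")) {
    res <- if (fit$rho != 0 && !is.null(fit$fit$std.rsd)) fit$fit$std.rsd
           else residuals(fit$fit)
    group <- fit$data$turtle_id
  } else {
    res <- fit
    if (is.null(group)) abort("`group` is required for a residual vector")
  }
  pieces <- split(res, group)
  r <- w <- numeric(0)
  for (e in pieces) {
    ne <- length(e)
    if (ne < 3L) next
    e <- e - mean(e)
    denom <- sum(e^2)
    if (denom == 0) next
    r <- c(r, sum(e[-1] * e[-ne]) / denom)
    w <- c(w, ne - 1)
  }
  if (length(r) == 0L) {
    warn("no animal has 3+ dives; returning rho = 0")
    return(0)
  }
  sum(r * w) / sum(w)
}

#' Select the most parsimonious environmental model by AICc
#'
#' Fits every candidate of the term grammar (all subsets of the hour /
#' tide-height / tide-rate smooths, each optionally by season, an optional
#' parametric season effect, and the null model; every candidate carries
#' the per-animal random intercept). Each candidate is fitted twice: an
#' initial independent-residual fit, then a refit whitened with that fit's
#' estimated lag-1 residual autocorrelation (two-stage AR(1)). Candidates
#' are ranked by AICc; among models within two AICc units of the minimum
#' the one with the fewest variables wins.
#'
#' @inheritParams fit_additive_model
#' @param candidates List of [term_set()]s; defaults to the full grammar.
#'   Evaluation order does not affect the result.
#' @return An object of class `gamm_selection`: `ranking` tibble (label,
#'   edf, AICc, delta, rho, variables), the winning `dive_gamm` in
#'   `$winner`, and the selection parameters.
#' @export
select_model <- function(covariates, response, k_hour = 8, k_tide = 5,
                         gamma = 1.4, candidates = candidate_term_sets(),
                         transform = NULL) {
  rows <- list()
  fits <- list()
  for (i in seq_along(candidates)) {
    ts <- candidates[[i]]
    fit0 <- tryCatch(
      fit_additive_model(covariates, response, ts, rho = 0,
                         k_hour = k_hour, k_tide = k_tide, gamma = gamma),
      error = function(e) NULL)
    if (is.null(fit0) || fit0$n - fit0$edf - 1 <= 0) {
      warn(sprintf("candidate '%s' skipped (too few dives for its size)",
                   term_set_label(ts)))
      next
    }
    rho <- estimate_ar1(fit0)
    rho <- max(min(rho, 0.98), 0)   # whitening needs a stationary, non-negative rho
    fit1 <- fit_additive_model(covariates, response, ts, rho = rho,
                               k_hour = k_hour, k_tide = k_tide,
                               gamma = gamma, transform = transform)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      label = fit1$label, n_variables = fit1$n_variables,
      edf = fit1$edf, loglik = fit1$loglik, aicc = fit1$aicc,
      rho = rho, de_full = fit1$de_full, de_fixed = fit1$de_fixed)
    fits[[length(fits) + 1L]] <- fit1
  }
  if (length(rows) == 0L) abort("no candidate model could be fitted")
  flat <- dplyr::bind_rows(rows)
  ranking <- flat |>
    dplyr::mutate(delta_aicc = .data$aicc - min(.data$aicc)) |>
    dplyr::arrange(.data$aicc)
  pick <- apply_parsimony_rule(flat$aicc, flat$n_variables)
  structure(list(ranking = ranking, winner = fits[[pick]],
                 k_hour = k_hour, k_tide = k_tide),
            class = "gamm_selection")
}

# The two-unit parsimony rule: among candidates within two AICc units of
# the minimum, pick the fewest variables (lowest AICc breaks ties).
# Returns the index into the input vectors.
apply_parsimony_rule <- function(aicc, n_variables, window = 2) {
  near <- which(aicc - min(aicc) <= window)
  near[order(n_variables[near], aicc[near])[1]]
}

#' Predict centred effect curves from a fitted model
#'
#' Evaluates each smooth term of the model (per season for by-season
#' smooths) on a grid over the observed covariate range - the full `[0, 24]`
#' cycle for hour - with pointwise standard errors from the coefficient
#' covariance, plus the parametric season contrast. Effects are centred
#' (sum-to-zero over the data), as usual for penalized smooths.
#'
#' @param fit A `dive_gamm`.
#' @param n_grid Grid resolution per term.
#' @return A tibble `term`, `type` (smooth/parametric), `season` (by-season
#'   level or `NA`), `x` (covariate value; level code for season), `effect`,
#'   `se`.
#' @export
predict_effects <- function(fit, n_grid = 100) {
  stopifnot(inherits(fit, "dive_gamm"))
  dat <- fit$data
  base_row <- function() {
    tibble::tibble(
      hour = median(dat$hour),
      tide_height = median(dat$tide_height),
      tide_diff = median(dat$tide_diff),
      season = factor("summer", levels = levels(dat$season)),
      turtle_id = factor(levels(dat$turtle_id)[1],
                         levels = levels(dat$turtle_id))
    )
  }
  out <- list()
  for (sm in fit$fit$smooth) {
    v <- sm$term[1]
    if (v == "turtle_id") next
    xr <- if (v == "hour") c(0, 24) else range(dat[[v]])
    grid <- seq(xr[1], xr[2], length.out = n_grid)
    nd <- base_row()[rep(1, n_grid), ]
    nd[[v]] <- grid
    by_lev <- if (!is.null(sm$by) && sm$by != "NA") as.character(sm$by.level)
              else NA_character_
    if (!is.na(by_lev)) nd$season <- factor(by_lev, levels = levels(dat$season))
    pr <- predict(fit$fit, newdata = nd, type = "terms", se.fit = TRUE)
    col <- match(sm$label, colnames(pr$fit))
    out[[length(out) + 1L]] <- tibble::tibble(
      term = sprintf("s(%s)", v), type = "smooth",
      season = if (is.na(by_lev)) NA_character_ else by_lev,
      x = grid, effect = pr$fit[, col], se = pr$se.fit[, col])
  }
  if (length(out) == 0L && !fit$terms$season) {
    return(tibble::tibble(term = character(), type = character(),
                          season = character(), x = numeric(),
                          effect = numeric(), se = numeric()))
  }
  if (fit$terms$season) {
    nd <- base_row()[rep(1, 2), ]
    nd$season <- factor(levels(dat$season), levels = levels(dat$season))
    pr <- predict(fit$fit, newdata = nd, type = "terms", se.fit = TRUE)
    col <- match("season", colnames(pr$fit))
    out[[length(out) + 1L]] <- tibble::tibble(
      term = "season", type = "parametric", season = levels(dat$season),
      x = c(0, 1), effect = pr$fit[, col], se = pr$se.fit[, col])
  }
  dplyr::bind_rows(out)
}

#' @export
#' @method tidy dive_gamm
tidy.dive_gamm <- function(x, ...) {
  s <- summary(x$fit)
  sm <- tibble::tibble(
    term = rownames(s$s.table), type = "smooth",
    edf = s$s.table[, "edf"], statistic = s$s.table[, "F"],
    p.value = s$s.table[, "p-value"])
  pt <- tibble::tibble(
    term = rownames(s$p.table), type = "parametric",
    estimate = s$p.table[, "Estimate"], std.error = s$p.table[, "Std. Error"],
    statistic = s$p.table[, "t value"], p.value = s$p.table[, "Pr(>|t|)"])
  dplyr::bind_rows(pt, sm)
}

#' @export
#' @method glance dive_gamm
glance.dive_gamm <- function(x, ...) {
  tibble::tibble(
    label = x$label, n = x$n, edf = x$edf, loglik = x$loglik,
    aicc = x$aicc, rho = x$rho, de_full = x$de_full, de_fixed = x$de_fixed
  )
}

#' @export
#' @method print dive_gamm
print.dive_gamm <- function(x, ...) {
  cat("Additive model:", x$label, "\n")
  cat(sprintf("n = %d dives, edf = %.2f, AICc = %.2f, rho = %.3f\n",
              x$n, x$edf, x$aicc, x$rho))
  cat(sprintf("deviance explained: %.1f%% (full), %.1f%% (fixed only)\n",
              x$de_full, x$de_fixed))
  invisible(x)
}

#' @export
#' @method tidy gamm_selection
tidy.gamm_selection <- function(x, ...) x$ranking

#' @export
#' @method glance gamm_selection
glance.gamm_selection <- function(x, ...) glance(x$winner)

#' @export
#' @method print gamm_selection
print.gamm_selection <- function(x, ...) {
  cat("AICc model selection over", nrow(x$ranking), "candidates\n")
  print(x$ranking, n = 10)
  cat("winner:", x$winner$label, "\n")
  invisible(x)
}

#' Effect-curve plot for a fitted environmental model
#'
#' @param object A `dive_gamm` or the result of [predict_effects()].
#' @param ... Passed to [predict_effects()] when `object` is a model.
#' @return A ggplot of the centred smooth effects with ribbons of +/- 1 s.e.
#' @export
#' @method autoplot dive_gamm
autoplot.dive_gamm <- function(object, ...) {
  eff <- predict_effects(object, ...)
  sm <- dplyr::filter(eff, .data$type == "smooth") |>
    dplyr::mutate(season = dplyr::coalesce(.data$season, "both"))
  ggplot2::ggplot(sm, ggplot2::aes(.data$x, .data$effect,
                                   colour = .data$season,
                                   fill = .data$season)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$effect - .data$se,
                                      ymax = .data$effect + .data$se),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~term, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "centred effect on score",
                  colour = "season", fill = "season") +
    ggplot2::theme_minimal()
}
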