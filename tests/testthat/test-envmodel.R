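# Environmental covariates, score transforms, penalized additive fits,
# AR(1) whitening, AICc selection and effect prediction.

test_that("covariates are built from dive midpoints and the hourly tide", {
  dives <- tibble::tibble(deployment = 1, dive = 1, midpoint_s = 1800)
  tide <- tibble::tibble(time_s = c(0, 3600), sea_level_m = c(2, 3))
  md <- tibble::tibble(deployment = 1, season = "summer", start_hour = 6)
  cov <- build_covariates(dives, tide, md)
  expect_equal(cov$hour, 6.5)
  expect_equal(cov$tide_height, 2.5)
  expect_equal(cov$tide_diff, 1)
  expect_identical(levels(cov$season), c("summer", "winter"))

  # midpoint outside tide coverage names the offending dive time
  bad <- tibble::tibble(deployment = 1, dive = 1, midpoint_s = 7300)
  expect_error(build_covariates(bad, tide, md), "coverage")

  # a sinusoidal tide's forward difference tracks the analytic derivative:
  # peak rate = amplitude * 2*pi/T, attenuated by sinc(pi/T) for hourly
  # differencing
  tide2 <- simulate_tide(72, range_m = 10, period_h = 12.42)
  mids <- seq(7200, 250000, by = 1800)
  dd <- divekin:::tide_diff_at(tide2, mids)
  amp <- (max(tide2$sea_level_m) - min(tide2$sea_level_m)) / 2
  att <- sin(pi / 12.42) / (pi / 12.42)
  expect_equal(max(abs(dd)), amp * 2 * pi / 12.42 * att, tolerance = 0.05)
})

test_that("scores are log-transformed only when strongly skewed", {
  set.seed(6)
  sym <- rnorm(500)
  out <- maybe_transform_scores(sym)
  expect_false(out$record$applied)
  expect_identical(out$scores, sym)

  skewed <- exp(rnorm(500, sd = 1.2))
  out2 <- maybe_transform_scores(skewed)
  expect_true(out2$record$applied)
  expect_lt(abs(out2$record$skew_after), abs(out2$record$skew_before))

  const <- rep(2, 50)
  out3 <- maybe_transform_scores(const)
  expect_false(out3$record$applied)
  expect_error(maybe_transform_scores(c(1, NA)), "finite")
})

test_that("term grammar builds 35 candidates and labels sizes correctly", {
  cand <- divekin:::candidate_term_sets()
  expect_identical(length(cand), 35L)
  labels <- vapply(cand, divekin:::term_set_label, character(1))
  expect_identical(sum(labels == "null"), 1L)
  expect_identical(anyDuplicated(labels), 0L)
  # by-season smooths force the parametric season term
  ts <- term_set(hour = "by_season")
  expect_true(ts$season)
  expect_identical(divekin:::term_set_size(term_set("plain", "by_season",
                                                    season = TRUE)), 3L)
})

test_that("a linear covariate effect is recovered by the penalized smooth", {
  set.seed(7)
  d <- simulate_dive_scores(n_turtles = 6, dives_per_turtle = 80,
                            diel_amp = 0, tide_slope = c(summer = 0, winter = 0),
                            season_shift = 0, re_sd = 0, resid_sd = 0.02,
                            rho = 0, seed = 7)
  y <- 2 * d$tide_height + rnorm(nrow(d), sd = 0.02)
  fit <- fit_additive_model(d, y, term_set(tide_height = "plain"))
  eff <- predict_effects(fit, n_grid = 200)
  th <- eff[eff$term == "s(tide_height)", ]
  qs <- quantile(d$tide_height, c(0.05, 0.95))
  core <- th$x >= qs[1] & th$x <= qs[2]
  resid <- th$effect[core] - (2 * th$x[core] - mean(2 * th$x[core]))
  expect_lt(max(abs(resid)) / diff(range(2 * th$x[core])), 0.02)
  expect_true(all(th$se > 0))
})

test_that("the cyclic hour smooth is continuous at the 0/24 boundary", {
  d <- simulate_dive_scores(n_turtles = 8, dives_per_turtle = 80, seed = 9)
  fit <- fit_additive_model(d, d$score, term_set(hour = "plain",
                                                 tide_height = "plain"))
  nd <- fit$data[rep(1, 4), ]
  nd$hour <- c(0, 24, 1e-4, 24 - 1e-4)
  pr <- predict(fit$fit, newdata = nd, type = "terms")
  col <- grep("hour", colnames(pr))
  expect_lt(abs(pr[1, col] - pr[2, col]), 1e-6)
  d0 <- (pr[3, col] - pr[1, col]) / 1e-4
  d24 <- (pr[2, col] - pr[4, col]) / 1e-4
  expect_lt(abs(d0 - d24), 1e-3 * max(1, abs(d0)))
})

test_that("lag-1 residual autocorrelation is estimated and whitened away", {
  set.seed(8)
  # white noise: unbiased near-zero estimate (Monte-Carlo over replicates)
  g <- factor(rep(1:10, each = 200))
  ests <- replicate(10, estimate_ar1(rnorm(2000), g))
  expect_lt(abs(mean(ests)), 0.02)
  expect_lt(mean(abs(ests)), 0.05)
  # AR(1) with rho 0.6: recovered within 0.05
  e <- as.numeric(replicate(10, arima.sim(list(ar = 0.6), 200)))
  expect_lt(abs(estimate_ar1(e, g) - 0.6), 0.05)
  # groups too short for a lag: zero with a warning
  expect_warning(r0 <- estimate_ar1(rnorm(6), factor(1:6)), "rho = 0")
  expect_identical(r0, 0)

  # whitening with the estimated rho removes the residual autocorrelation
  d <- simulate_dive_scores(n_turtles = 10, dives_per_turtle = 150,
                            rho = 0.5, seed = 11)
  true_set <- term_set("by_season", "by_season", "by_season")
  f0 <- fit_additive_model(d, d$score, true_set)
  rho <- estimate_ar1(f0)
  expect_lt(abs(rho - 0.5), 0.07)
  f1 <- fit_additive_model(d, d$score, true_set, rho = rho)
  expect_lt(abs(estimate_ar1(f1)), 0.05)
})

test_that("AICc reproduces its formula and model metrics are coherent", {
  d <- simulate_dive_scores(n_turtles = 6, dives_per_turtle = 50, seed = 13)
  fit <- fit_additive_model(d, d$score, term_set(hour = "plain",
                                                 season = TRUE))
  p <- fit$edf; n <- fit$n; ll <- fit$loglik
  expect_equal(fit$aicc, -2 * ll + 2 * p + 2 * p * (p + 1) / (n - p - 1),
               tolerance = 1e-9)
  expect_gt(fit$aicc, -2 * ll + 2 * p)      # AICc >= AIC for finite n
  expect_gte(fit$de_full + 1e-6, fit$de_fixed)
  expect_true(fit$de_full >= 0 && fit$de_full <= 100)
  expect_error(fit_additive_model(d, rep(Inf, nrow(d)), term_set()), "finite")
})

test_that("random intercepts recover planted per-animal offsets", {
  d <- simulate_dive_scores(n_turtles = 24, dives_per_turtle = 150,
                            re_sd = 0.5, seed = 15)
  fit <- fit_additive_model(d, d$score,
                            term_set("plain", "by_season", season = TRUE))
  cf <- coef(fit$fit)
  re <- cf[grep("s\\(turtle_id\\)", names(cf))]
  truth <- attr(d, "intercepts")$intercept
  expect_gte(cor(re, truth), 0.9)
})

test_that("AICc selection follows the two-unit parsimony rule", {
  # within two units of the minimum, the smaller model wins
  expect_identical(divekin:::apply_parsimony_rule(c(100, 98.7), c(3, 5)), 1L)
  # outside the window, the minimum wins regardless of size
  expect_identical(divekin:::apply_parsimony_rule(c(101.5, 98.7), c(3, 5)), 2L)
  # inside the window the smallest model wins even if not the minimum
  expect_identical(divekin:::apply_parsimony_rule(c(99, 98.7, 100), c(3, 3, 1)),
                   3L)
  # equal sizes inside the window break towards the lower AICc
  expect_identical(divekin:::apply_parsimony_rule(c(99, 98.7), c(3, 3)), 2L)

  # and on real fits the ranking always reports the rule inputs needed to
  # audit a selection
  d <- simulate_dive_scores(n_turtles = 8, dives_per_turtle = 50, seed = 23)
  sel <- suppressWarnings(select_model(d, d$score, candidates = list(
    term_set(season = TRUE), term_set("plain", season = TRUE))))
  rk <- tidy(sel)
  expect_true(all(c("label", "n_variables", "aicc", "delta_aicc", "rho")
                  %in% names(rk)))
  expect_equal(min(rk$delta_aicc), 0)
})

test_that("selection with planted effects recovers the true term set", {
  # planted: by-season cyclic diel effect + by-season tide-height and
  # tide-rate effects + turtle intercepts + AR(1) residuals
  true_lab <- paste("s(hour x season) + s(tide_height x season) +",
                    "s(tide_diff x season) + season")
  wins <- 0; n_seeds <- 4
  for (s in seq_len(n_seeds)) {
    d <- simulate_dive_scores(n_turtles = 14, dives_per_turtle = 70,
                              rho = 0.5, seed = 300 + s)
    sel <- suppressWarnings(select_model(d, d$score))
    if (sel$winner$label == true_lab) wins <- wins + 1
  }
  expect_gte(wins / n_seeds, 0.75)
})

test_that("with no planted effects the grammar does not overfit badly", {
  # AICc plus the two-unit parsimony rule cannot fully suppress spurious
  # inclusion over a 35-candidate grammar (~5% per upgrade direction), but
  # the null model must win a majority of seeds and spurious winners stay
  # small
  wins <- 0; n_seeds <- 8; max_vars <- 0
  for (s in seq_len(n_seeds)) {
    d <- simulate_dive_scores(n_turtles = 10, dives_per_turtle = 60,
                              diel_amp = 0,
                              tide_slope = c(summer = 0, winter = 0),
                              tide_diff_slope = c(summer = 0, winter = 0),
                              season_shift = 0, rho = 0, seed = 520 + s)
    sel <- suppressWarnings(select_model(d, d$score))
    wins <- wins + (sel$winner$label == "null")
    max_vars <- max(max_vars, sel$winner$n_variables)
  }
  expect_gte(wins / n_seeds, 0.5)
  expect_lte(max_vars, 2)
})

test_that("effect prediction is consistent with the fitted terms", {
  d <- simulate_dive_scores(n_turtles = 8, dives_per_turtle = 60, seed = 19)
  fit <- fit_additive_model(d, d$score,
                            term_set("plain", "by_season", season = TRUE))
  eff <- predict_effects(fit, n_grid = 50)
  expect_setequal(unique(eff$term), c("s(hour)", "s(tide_height)", "season"))
  # by-season smooth appears once per season
  expect_identical(sum(eff$term == "s(tide_height)" & eff$season == "winter"),
                   50L)
  # smooth-effect uncertainty bands are strictly positive everywhere (the
  # parametric reference level legitimately has se 0)
  expect_true(all(eff$se[eff$type == "smooth"] > 0))
  # partial effects at the training covariates sum back to the fitted values
  pr <- predict(fit$fit, newdata = fit$data, type = "terms")
  recomposed <- rowSums(pr) + attr(pr, "constant")
  expect_equal(unname(recomposed), unname(fitted(fit$fit)),
               tolerance = 1e-9)
})
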