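# Signal-level kinematics: ZOC, resampling, the static/dynamic split,
# ODBA/VeDBA, pitch, heading, circular variance and dead-reckoning.

test_that("zero-offset correction recovers a drifting surface baseline", {
  set.seed(1)
  # hourly surfacings with a constant +0.4 m sensor offset
  depth <- rep(0.4, 7200)
  for (s in seq(300, 6900, by = 600)) {
    depth[s:(s + 180)] <- depth[s:(s + 180)] + 5
  }
  corrected <- zero_offset_correct(depth, window_s = 600)
  surface <- corrected[depth == 0.4]
  expect_true(abs(median(surface)) <= 0.02)

  # idempotence on an already-zeroed trace
  clean <- pmax(depth - 0.4, 0)
  again <- zero_offset_correct(clean, window_s = 600)
  expect_lt(max(abs(again - clean)), 0.02)

  # all-surface record collapses to ~0
  flat <- zero_offset_correct(rep(0.3, 3600), window_s = 600)
  expect_lt(max(abs(flat)), 1e-9)

  expect_warning(zero_offset_correct(rep(0.2, 100), window_s = 600),
                 "global offset")
  expect_error(zero_offset_correct(depth, window_s = 30), ">= 60")
})

test_that("bin-mean resampling reproduces closed-form bin means", {
  const <- resample_uniform(seq(0, 9.9, by = 0.1), rep(3, 100))
  expect_equal(const$value, rep(3, 10))

  ramp <- resample_uniform(seq(0, 9.9, by = 0.1), 0.01 * (0:99))
  expect_equal(ramp$value, 0.045 + 0.1 * (0:9), tolerance = 1e-12)

  # circular channel: the mean of 359 and 1 degrees is 0, not 180
  circ <- resample_uniform(c(0.2, 0.6), c(359, 1) * pi / 180,
                           circular = TRUE)
  expect_lt(abs(((circ$value + pi) %% (2 * pi)) - pi), 1e-9)

  empty <- resample_uniform(numeric(0), numeric(0))
  expect_identical(nrow(empty), 0L)
})

test_that("resampling flags long gaps and bridges short ones", {
  t <- c(seq(0, 4.9, 0.1), seq(13, 17.9, 0.1))
  out <- resample_uniform(t, rep(1, length(t)))
  expect_true(all(is.na(out$value[out$time %in% 5:12])))
  t2 <- c(seq(0, 4.9, 0.1), seq(8, 12.9, 0.1))
  out2 <- resample_uniform(t2, c(rep(1, 50), rep(3, 50)))
  expect_false(any(is.na(out2$value)))
})

test_that("static/dynamic split is an exact complement with known attenuation", {
  n <- 400
  const <- data.frame(x = rep(0, n), y = rep(0, n), z = rep(1, n))
  dec <- split_acceleration(const, sample_rate = 20)
  expect_equal(as.matrix(dec$static), as.matrix(const), ignore_attr = TRUE)
  expect_true(all(as.matrix(dec$dynamic) == 0))

  # DC 1.0 + 0.2 sine at 2 Hz, 20 Hz sampling, 4 s (81-sample) boxcar:
  # Dirichlet gain H = 1/81, so dynamic RMS = 0.2 * (1 - 1/81) / sqrt(2)
  t <- seq(0, 60, by = 0.05)
  sine <- data.frame(x = 1 + 0.2 * sin(2 * pi * 2 * t),
                     y = 0 * t, z = 0 * t)
  dec2 <- split_acceleration(sine, sample_rate = 20)
  mid <- 200:(nrow(sine) - 200)
  rms <- sqrt(mean(dec2$dynamic$x[mid]^2))
  expect_equal(rms, 0.2 * (1 - 1 / 81) / sqrt(2), tolerance = 1e-3)
  expect_equal(rms, 0.141, tolerance = 0.05)

  set.seed(2)
  noisy <- data.frame(x = rnorm(n), y = rnorm(n), z = rnorm(n))
  dec3 <- split_acceleration(noisy, sample_rate = 20)
  expect_equal(as.matrix(dec3$static) + as.matrix(dec3$dynamic),
               as.matrix(noisy), tolerance = 1e-12, ignore_attr = TRUE)

  expect_error(split_acceleration(noisy, window_s = 0.05, sample_rate = 20),
               "3 samples")
})

test_that("ODBA and VeDBA follow their closed forms and inequality", {
  m <- body_acceleration_metrics(data.frame(0.1, -0.2, 0.3))
  expect_equal(m$odba_g, 0.6)
  m2 <- body_acceleration_metrics(data.frame(0.3, 0.4, 0))
  expect_equal(m2$vedba_g, 0.5)
  m3 <- body_acceleration_metrics(data.frame(0, 0, 0))
  expect_equal(c(m3$odba_g, m3$vedba_g), c(0, 0))

  set.seed(3)
  d <- matrix(rnorm(300), ncol = 3)
  m4 <- body_acceleration_metrics(d)
  expect_true(all(m4$vedba_g <= m4$odba_g + 1e-12))
  expect_true(all(m4$odba_g <= sqrt(3) * m4$vedba_g + 1e-12))
})

test_that("pitch from acceleration matches closed-form angles", {
  expect_equal(pitch_from_acceleration(0, 0.6, 0.8), 0)
  expect_equal(pitch_from_acceleration(1, 0, 0), 90)
  expect_equal(pitch_from_acceleration(-1, 0, 0), -90)
  expect_equal(pitch_from_acceleration(-0.5, 0, 0.8660254), -30,
               tolerance = 1e-6)
  # offset subtraction and clamping
  expect_equal(pitch_from_acceleration(1, 0, 0, correction_offset = -5), 90)
  expect_equal(pitch_from_acceleration(0, 0, 1, correction_offset = 10), -10)
})

test_that("tag mounting pitch offset is recovered from level swimming", {
  dep <- small_deployment()$dep
  kin <- small_deployment()$kin
  expect_lt(abs(attr(kin, "pitch_offset") - dep$deployment$pitch_offset_deg),
            0.5)

  # a zero-offset record estimates ~0
  pitch <- c(rep(0, 200), rep(30, 50), rep(0, 200))
  depth <- c(rep(5, 200), seq(5, 20, length.out = 50), rep(20, 200))
  expect_lt(abs(estimate_pitch_offset(pitch, depth)), 1e-9)

  # all-surface record: no qualifying samples
  expect_error(estimate_pitch_offset(rep(0, 100), rep(0.2, 100)),
               "manually")
})

test_that("tilt-compensated heading inverts the forward rotation model", {
  # level body, field pointing North with positive down-component
  h <- cos(45 * pi / 180); v <- -sin(45 * pi / 180)
  lev <- heading_from_sensors(data.frame(0, 0, 1), data.frame(h, 0, v))
  expect_equal(lev$heading_rad, 0, tolerance = 1e-9)
  yawed <- heading_from_sensors(data.frame(0, 0, 1), data.frame(0, -h, v))
  expect_equal(yawed$heading_rad, pi / 2, tolerance = 1e-9)

  # random attitudes up to 60 deg tilt: compare against an independent
  # forward model built from explicit rotation matrices
  set.seed(4)
  Rx <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a),
                             0, -sin(a), cos(a)), 3, 3)
  Ry <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0,
                             sin(a), 0, cos(a)), 3, 3)
  Rz <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0,
                             0, 0, 1), 3, 3)
  m_w <- c(0, cos(45 * pi / 180), -sin(45 * pi / 180))  # (E, N, Up)
  for (i in 1:50) {
    psi <- runif(1, 0, 2 * pi)
    theta <- runif(1, -60, 60) * pi / 180
    phi <- runif(1, -60, 60) * pi / 180
    R <- Rz(-psi) %*% Rx(theta) %*% Ry(phi)   # body (right,fwd,up) -> world
    g_b <- t(R) %*% c(0, 0, 1)
    m_b <- t(R) %*% m_w
    # sensor order: X = surge (fwd), Y = sway (right), Z = heave (up)
    acc <- data.frame(g_b[2], g_b[1], g_b[3])
    mag <- data.frame(m_b[2], m_b[1], m_b[3])
    out <- heading_from_sensors(acc, mag)
    err <- abs(((out$heading_rad - psi + pi) %% (2 * pi)) - pi)
    expect_lt(err, 1e-6)
  }
})

test_that("gimbal-degenerate headings are flagged and interpolated", {
  acc <- data.frame(x = c(0, 1, 0), y = c(0, 0, 0), z = c(1, 1e-3, 1))
  h <- cos(pi / 4); v <- -sin(pi / 4)
  mag <- data.frame(x = c(h, v, h), y = c(0, 0, 0), z = c(v, -h, v))
  out <- heading_from_sensors(acc, mag)
  expect_identical(out$degenerate, c(FALSE, TRUE, FALSE))
  expect_equal(out$heading_rad[2], 0, tolerance = 1e-6)
})

test_that("circular variance matches vector-mean arithmetic", {
  expect_equal(circular_variance(rep(1.3, 10)), 0)
  expect_equal(circular_variance(c(0, pi / 2, pi, 3 * pi / 2)), 1,
               tolerance = 1e-12)
  expect_equal(circular_variance(c(0, pi / 2)), 1 - sqrt(2) / 2,
               tolerance = 1e-12)
  expect_error(circular_variance(numeric(0)), "at least one")
})

test_that("dead-reckoned tracks integrate heading, pitch and speed", {
  n <- 60
  straight <- dead_reckon_track(rep(0, n), rep(0, n),
                                vedba = rep(1 / 1.6 + 0.05, n),
                                depth = rep(2, n))
  expect_equal(straight$easting_m[n], 0, tolerance = 1e-9)
  expect_equal(straight$northing_m[n], 59, tolerance = 1e-9)
  expect_equal(straight$easting_m[1], 0)

  # four 90-degree legs of equal length close on the anchor
  square <- dead_reckon_track(rep(c(0, pi / 2, pi, 3 * pi / 2), each = 10),
                              rep(0, 40), rep(1 / 1.6 + 0.05, 40),
                              rep(1, 40), anchor = c(5, 5))
  expect_equal(unlist(square[1, c("easting_m", "northing_m")]), c(5, 5),
               ignore_attr = TRUE)
  # position after all 40 unit steps (row 40 plus its own step) = anchor
  closing <- c(square$easting_m[40] + sin(3 * pi / 2),
               square$northing_m[40] + cos(3 * pi / 2))
  expect_equal(closing, c(5, 5), tolerance = 1e-6)

  # path length decomposes exactly
  set.seed(5)
  hdg <- runif(200, 0, 2 * pi); pit <- runif(200, -60, 60)
  ved <- runif(200, 0, 0.6); dep <- runif(200, 0, 10)
  tr <- dead_reckon_track(hdg, pit, ved, dep)
  steps <- sqrt(diff(tr$easting_m)^2 + diff(tr$northing_m)^2)
  speed <- 1.6 * pmax(ved - 0.05, 0) * cos(pit * pi / 180)
  expect_equal(sum(steps), sum(speed[-200]), tolerance = 1e-9)

  expect_error(dead_reckon_track(1:3, 1:3, 1:2, 1:3), "equal length")
})

test_that("measured 1 Hz kinematics recover the planted pitch and heading truth", {
  fx <- small_deployment()
  kin <- fx$kin; ts <- fx$dep$truth_series
  m <- min(nrow(kin), nrow(ts))
  # pitch matches planted pitch away from transitions (interior samples)
  perr <- abs(kin$pitch_deg[1:m] - ts$pitch_deg[1:m])
  expect_lt(quantile(perr, 0.9, na.rm = TRUE), 1)
  # ODBA/VeDBA inequality holds on the full measured record
  ok <- !is.na(kin$odba_g)
  expect_true(all(kin$vedba_g[ok] <= kin$odba_g[ok] + 1e-9))
  expect_true(all(kin$odba_g[ok] <= sqrt(3) * kin$vedba_g[ok] + 1e-9))
})
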