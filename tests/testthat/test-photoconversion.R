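flat_movie <- function(value = 0.5, n_frames = 6, nx = 80, ny = 50) {
  frames <- replicate(n_frames, matrix(value, ny, nx), simplify = FALSE)
  photoconversion_movie(
    frames, pixel_size = 0.1, frame_interval = 5,
    pole_tracks = list(matrix(c(1, 2.5), n_frames, 2, byrow = TRUE),
                       matrix(c(7, 2.5), n_frames, 2, byrow = TRUE)))
}

test_that("movies round-trip through TIFF + sidecar within float precision", {
  cfg <- synthetic_movie_config(seed = 61, duration = 0.5)
  gm <- generate_movie(cfg)
  path <- file.path(tempdir(), "mv")
  write_movie(gm$movie, path)
  mv2 <- read_movie(path)
  expect_identical(length(mv2$frames), length(gm$movie$frames))
  rng <- max(abs(unlist(gm$movie$frames)))
  err <- max(abs(unlist(mv2$frames) - unlist(gm$movie$frames)))
  expect_lt(err / rng, 1e-6)
  expect_equal(mv2$pole_tracks, gm$movie$pole_tracks, ignore_attr = TRUE)
  expect_equal(mv2$frame_interval, gm$movie$frame_interval,
               ignore_attr = TRUE)
})

test_that("movie container validates frame shapes and pole tracks", {
  f <- list(matrix(0, 5, 5), matrix(0, 4, 5))
  tr <- list(matrix(0, 2, 2), matrix(0, 2, 2))
  expect_error(photoconversion_movie(f, 0.1, 5, tr), "same shape")
  expect_error(photoconversion_movie(list(matrix(0, 5, 5)), 0.1, 5,
                                     list(matrix(0, 1, 2))), "pole tracks")
})

test_that("a uniform image yields a flat profile at the uniform value", {
  mv <- flat_movie(0.37)
  prof <- extract_line_profile(mv, 1)
  expect_true(all(abs(prof$intensity - 0.37) < 1e-12))
  # and no peak is found above the noise floor
  expect_false(fit_peak(prof)$ok)
})

test_that("a Gaussian stripe is located to within a pixel, rotation-invariant", {
  nx <- 90; ny <- 60; px <- 0.1
  mk <- function(theta) {
    ctr <- c(4.5, 3)
    u <- c(cos(theta), sin(theta))
    p1 <- ctr - 3 * u; p2 <- ctr + 3 * u
    x0 <- 1.2   # stripe at 1.2 um from pole 1 along the axis
    xc <- (col(matrix(0, ny, nx)) - 0.5) * px
    yc <- (row(matrix(0, ny, nx)) - 0.5) * px
    a <- (xc - p1[1]) * u[1] + (yc - p1[2]) * u[2]
    f <- exp(-(a - x0)^2 / (2 * 0.3^2))
    list(movie = photoconversion_movie(
      list(f), px, 5,
      list(matrix(p1, 1, 2, byrow = TRUE), matrix(p2, 1, 2, byrow = TRUE))),
      x0 = x0)
  }
  m0 <- mk(0)
  prof0 <- extract_line_profile(m0$movie, 1)
  pk0 <- fit_peak(prof0)
  expect_lt(abs(pk0$center - m0$x0), px)
  m30 <- mk(30 * pi / 180)
  prof30 <- extract_line_profile(m30$movie, 1)
  pk30 <- fit_peak(prof30)
  expect_lt(abs(pk30$center - m30$x0), px)
  # profiles agree where both are defined
  common <- intersect(round(prof0$pos, 3), round(prof30$pos, 3))
  common <- common[common > 0.3 & common < 2.5]
  i0 <- match(common, round(prof0$pos, 3))
  i30 <- match(common, round(prof30$pos, 3))
  rel <- sqrt(mean((prof0$intensity[i0] - prof30$intensity[i30])^2)) /
    max(prof0$intensity)
  expect_lt(rel, 0.01)
})

test_that("an exact Gaussian peak is fit to near machine precision", {
  x <- seq(0, 8, by = 0.1)
  y <- 1.7 * exp(-(x - 3.23)^2 / (2 * 0.4^2))
  prof <- data.frame(pos = x, intensity = y)
  attr(prof, "pixel_size") <- 0.1
  pk <- fit_peak(prof)
  expect_true(pk$ok)
  expect_equal(pk$center, 3.23, tolerance = 1e-8)
  expect_equal(pk$height, 1.7, tolerance = 1e-6)
  expect_equal(pk$sigma, 0.4, tolerance = 1e-4)
})

test_that("among equal peaks the one nearest the previous center wins", {
  x <- seq(0, 8, by = 0.1)
  y <- exp(-(x - 2)^2 / (2 * 0.3^2)) + exp(-(x - 6)^2 / (2 * 0.3^2))
  prof <- data.frame(pos = x, intensity = y)
  attr(prof, "pixel_size") <- 0.1
  expect_equal(fit_peak(prof, previous_center = 3)$center, 2,
               tolerance = 0.01)
  expect_equal(fit_peak(prof, previous_center = 5.2)$center, 6,
               tolerance = 0.01)
})

test_that("peak centers are recovered within 0.2 px at SNR 10", {
  set.seed(71)
  x <- seq(0, 8, by = 0.1)
  # peak width matched to the 5-pixel fit window (sigma = 1.5 px)
  err <- replicate(500, {
    mu <- runif(1, 3, 5)
    y <- exp(-(x - mu)^2 / (2 * 0.15^2)) + rnorm(length(x), 0, 0.1)
    pk <- fit_peak(data.frame(pos = x, intensity = y))
    if (pk$ok) abs(pk$center - mu) else NA
  })
  expect_lt(mean(err, na.rm = TRUE), 0.2 * 0.1)
})

test_that("height correction identities hold", {
  h <- c(1, 0.8, 0.6)
  expect_identical(correct_height(h), h)
  expect_equal(correct_height(h, opposite = 0.1), h - 0.1)
  t <- 0:2
  bl <- exp(-0.2 * t)
  expect_equal(correct_height(h * bl, bleach = bl), h, tolerance = 1e-12)
  expect_error(correct_height(h, bleach = c(1, 0, 1)), "positive")
})

test_that("single-exponential input degenerates cleanly in the dual fit", {
  t <- seq(0, 5, by = 1 / 12)
  h <- 0.9 * exp(-0.5 * t)
  tf <- fit_turnover(t, h)
  expect_true(tf$converged)
  expect_equal(tf$k_slow, 0.5, tolerance = 0.01)
  expect_lt(tf$A_fast, 0.02 * tf$A_slow)
})

test_that("measurement-like dual-exponential parameters are recovered from ideal traces", {
  t <- seq(0, 2.5, by = 5 / 60)
  set.seed(72)
  res <- replicate(200, {
    h <- 0.26 * exp(-t / 2.8) + 0.74 * exp(-t / 0.26) +
      rnorm(length(t), 0, 0.01)
    tf <- fit_turnover(t, h)
    c(tf$slow_fraction, tf$k_slow, tf$k_fast)
  })
  expect_equal(mean(res[1, ]), 0.26, tolerance = 0.02)
  expect_equal(mean(res[2, ]), 1 / 2.8, tolerance = 0.02)
  expect_equal(mean(res[3, ]), 1 / 0.26, tolerance = 0.02)
})

test_that("line speed fits report poleward motion and unit conversion", {
  t5 <- (0:10) * 5 / 60         # 5 s frames in minutes
  ctr <- 4 - 0.1 * (0:10)       # 0.1 um per frame poleward
  sf <- fit_speed(t5, ctr)
  expect_equal(sf$speed, 1.2, tolerance = 1e-9)
  expect_equal(sf$initial_position, 4, tolerance = 1e-9)
  expect_false(sf$flagged)
  st <- fit_speed(t5, rep(2.2, 11))
  expect_equal(st$speed, 0, tolerance = 1e-12)
  expect_true(fit_speed(t5[1:3], ctr[1:3])$flagged)
})

test_that("simulated marks translate rigidly at constant tubulin speed", {
  ax <- structure(list(points = cbind(seq(0, 6, 0.05), 0),
                       s = seq(0, 6, 0.05), pole = 1), class = "streamline")
  kins <- data.frame(streamline = 1, s_kin = rep(6, 40), rate = 3)
  # constant v: dv/ds = 0, no treadmilling gradient
  prof <- structure(list(amp = 0, mu = 1, sigma = 1, c0 = 1,
                         fit_valid = TRUE, s_max = 6),
                    class = "minus_end_profile")
  sp <- solve_speed(prof, recruitment_nucleate(), r = 0.4, s_kin = 6)
  sp$v <- rep(0.9, length(sp$s))
  sp <- treadmill_profile(sp, s_pole = 1e-9)   # v_tub = 0.9 everywhere
  set.seed(73)
  sim <- simulate_photoconversion(sp, list(ax), kins, activation_s = 4,
                                  r = 1e-3, duration = 1.5, gamma = 0.5)
  ana <- analyze_movie(sim$movie)
  expect_equal(ana$speed$speed, 0.9, tolerance = 0.05)
})

test_that("marked tubulin is conserved without turnover and decays with it", {
  ax <- structure(list(points = cbind(seq(0, 6, 0.05), 0),
                       s = seq(0, 6, 0.05), pole = 1), class = "streamline")
  kins <- data.frame(streamline = 1, s_kin = rep(6, 40), rate = 3)
  prof <- structure(list(amp = 0, mu = 1, sigma = 1, c0 = 1,
                         fit_valid = TRUE, s_max = 6),
                    class = "minus_end_profile")
  sp <- solve_speed(prof, recruitment_nucleate(), r = 0.4, s_kin = 6)
  # constant tubulin speed, no treadmilling: marks never overrun the minus
  # end, so with negligible detachment the marked weight is conserved
  sp$v <- rep(0.9, length(sp$s))
  sp <- treadmill_profile(sp, s_pole = 1e-9)
  set.seed(74)
  sim0 <- simulate_photoconversion(sp, list(ax), kins, activation_s = 3,
                                   r = 1e-4, duration = 1.5)
  tm <- sim0$truth$total_marked
  expect_lt(diff(range(tm)) / tm[1], 0.02)
  # detachment at r: marked weight decays like exp(-r t); a single
  # population is dominated by few KMTs, so average several replicates
  slopes <- vapply(1:4, function(k) {
    set.seed(74 + k)
    sim1 <- simulate_photoconversion(sp, list(ax), kins, activation_s = 3,
                                     r = 0.5, duration = 2)
    t_fr <- (seq_along(sim1$truth$total_marked) - 1) * 5 / 60
    -unname(coef(stats::lm(log(sim1$truth$total_marked) ~ t_fr))[2])
  }, numeric(1))
  expect_equal(mean(slopes), 0.5, tolerance = 0.12)
})

test_that("the peak width spreads over time in bulk simulations", {
  stack <- sim_stack()
  set.seed(76)
  sim <- simulate_photoconversion(stack$speed, stack$streamlines,
                                  stack$kinetochores, activation_s = 3.5,
                                  seed = 42)
  widths <- vapply(seq(1, 31, by = 5), function(fr) {
    prof <- extract_line_profile(sim$movie, fr)
    fit_peak(prof)$sigma
  }, numeric(1))
  # monotone trend, not magnitude: late widths exceed early ones
  expect_gt(mean(widths[4:6], na.rm = TRUE), mean(widths[1:2], na.rm = TRUE))
})

test_that("analysis of simulated movies recovers the detachment rate without shear", {
  # a spatially varying v(s) compresses the advecting line (dv/ds > 0), so
  # peak height confounds detachment with compression; at uniform tubulin
  # speed the height decay is the detachment rate alone
  stack <- sim_stack()
  sp <- stack$speed
  sp$v <- rep(0.8, length(sp$s))
  sp <- treadmill_profile(sp, s_pole = 1e-9)
  rates <- t(vapply(1:4, function(k) {
    sim <- simulate_photoconversion(sp, stack$streamlines,
                                    stack$kinetochores, activation_s = 3.5,
                                    r = 0.4, duration = 2.5, seed = 100 + k)
    tr <- analyze_movie(sim$movie)$track
    ok <- is.finite(tr$corrected) & tr$corrected > 0 & tr$t_min <= 2
    t_fr <- (seq_along(sim$truth$total_marked) - 1) * 5 / 60
    c(chain = -unname(coef(stats::lm(log(tr$corrected[ok]) ~
                                       tr$t_min[ok]))[2]),
      truth = -unname(coef(stats::lm(log(sim$truth$total_marked) ~
                                       t_fr))[2]))
  }, numeric(2)))
  # the extracted height decay follows the realised marked-tubulin decay
  expect_equal(mean(rates[, "chain"]), mean(rates[, "truth"]),
               tolerance = 0.12)
  # and the realised decay is the configured detachment rate (plus a small
  # pole-chipping contribution)
  expect_equal(mean(rates[, "truth"]), 0.4, tolerance = 0.15)
})
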