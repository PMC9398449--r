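onekin <- function(n = 40, s_kin = 4.5, rate = 1) {
  data.frame(streamline = 1, s_kin = rep(s_kin, n), rate = rate)
}

test_that("with no nucleation the population decays exponentially", {
  sp <- solve_speed(measured_profile(), recruitment_nucleate(), r = 0.4)
  set.seed(51)
  n0 <- 60
  init <- data.frame(s = runif(n0, 0.5, 4), s_kin = 4.5, kin = 1L)
  reps <- 60
  counts <- replicate(reps, {
    pop <- run_kmt_simulation(sp, onekin(1, rate = 0), init = init,
                              dt = 0.02, t_end = 2.5, burn_in = 2.5,
                              snapshot_every = 10)
    utils::tail(pop$count, 1)
  })
  expected <- n0 * exp(-0.4 * 2.5)
  # mean of `reps` binomial survivals within 3 sigma
  sd_mean <- sqrt(n0 * exp(-1) * (1 - exp(-1))) / sqrt(reps)
  expect_lt(abs(mean(counts) - expected), 3 * sd_mean + 0.5)
})

test_that("steady-state population matches nucleation / detachment with Poisson bands", {
  sp <- solve_speed(measured_profile(), recruitment_nucleate(), r = 0.4)
  set.seed(52)
  pop <- run_kmt_simulation(sp, onekin(40, rate = 1), dt = 0.01, t_end = 50,
                            burn_in = 10, snapshot_every = 5)
  expected <- 40 * 1 / 0.4   # 100
  post <- pop$count[1001:5000]
  expect_lt(abs(mean(post) - expected) / expected, 0.1)
  expect_lt(abs(mean(post) - expected), 3 * sqrt(expected))
})

test_that("detachment times are exponential with the configured rate", {
  sp <- solve_speed(measured_profile(), recruitment_nucleate(), r = 0.4)
  set.seed(53)
  pop <- run_kmt_simulation(sp, onekin(60, rate = 2), dt = 0.01, t_end = 45,
                            burn_in = 5, snapshot_every = 5)
  # exclude births near t_end: their lifetimes are right-censored
  lt <- pop$lifetimes[pop$lifetime_births < 45 - 20]
  expect_gt(length(lt), 2000)
  kt <- stats::ks.test(lt, "pexp", 0.4)
  expect_gt(kt$p.value, 0.01)
})

test_that("steady-state minus ends reproduce the driving density profile", {
  prof <- measured_profile()
  sp <- solve_speed(prof, recruitment_nucleate(), r = 0.4)
  set.seed(54)
  pop <- run_kmt_simulation(sp, onekin(60, rate = 1), dt = 0.005, t_end = 60,
                            burn_in = 12, snapshot_every = 6)
  sm <- pooled_minus_ends(pop)
  expect_gt(length(sm), 1000)
  kt <- suppressWarnings(stats::ks.test(sm, profile_cdf(prof, 4.5)))
  expect_gt(kt$p.value, 0.01)
})

test_that("burn-in suffices: early and late post-burn-in halves agree", {
  sp <- solve_speed(measured_profile(), recruitment_nucleate(), r = 0.4)
  set.seed(55)
  pop <- run_kmt_simulation(sp, onekin(50, rate = 1), dt = 0.01, t_end = 58,
                            burn_in = 8, snapshot_every = 2)
  counts <- pop$count[801:5800]
  half <- length(counts) %/% 2
  m1 <- mean(counts[1:half]); m2 <- mean(counts[(half + 1):(2 * half)])
  sdm <- sd(counts) / sqrt(half / 250)   # ~250 steps per lifetime
  expect_lt(abs(m1 - m2), 2 * sdm)
})

test_that("fixed seeds give identical trajectories", {
  sp <- solve_speed(measured_profile(), recruitment_nucleate(), r = 0.4)
  run1 <- local({set.seed(56); run_kmt_simulation(sp, onekin(10), dt = 0.02,
                                                  t_end = 10, burn_in = 5,
                                                  snapshot_every = 2)})
  run2 <- local({set.seed(56); run_kmt_simulation(sp, onekin(10), dt = 0.02,
                                                  t_end = 10, burn_in = 5,
                                                  snapshot_every = 2)})
  expect_identical(run1$snapshots, run2$snapshots)
  expect_identical(run1$lifetimes, run2$lifetimes)
})

test_that("capture recruitment draws initial minus ends from j(s)", {
  prof <- measured_profile()
  cap <- capture_recruitment(function(s) profile_density(prof, s),
                             reach_length = Inf, s_kin = 4.5)
  sp <- solve_speed(prof, cap, r = 0.4)   # v = 0: positions never move
  set.seed(57)
  pop <- run_kmt_simulation(sp, onekin(50, rate = 1), model = cap,
                            dt = 0.01, t_end = 40, burn_in = 10,
                            snapshot_every = 5)
  sm <- pooled_minus_ends(pop)
  kt <- suppressWarnings(stats::ks.test(sm, profile_cdf(prof, 4.5)))
  expect_gt(kt$p.value, 0.01)
})

test_that("lengths are streamline arc lengths with the right moments", {
  prof <- measured_profile()
  sp <- solve_speed(prof, recruitment_nucleate(), r = 0.4)
  set.seed(58)
  pop <- run_kmt_simulation(sp, onekin(60, rate = 1), dt = 0.005, t_end = 60,
                            burn_in = 12, snapshot_every = 6)
  ld <- length_distribution(pop)
  # moment oracle on the driving density: mean length = <s_kin - s>
  sg <- seq(0, 4.5, length.out = 2000)
  ng <- profile_density(prof, sg)
  mean_ref <- sum((4.5 - sg) * ng) / sum(ng)
  expect_equal(ld$mean, mean_ref, tolerance = 0.03)
  # all minus ends at the kinetochore: all lengths zero
  init <- data.frame(s = rep(4.5, 20), s_kin = 4.5, kin = 1L)
  pop0 <- run_kmt_simulation(sp, onekin(1, rate = 0), init = init,
                             dt = 0.01, t_end = 0.02, burn_in = 0.01,
                             snapshot_every = 0.01)
  expect_true(all(pop0$snapshots[[1]]$s_kin - pop0$snapshots[[1]]$s
                  <= sp$v_fun(4.5) * 0.02 + 1e-9))
})

test_that("projected orientations follow the streamline geometry", {
  # straight axial track: all projections 1
  ax <- structure(list(points = cbind(seq(0, 4.5, 0.1), 0),
                       s = seq(0, 4.5, 0.1), pole = 1), class = "streamline")
  sp <- solve_speed(measured_profile(), recruitment_nucleate(), r = 0.4)
  set.seed(59)
  pop <- run_kmt_simulation(sp, onekin(20, rate = 1), dt = 0.01, t_end = 14,
                            burn_in = 6, snapshot_every = 4)
  pr <- projected_orientation_distribution(pop, list(ax))
  expect_true(all(abs(pr$projections - 1) < 1e-9))
  # 45-degree straight track: all projections cos(45)
  d45 <- structure(list(points = cbind(seq(0, 4.5, 0.1) / sqrt(2),
                                       seq(0, 4.5, 0.1) / sqrt(2)),
                        s = seq(0, 4.5, 0.1), pole = 1),
                   class = "streamline")
  pr45 <- projected_orientation_distribution(pop, list(d45))
  expect_true(all(abs(pr45$projections - cos(pi / 4)) < 1e-6))
})

test_that("exported reconstructions agree with the orientation module", {
  sc <- spindle_case()
  sls <- Filter(function(s) s$pole == 1, seed_streamlines(sc$field, 1))
  kins <- data.frame(streamline = seq_along(sls),
                     s_kin = vapply(sls, function(s) max(s$s), numeric(1)),
                     rate = 2)
  prof <- measured_profile(max(kins$s_kin))
  sp <- solve_speed(prof, recruitment_nucleate(), r = 0.4,
                    s_kin = max(kins$s_kin))
  set.seed(60)
  pop <- run_kmt_simulation(sp, kins, dt = 0.01, t_end = 14, burn_in = 6,
                            snapshot_every = 4)
  # compare both code paths on the same (final) snapshot
  pop$snapshots <- pop$snapshots[length(pop$snapshots)]
  rec <- population_reconstruction(pop, sls,
                                   poles = cbind(sc$geom$defects, 0))
  segs <- segment_angles(rec, cls = "kmt", segment_len = 0.1)
  proj_segs <- abs(cos(segs$angle))
  pr <- projected_orientation_distribution(pop, sls, segment_len = 0.1)
  # same distribution through both code paths
  kt <- suppressWarnings(stats::ks.test(proj_segs, pr$projections))
  expect_gt(kt$p.value, 0.01)
  expect_equal(mean(proj_segs), mean(pr$projections), tolerance = 0.02)
})

test_that("the time step guard rejects coarse steps", {
  sp <- solve_speed(measured_profile(), recruitment_nucleate(), r = 0.4)
  expect_error(run_kmt_simulation(sp, onekin(5), dt = 1, t_end = 5),
               "dt too coarse")
})
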