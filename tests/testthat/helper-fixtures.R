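# Shared fixtures, built once per test run and memoised in this environment.
# Everything is generated in code; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# circular geometry with a central radial defect: the field is analytically
# radial when the boundary anchoring is radial too
radial_case <- function(spacing = 0.1, tol = 1e-7) {
  memo(sprintf("radial_%g_%g", spacing, tol), {
    geom <- spindle_geometry(a = 3, b = 3,
                             defects = rbind(c(0, 0), c(0, 0)),
                             defect_radius = 0.5)
    list(geom = geom,
         field = solve_director(geom, spacing = spacing, tol = tol,
                                boundary_anchoring = "radial"))
  })
}

# the standard two-pole spindle used across tests
spindle_case <- function() {
  memo("spindle", {
    geom <- spindle_geometry(a = 5.5, b = 3,
                             defects = rbind(c(-4.5, 0), c(4.5, 0)),
                             defect_radius = 0.5)
    field <- solve_director(geom, spacing = 0.1, tol = 1e-6)
    list(geom = geom, field = field)
  })
}

# streamlines toward pole 1 with one kinetochore per streamline at its far
# end, plus a measurement-like minus-end profile and the nucleate flux solution
sim_stack <- function(rate = 8) {
  memo(sprintf("stack_%g", rate), {
    sc <- spindle_case()
    sls <- Filter(function(s) s$pole == 1,
                  seed_streamlines(sc$field, spacing = 0.5))
    kins <- data.frame(streamline = seq_along(sls),
                       s_kin = vapply(sls, function(s) max(s$s), numeric(1)),
                       rate = rate)
    prof <- measured_profile(max(kins$s_kin))
    speed <- solve_speed(prof, recruitment_nucleate(), r = 0.4,
                         s_kin = max(kins$s_kin))
    list(streamlines = sls, kinetochores = kins, profile = prof,
         speed = speed, field = sc$field, geom = sc$geom)
  })
}

# minus-end profile with a Gaussian pole peak (~half the mass, centered
# 1 um from the pole) plus a flat bulk term
measured_profile <- function(s_max = 4.5, amp = 0.3, mu = 1, sigma = 0.45,
                          c0 = 0.15) {
  structure(list(amp = amp, mu = mu, sigma = sigma, c0 = c0,
                 fit_valid = TRUE, s_max = s_max,
                 s = seq(0.125, s_max, by = 0.25), bin = 0.25),
            class = "minus_end_profile")
}

# normalised CDF of a minus-end profile on [0, s_max], for KS tests
profile_cdf <- function(prof, s_max = prof$s_max) {
  sg <- seq(0, s_max, length.out = 4000)
  ng <- profile_density(prof, sg)
  cdf <- cumsum(c(0, diff(sg) * (ng[-1] + ng[-length(ng)]) / 2))
  cdf <- cdf / cdf[length(cdf)]
  stats::approxfun(sg, cdf, rule = 2)
}

# tiny hand-built reconstruction: two KMTs and one free MT around two poles
toy_reconstruction <- function() {
  kin <- data.frame(id = c(1L, 2L), x = c(4, 4.2), y = c(0.5, -0.4),
                    z = c(0, 0.2))
  mts <- list(
    mt_polyline(rbind(c(0.5, 0, 0), c(2, 0.2, 0), c(4, 0.5, 0)),
                plus_end = 3, minus_end = 1, cls = "kmt",
                kinetochore_id = 1L),
    mt_polyline(rbind(c(4.2, -0.4, 0.2), c(2.5, -0.3, 0.1), c(1.2, 0, 0)),
                plus_end = 1, minus_end = 3, cls = "kmt",
                kinetochore_id = 2L),
    mt_polyline(rbind(c(1, 1, 0), c(2, 1.2, 0.3)), cls = "non-kmt"))
  spindle_reconstruction(mts, poles = rbind(c(0, 0, 0), c(9, 0, 0)),
                         kinetochores = kin, meta = list(note = "toy"))
}
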