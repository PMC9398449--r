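#' Discrete stochastic simulation of the KMT lifecycle
#'
#' Simulates kinetochore-microtubule (KMT) birth, minus-end advection and
#' detachment along streamlines. At every time step, new KMTs appear at each
#' kinetochore with Poisson statistics; under nucleate-at-kinetochore
#' recruitment the new minus end starts at the kinetochore (zero length),
#' under capture-from-spindle it is drawn from the recruitment density
#' `j(s)` truncated to the kinetochore's streamline. Minus ends advect
#' toward the pole, `ds/dt = -v(s)`, by explicit Euler; each KMT carries a
#' detachment time drawn from an exponential distribution with rate `r` and
#' is removed when it detaches. Minus ends reaching the pole pin at
#' `s = pin_s` (the defect edge in a geometric spindle).
#'
#' @param speed a `speed_profile` from [solve_speed()] (its `v_fun` drives
#'   the advection and its `r` is the default detachment rate).
#' @param kinetochores data.frame with columns `streamline` (integer label),
#'   `s_kin` (kinetochore arc-length coordinate, um) and optionally `rate`
#'   (nucleation rate per kinetochore, 1/min; default 2).
#' @param model a `recruitment_model` (default nucleate).
#' @param r detachment rate, 1/min (default `speed$r`).
#' @param dt time step, min.
#' @param t_end total simulated time, min.
#' @param burn_in time before the first snapshot, min (default `3 / r`).
#' @param snapshot_every interval between recorded snapshots, min.
#' @param pin_s pole pinning coordinate, um.
#' @param init optional data.frame (`s`, `s_kin`, `kin`) giving an initial
#'   population (born at t = 0 with fresh exponential lifetimes).
#' @return object of class `kmt_population`: `snapshots` (list of
#'   data.frames `t`, `s`, `s_kin`, `kin`, `streamline`, `birth`),
#'   `lifetimes` of all detached KMTs with their `lifetime_births` (KMTs
#'   still attached at `t_end` are censored and not recorded), `count`
#'   (time series of population size), and the configuration.
#' @export
run_kmt_simulation <- function(speed, kinetochores, model = recruitment_nucleate(),
                               r = speed$r, dt = 0.01, t_end = 20,
                               burn_in = 3 / r, snapshot_every = 2 / r,
                               pin_s = 0, init = NULL) {
  stopifnot(inherits(speed, "speed_profile"),
            inherits(model, "recruitment_model"),
            all(c("streamline", "s_kin") %in% names(kinetochores)))
  if (dt > 0.1 / r)
    stop_kfiber("dt too coarse for detachment rate r (need dt << 1/r)")
  rate <- kinetochores$rate %||% rep(2, nrow(kinetochores))
  nk <- nrow(kinetochores)
  f_cap <- model$fraction_captured

  # inverse-CDF sampler for capture initial positions, per kinetochore domain
  draw_capture <- if (f_cap > 0) {
    sg <- seq(0, max(kinetochores$s_kin), length.out = 1024)
    jg <- pmax(model$j(sg), 0)
    if (all(jg <= 0)) stop_kfiber("capture model with vanishing j(s)")
    cdf <- cumtrapz(sg, jg)
    function(s_max) {
      cmax <- stats::approx(sg, cdf, xout = s_max, rule = 2)$y
      u <- stats::runif(length(s_max)) * cmax
      stats::approx(cdf, sg, xout = u, ties = "ordered")$y
    }
  } else NULL

  s <- numeric(0); skin <- numeric(0); kin <- integer(0)
  birth <- numeric(0); detach <- numeric(0)
  if (!is.null(init)) {
    s <- init$s; skin <- init$s_kin; kin <- init$kin
    birth <- rep(0, length(s))
    detach <- stats::rexp(length(s), r)
  }

  n_steps <- ceiling(t_end / dt)
  snap_at <- seq(burn_in, t_end, by = snapshot_every)
  snaps <- vector("list", length(snap_at))
  isnap <- 1L
  lifetimes <- lifetime_births <- numeric(0)
  count <- numeric(n_steps)

  for (step in seq_len(n_steps)) {
    t <- step * dt
    # births
    nb <- stats::rpois(nk, rate * dt)
    if (any(nb > 0)) {
      kin_new <- rep(seq_len(nk), nb)
      skin_new <- kinetochores$s_kin[kin_new]
      if (f_cap > 0) {
        cap <- stats::runif(length(kin_new)) < f_cap
        s_new <- skin_new
        if (any(cap)) s_new[cap] <- draw_capture(skin_new[cap])
      } else s_new <- skin_new
      s <- c(s, s_new); skin <- c(skin, skin_new); kin <- c(kin, kin_new)
      birth <- c(birth, rep(t, length(kin_new)))
      detach <- c(detach, t + stats::rexp(length(kin_new), r))
    }
    # advection
    if (length(s) > 0) {
      s <- pmin(pmax(s - speed$v_fun(s) * dt, pin_s), skin)
      # detachments
      gone <- detach <= t
      if (any(gone)) {
        lifetimes <- c(lifetimes, detach[gone] - birth[gone])
        lifetime_births <- c(lifetime_births, birth[gone])
        keep <- !gone
        s <- s[keep]; skin <- skin[keep]; kin <- kin[keep]
        birth <- birth[keep]; detach <- detach[keep]
      }
    }
    count[step] <- length(s)
    if (isnap <= length(snap_at) && t >= snap_at[isnap]) {
      snaps[[isnap]] <- data.frame(
        t = t, s = s, s_kin = skin, kin = kin,
        streamline = kinetochores$streamline[kin], birth = birth)
      isnap <- isnap + 1L
    }
  }
  structure(list(snapshots = snaps[!vapply(snaps, is.null, logical(1))],
                 lifetimes = lifetimes, lifetime_births = lifetime_births,
                 count = count, dt = dt, r = r, t_end = t_end,
                 burn_in = burn_in, kinetochores = kinetochores,
                 model_kind = model$kind, pin_s = pin_s),
            class = "kmt_population")
}

#' @export
print.kmt_population <- function(x, ...) {
  ns <- length(x$snapshots)
  cat(sprintf("Simulated KMT population (%s recruitment, r = %.3g /min)\n",
              x$model_kind, x$r))
  cat(sprintf("  %d snapshots over %.3g min (burn-in %.3g min); final count %d\n",
              ns, x$t_end, x$burn_in, utils::tail(x$count, 1)))
  cat(sprintf("  %d recorded detachments\n", length(x$lifetimes)))
  invisible(x)
}

#' Pooled steady-state minus-end positions
#'
#' @param pop a `kmt_population`.
#' @return numeric vector of minus-end `s` coordinates pooled over all
#'   post-burn-in snapshots.
#' @export
pooled_minus_ends <- function(pop) {
  unlist(lapply(pop$snapshots, `[[`, "s"), use.names = FALSE)
}

#' KMT length distribution of a simulated population
#'
#' The length of a simulated KMT is the arc length along its streamline
#' trajectory from the minus end to the kinetochore, `s_kin - s`. Lengths
#' are pooled over post-burn-in snapshots.
#'
#' @param pop a `kmt_population`.
#' @param bin histogram bin width, um.
#' @return list with `lengths`, `mids`, `density` and `mean`.
#' @export
length_distribution <- function(pop, bin = 0.25) {
  lens <- unlist(lapply(pop$snapshots, function(d) d$s_kin - d$s),
                 use.names = FALSE)
  breaks <- seq(0, max(lens) + bin, by = bin)
  h <- graphics::hist(lens, breaks = breaks, plot = FALSE)
  list(lengths = lens, mids = h$mids, density = h$density,
       mean = mean(lens))
}

#' Export a simulated population as a spindle reconstruction
#'
#' Materialises each simulated KMT of one snapshot as a polyline along its
#' streamline between the minus end and the kinetochore (plane z = 0), so
#' structural analyses (segment angles, length and orientation
#' distributions) run on simulated and reconstructed spindles through the
#' same code path.
#'
#' @param pop a `kmt_population`.
#' @param streamlines list of `streamline` objects; entry `i` is the path
#'   for kinetochores with `streamline == i`.
#' @param poles 2 x 3 matrix of pole coordinates.
#' @param snapshot which snapshot to export (default: last).
#' @param ds polyline resampling step, um.
#' @return a [spindle_reconstruction()].
#' @export
population_reconstruction <- function(pop, streamlines, poles,
                                      snapshot = length(pop$snapshots),
                                      ds = 0.1) {
  snap <- pop$snapshots[[snapshot]]
  kins <- pop$kinetochores
  kin_xy <- t(vapply(seq_len(nrow(kins)), function(i)
    streamline_point(streamlines[[kins$streamline[i]]], kins$s_kin[i]),
    numeric(2)))
  kin_df <- data.frame(id = seq_len(nrow(kins)),
                       x = kin_xy[, 1], y = kin_xy[, 2], z = 0)
  mts <- vector("list", nrow(snap))
  keep <- logical(nrow(snap))
  for (i in seq_len(nrow(snap))) {
    sl <- streamlines[[snap$streamline[i]]]
    sg <- seq(snap$s[i], snap$s_kin[i], by = ds)
    if (length(sg) < 2 || snap$s_kin[i] - snap$s[i] < 1e-6) next
    if (sg[length(sg)] < snap$s_kin[i]) sg <- c(sg, snap$s_kin[i])
    xy <- streamline_point(sl, sg)
    mts[[i]] <- mt_polyline(cbind(xy, 0), plus_end = length(sg),
                            minus_end = 1, cls = "kmt",
                            kinetochore_id = snap$kin[i])
    keep[i] <- TRUE
  }
  spindle_reconstruction(mts[keep], poles, kin_df,
                         meta = list(source = "kmt_simulation",
                                     t = snap$t[1]))
}

# interpolate point(s) on a streamline at arc-length coordinate s
streamline_point <- function(sl, s) {
  x <- stats::approx(sl$s, sl$points[, 1], xout = s, rule = 2,
                     ties = "ordered")$y
  y <- stats::approx(sl$s, sl$points[, 2], xout = s, rule = 2,
                     ties = "ordered")$y
  cbind(x, y)
}

#' Projected orientation distribution of a simulated population
#'
#' Divides every simulated KMT into short segments along its streamline and
#' reports the distribution of the segments' axial projection fraction (the
#' portion of each segment lying along the spindle axis), as used to compare
#' simulated KMT orientations with reconstructed ones.
#'
#' @param pop a `kmt_population`.
#' @param streamlines list of `streamline` objects (see
#'   [population_reconstruction()]).
#' @param segment_len segment length, um (default 0.1).
#' @param breaks histogram breaks on the projection fraction in `[0, 1]`.
#' @return list with `projections`, `mids`, `density`.
#' @export
projected_orientation_distribution <- function(pop, streamlines,
                                               segment_len = 0.1,
                                               breaks = seq(0, 1, by = 0.05)) {
  proj <- numeric(0)
  for (snap in pop$snapshots) {
    for (i in seq_len(nrow(snap))) {
      if (snap$s_kin[i] - snap$s[i] < segment_len / 2) next
      sl <- streamlines[[snap$streamline[i]]]
      sg <- seq(snap$s[i], snap$s_kin[i], by = segment_len)
      if (length(sg) < 2) next
      xy <- streamline_point(sl, sg)
      d <- diff(xy)
      len <- sqrt(rowSums(d^2))
      ok <- len > 1e-12
      proj <- c(proj, abs(d[ok, 1]) / len[ok])
    }
  }
  proj <- pmin(proj, 1)
  h <- graphics::hist(proj, breaks = breaks, plot = FALSE)
  list(projections = proj, mids = h$mids, density = h$density)
}
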