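#' Simulate a photoconversion experiment in the model spindle
#'
#' Runs the discrete KMT lifecycle (Poisson recruitment, minus-end advection
#' at `v(s)`, pole treadmilling, exponential detachment) to steady state,
#' then marks the tubulin lying under an activation line drawn perpendicular
#' to the spindle axis (in-plane profile `1 / (1 + (d / gamma)^2)^cauchy_p`
#' across the line) and follows the marks: tubulin in a KMT whose minus end
#' is at `s` moves poleward at `v_tub(s)` (equal to `v(s)` in the bulk and
#' to `v(s_p)` in the treadmilling pole region), marks are destroyed when
#' they treadmill past the minus end or when their KMT detaches, and frames
#' are rendered by binning mark weights into pixels. Optionally an immobile
#' fast-turnover non-KMT pool is added under the same activation profile.
#'
#' @param speed a `speed_profile` from [solve_speed()].
#' @param streamlines list of `streamline` objects (the geometric tracks).
#' @param kinetochores data.frame (`streamline`, `s_kin`, optional `rate`)
#'   as in [run_kmt_simulation()].
#' @param activation_s distance of the activation line from the pole along
#'   the spindle axis, um.
#' @param model a `recruitment_model`.
#' @param r detachment rate (1/min; default `speed$r`).
#' @param burn_in simulation time before the line is drawn, min (default 5).
#' @param duration imaging time after activation, min.
#' @param frame_interval seconds between rendered frames.
#' @param dt simulation step, min.
#' @param pixel_size um/px.
#' @param gamma,cauchy_p activation profile parameters: half-width at half
#'   maximum (um; default 1.0, matching the measured activation width) and
#'   shape exponent.
#' @param mark_ds quadrature spacing of marked tubulin along each KMT, um.
#' @param nonkmt_amp amplitude of the immobile non-KMT pool relative to the
#'   KMT tubulin line density (0 disables it).
#' @param nonkmt_rate turnover rate of the non-KMT pool, 1/min.
#' @param background,dark,noise_sd,bleach_rate rendering nuisances as in
#'   [generate_movie()].
#' @param pin_s pole pinning coordinate, um.
#' @param pole which pole (defect index) the activation distance is measured
#'   from; the simulation uses streamlines of that pole.
#' @param seed optional integer seed.
#' @return list with `movie` (a [photoconversion_movie()]) and `truth`
#'   (generating parameters; total marked weight per frame).
#' @export
simulate_photoconversion <- function(speed, streamlines, kinetochores,
                                     activation_s, model = recruitment_nucleate(),
                                     r = speed$r, burn_in = 5, duration = 2.5,
                                     frame_interval = 5, dt = 0.01,
                                     pixel_size = 0.1, gamma = 1.0,
                                     cauchy_p = 1, mark_ds = 0.05,
                                     nonkmt_amp = 0, nonkmt_rate = 1 / 0.26,
                                     background = 0, dark = 0, noise_sd = 0,
                                     bleach_rate = 0, pin_s = 0, pole = 1,
                                     seed = NULL) {
  stopifnot(inherits(speed, "speed_profile"))
  if (!is.null(seed)) set.seed(seed)
  rate <- kinetochores$rate %||% rep(2, nrow(kinetochores))
  nk <- nrow(kinetochores)
  f_cap <- model$fraction_captured
  draw_capture <- if (f_cap > 0) {
    sg <- seq(0, max(kinetochores$s_kin), length.out = 1024)
    jg <- pmax(model$j(sg), 0)
    cdf <- cumtrapz(sg, jg)
    function(s_max) {
      cmax <- stats::approx(sg, cdf, xout = s_max, rule = 2)$y
      u <- stats::runif(length(s_max)) * cmax
      stats::approx(cdf, sg, xout = u, ties = "ordered")$y
    }
  } else NULL

  # geometry / image frame
  allpts <- do.call(rbind, lapply(streamlines, `[[`, "points"))
  x0 <- min(allpts[, 1]) - 1; x1 <- max(allpts[, 1]) + 1
  y0 <- min(allpts[, 2]) - 1; y1 <- max(allpts[, 2]) + 1
  nx <- ceiling((x1 - x0) / pixel_size); ny <- ceiling((y1 - y0) / pixel_size)
  # pole marker positions in image coordinates
  pole_xy <- lapply(streamlines, function(sl) sl$points[1, ])
  pole_ids <- vapply(streamlines, `[[`, numeric(1), "pole")
  p1 <- colMeans(do.call(rbind, pole_xy[pole_ids == pole]))
  p2 <- if (any(pole_ids != pole)) {
    colMeans(do.call(rbind, pole_xy[pole_ids != pole]))
  } else {
    # single-pole streamline set: reflect the pole across the equatorial
    # plane (the streamlines' far endpoints straddle the equator)
    far <- t(vapply(streamlines, function(sl) sl$points[nrow(sl$points), ],
                    numeric(2)))
    2 * colMeans(far) - p1
  }
  axis_u <- (p2 - p1) / sqrt(sum((p2 - p1)^2))
  x_act <- p1 + activation_s * axis_u

  profile_w <- function(xy) {
    d <- (xy[, 1] - x_act[1]) * axis_u[1] + (xy[, 2] - x_act[2]) * axis_u[2]
    1 / (1 + (d / gamma)^2)^cauchy_p
  }

  # ---- lifecycle state ----
  s <- numeric(0); skin <- numeric(0); kin <- integer(0)
  detach <- numeric(0); id <- integer(0); next_id <- 1L
  # marks: positions along streamline, weight, owning KMT id
  mk_s <- numeric(0); mk_w <- numeric(0); mk_id <- integer(0)

  n_frames <- floor(duration * 60 / frame_interval) + 1
  frame_t <- burn_in + (seq_len(n_frames) - 1) * frame_interval / 60
  frames <- vector("list", n_frames)
  total_marked <- numeric(n_frames)
  ifr <- 1L
  activated <- FALSE

  t_end <- burn_in + duration + dt
  n_steps <- ceiling(t_end / dt)
  for (step in seq_len(n_steps)) {
    t <- step * dt
    nb <- stats::rpois(nk, rate * dt)
    if (any(nb > 0)) {
      kn <- rep(seq_len(nk), nb)
      sk <- kinetochores$s_kin[kn]
      sn <- sk
      if (f_cap > 0) {
        cap <- stats::runif(length(kn)) < f_cap
        if (any(cap)) sn[cap] <- pmin(draw_capture(sk[cap]), sk[cap])
      }
      m <- length(kn)
      s <- c(s, sn); skin <- c(skin, sk); kin <- c(kin, kn)
      detach <- c(detach, t + stats::rexp(m, r))
      id <- c(id, next_id:(next_id + m - 1L))
      next_id <- next_id + m
    }
    if (length(s) > 0) {
      u_tub <- speed$v_tub_fun(s)
      s <- pmin(pmax(s - speed$v_fun(s) * dt, pin_s), skin)
      gone <- detach <= t
      if (activated && length(mk_s) > 0) {
        row <- match(mk_id, id)
        mk_s <- mk_s - u_tub[row] * dt
        keep <- !is.na(row) & mk_s >= s[row] & !gone[row]
        mk_s <- mk_s[keep]; mk_w <- mk_w[keep]; mk_id <- mk_id[keep]
      }
      if (any(gone)) {
        keep <- !gone
        s <- s[keep]; skin <- skin[keep]; kin <- kin[keep]
        detach <- detach[keep]; id <- id[keep]
      }
    }
    # activation
    if (!activated && t >= burn_in) {
      activated <- TRUE
      for (i in seq_along(s)) {
        if (skin[i] - s[i] < mark_ds / 2) next
        q <- seq(s[i], skin[i], by = mark_ds)
        xy <- streamline_point(streamlines[[kinetochores$streamline[kin[i]]]], q)
        w <- profile_w(xy) * mark_ds
        sel <- w > 1e-4 * mark_ds
        if (any(sel)) {
          mk_s <- c(mk_s, q[sel]); mk_w <- c(mk_w, w[sel])
          mk_id <- c(mk_id, rep(id[i], sum(sel)))
        }
      }
    }
    # render
    while (ifr <= n_frames && t >= frame_t[ifr] - 1e-9) {
      tf <- t - burn_in
      img <- matrix(0, ny, nx)
      if (length(mk_s) > 0) {
        row <- match(mk_id, id)
        sl_idx <- kinetochores$streamline[kin[row]]
        xy <- matrix(NA_real_, length(mk_s), 2)
        for (sidx in unique(sl_idx)) {
          sel <- sl_idx == sidx
          xy[sel, ] <- streamline_point(streamlines[[sidx]], mk_s[sel])
        }
        cix <- pmin(pmax(ceiling((xy[, 1] - x0) / pixel_size), 1), nx)
        ciy <- pmin(pmax(ceiling((xy[, 2] - y0) / pixel_size), 1), ny)
        pix <- (cix - 1L) * ny + ciy
        acc <- rowsum(mk_w, pix)
        img[as.integer(rownames(acc))] <- acc / pixel_size^2
        total_marked[ifr] <- sum(mk_w)
      }
      if (nonkmt_amp > 0) {
        xc <- x0 + (seq_len(nx) - 0.5) * pixel_size
        yc <- y0 + (seq_len(ny) - 0.5) * pixel_size
        G <- cbind(rep(xc, each = ny), rep(yc, nx))
        wnk <- nonkmt_amp * profile_w(G) * exp(-nonkmt_rate * tf)
        img <- img + matrix(wnk, ny, nx)
      }
      img <- (img + background) * exp(-bleach_rate * tf) + dark
      if (noise_sd > 0)
        img <- img + matrix(stats::rnorm(nx * ny, 0, noise_sd), ny, nx)
      frames[[ifr]] <- img
      ifr <- ifr + 1L
    }
  }
  tracks <- list(matrix(p1 - c(x0, y0), n_frames, 2, byrow = TRUE),
                 matrix(p2 - c(x0, y0), n_frames, 2, byrow = TRUE))
  act_xy <- x_act - c(x0, y0)
  mv <- photoconversion_movie(
    frames, pixel_size, frame_interval, tracks, activation_frame = 1,
    activation_line = rbind(act_xy + c(0, -2), act_xy + c(0, 2)),
    meta = list(source = "kmt_photoconversion_simulation",
                activation_s = activation_s, model = model$kind))
  list(movie = mv,
       truth = list(activation_s = activation_s, r = r,
                    total_marked = total_marked,
                    v_tub_at_line = speed$v_tub_fun(activation_s),
                    model_kind = model$kind))
}
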