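#' Photoconversion movie container
#'
#' @param frames list of equal-sized numeric matrices (rows = y, cols = x),
#'   time-ordered.
#' @param pixel_size micrometres per pixel.
#' @param frame_interval seconds between frames.
#' @param pole_tracks list of two n_frames x 2 matrices of pole positions in
#'   image micrometres.
#' @param activation_frame index of the first post-activation frame.
#' @param activation_line 2 x 2 matrix, endpoints of the drawn line
#'   (micrometres).
#' @param meta optional metadata list.
#' @return object of class `photoconversion_movie`.
#' @export
photoconversion_movie <- function(frames, pixel_size, frame_interval,
                                  pole_tracks, activation_frame = 1,
                                  activation_line = NULL, meta = list()) {
  stopifnot(length(frames) >= 1, pixel_size > 0, frame_interval > 0)
  dm <- dim(frames[[1]])
  if (!all(vapply(frames, function(f) identical(dim(f), dm), logical(1))))
    stop_kfiber("all frames must have the same shape")
  if (length(pole_tracks) != 2 ||
      any(vapply(pole_tracks, nrow, integer(1)) < length(frames)))
    stop_kfiber("pole tracks must cover every frame for both poles")
  structure(list(frames = frames, pixel_size = pixel_size,
                 frame_interval = frame_interval,
                 pole_tracks = pole_tracks,
                 activation_frame = activation_frame,
                 activation_line = activation_line, meta = meta),
            class = "photoconversion_movie")
}

#' @export
print.photoconversion_movie <- function(x, ...) {
  dm <- dim(x$frames[[1]])
  cat(sprintf("Photoconversion movie: %d frames of %d x %d px (%.3g um/px, %.3g s/frame)\n",
              length(x$frames), dm[2], dm[1], x$pixel_size,
              x$frame_interval))
  invisible(x)
}

#' Write / read a photoconversion movie
#'
#' Frames go to a multi-page 32-bit float TIFF (intensities rescaled to
#' `[0, 1]`; the scale factor is kept in the JSON sidecar), pole tracks to a
#' delimited text file, and scalar metadata to JSON, under a common path
#' prefix.
#'
#' @param movie a [photoconversion_movie()].
#' @param path file path prefix.
#' @return `write_movie` returns `path` invisibly; `read_movie` the movie.
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "photoconversion_movie"))
  mx <- max(1e-12, max(vapply(movie$frames, max, numeric(1))))
  mn <- min(0, min(vapply(movie$frames, min, numeric(1))))
  tiff::writeTIFF(lapply(movie$frames, function(f) (f - mn) / (mx - mn)),
                  paste0(path, ".tif"), bits.per.sample = 32)
  tr <- data.frame(frame = seq_len(nrow(movie$pole_tracks[[1]])),
                   p1x = movie$pole_tracks[[1]][, 1],
                   p1y = movie$pole_tracks[[1]][, 2],
                   p2x = movie$pole_tracks[[2]][, 1],
                   p2y = movie$pole_tracks[[2]][, 2])
  utils::write.csv(tr, paste0(path, "_poles.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(pixel_size = movie$pixel_size,
         frame_interval = movie$frame_interval,
         activation_frame = movie$activation_frame,
         activation_line = movie$activation_line,
         scale = c(mn, mx), meta = movie$meta),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_movie
#' @export
read_movie <- function(path) {
  fr <- tiff::readTIFF(paste0(path, ".tif"), all = TRUE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  sc <- side$scale
  fr <- lapply(fr, function(f) f * (sc[2] - sc[1]) + sc[1])
  tr <- utils::read.csv(paste0(path, "_poles.csv"))
  photoconversion_movie(
    fr, side$pixel_size, side$frame_interval,
    pole_tracks = list(as.matrix(tr[, c("p1x", "p1y")]),
                       as.matrix(tr[, c("p2x", "p2y")])),
    activation_frame = side$activation_frame,
    activation_line = if (!is.null(side$activation_line))
      matrix(side$activation_line, ncol = 2) else NULL,
    meta = as.list(side$meta))
}

#' Extract a line profile along the spindle axis
#'
#' Averages intensity across a band around the spindle axis (the line
#' through the two pole markers of the frame) and indexes the result by the
#' axial distance from the chosen pole, binned at pixel resolution.
#'
#' @param movie a [photoconversion_movie()].
#' @param frame frame index.
#' @param band_halfwidth half-width of the averaging band in pixels
#'   (default 15).
#' @param pole which pole distances are measured from (1 or 2).
#' @param radial_halfwidth_um optional tighter band (micrometres) to
#'   restrict the profile to the straight central section of the spindle.
#' @return data.frame `pos` (um from the pole), `intensity`, with the pixel
#'   size in attribute `pixel_size`.
#' @export
extract_line_profile <- function(movie, frame, band_halfwidth = 15,
                                 pole = 1, radial_halfwidth_um = NULL) {
  f <- movie$frames[[frame]]
  p1 <- movie$pole_tracks[[pole]][frame, ]
  p2 <- movie$pole_tracks[[c(2, 1)[pole]]][frame, ]
  ax <- p2 - p1
  L <- sqrt(sum(ax^2))
  if (L <= 0) stop_kfiber("coincident pole markers")
  u <- ax / L
  ny <- nrow(f); nx <- ncol(f)
  px <- movie$pixel_size
  xc <- (col(f) - 0.5) * px
  yc <- (row(f) - 0.5) * px
  a <- (xc - p1[1]) * u[1] + (yc - p1[2]) * u[2]
  b <- -(xc - p1[1]) * u[2] + (yc - p1[2]) * u[1]
  half <- band_halfwidth * px
  if (!is.null(radial_halfwidth_um)) half <- min(half, radial_halfwidth_um)
  sel <- abs(b) <= half
  if (!any(sel)) stop_kfiber("averaging band lies outside the frame")
  bin <- floor(a[sel] / px)
  inten <- as.vector(rowsum(f[sel], bin) / as.vector(table(bin)))
  pos <- (sort(unique(bin)) + 0.5) * px
  out <- data.frame(pos = pos, intensity = inten)
  attr(out, "pixel_size") <- px
  attr(out, "pole_distance") <- L
  out
}

#' Fit a Gaussian to the tracked intensity peak of a line profile
#'
#' Candidate peaks are local maxima above the noise floor (median + 3 MAD of
#' the profile); the candidate nearest to `previous_center` is selected
#' (nearest to the global maximum if no previous center is given) and a
#' 3-parameter Gaussian is fit to the `window` central pixels around it.
#'
#' @param profile output of [extract_line_profile()].
#' @param previous_center center fitted in the previous frame (um), used to
#'   disambiguate multiple peaks.
#' @param window number of central pixels used in the fit (default 5).
#' @return list with `center`, `height`, `sigma` (um), and `ok`; `ok =
#'   FALSE` flags a frame with no usable peak.
#' @export
fit_peak <- function(profile, previous_center = NULL, window = 5) {
  y <- profile$intensity; x <- profile$pos
  n <- length(y)
  if (n < window) return(list(center = NA, height = NA, sigma = NA, ok = FALSE))
  # noise floor: first-difference robust noise estimate, insensitive to
  # broad structure (the peak may span much of the profile)
  noise <- 1.4826 * stats::median(abs(diff(y))) / sqrt(2)
  floor_ <- stats::median(y) + 3 * noise
  im <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  im <- im[y[im] > floor_ + 1e-300]
  if (length(im) == 0) return(list(center = NA, height = NA, sigma = NA, ok = FALSE))
  ref <- previous_center %||% x[which.max(y)]
  ic <- im[which.min(abs(x[im] - ref))]
  hw <- (window - 1) %/% 2
  idx <- max(1, ic - hw):min(n, ic + hw)
  xd <- x[idx]; yd <- y[idx]
  px <- attr(profile, "pixel_size") %||% diff(x[1:2])
  fit <- tryCatch({
    f <- minpack.lm::nlsLM(yd ~ A * exp(-(xd - mu)^2 / (2 * sg^2)),
                           start = list(A = y[ic], mu = x[ic], sg = 1.2 * px),
                           lower = c(0, min(xd) - px, px / 10),
                           upper = c(Inf, max(xd) + px, 50 * px),
                           control = minpack.lm::nls.lm.control(maxiter = 100))
    co <- stats::coef(f)
    list(center = unname(co["mu"]), height = unname(co["A"]),
         sigma = unname(co["sg"]), ok = TRUE)
  }, error = function(e) NULL)
  if (is.null(fit)) {
    # log-parabola fallback (exact for a noiseless Gaussian)
    yy <- pmax(yd, 1e-12)
    q <- stats::lm(log(yy) ~ xd + I(xd^2))$coefficients
    if (!is.finite(q[3]) || q[3] >= 0)
      return(list(center = NA, height = NA, sigma = NA, ok = FALSE))
    mu <- -q[2] / (2 * q[3]); sg <- sqrt(-1 / (2 * q[3]))
    fit <- list(center = unname(mu), height = unname(exp(q[1] - q[2]^2 / (4 * q[3]))),
                sigma = unname(sg), ok = TRUE)
  }
  fit
}

#' Bleach- and background-correct peak heights
#'
#' `corrected(t) = (main(t) - opposite(t)) / bleach(t)`: the height of a
#' Gaussian fit on the opposite side of the spindle estimates the unconverted
#' background, and the bleaching calibration curve (normalised to 1 at the
#' first corrected frame, itself dark-level corrected upstream) removes
#' acquisition bleaching.
#'
#' @param heights main peak heights per frame.
#' @param opposite opposite-side fit heights (same length; use 0 when no
#'   background reference exists).
#' @param bleach bleaching calibration values per frame (must be positive).
#' @return corrected heights.
#' @export
correct_height <- function(heights, opposite = 0, bleach = 1) {
  opposite <- rep_len(opposite, length(heights))
  bleach <- rep_len(bleach, length(heights))
  if (any(bleach <= 0)) stop_kfiber("bleach calibration must be positive")
  (heights - opposite) / bleach
}

#' Fit a dual-exponential turnover decay
#'
#' Fits `A_s exp(-k_s t) + A_f exp(-k_f t)` to bleach-corrected peak heights
#' by nonlinear least squares. The fast and slow rates are kept identifiable
#' by the parametrisation `k_f = rho * k_s, rho >= 2`. Initialisation: a
#' log-linear fit to the late tail seeds the slow component and the early
#' residual seeds the fast one.
#'
#' @param time time since activation, minutes.
#' @param heights corrected peak heights.
#' @return object of class `turnover_fit`: amplitudes, rates (1/min),
#'   `lifetimes` (min), `slow_fraction = A_s / (A_s + A_f)`, covariance,
#'   and `flagged` (boundary-stuck or non-converged fits, or fewer than 10
#'   points).
#' @export
fit_turnover <- function(time, heights) {
  ok <- is.finite(time) & is.finite(heights)
  time <- time[ok]; heights <- heights[ok]
  if (length(time) < 6 || max(heights) <= 0)
    return(structure(list(flagged = TRUE, converged = FALSE),
                     class = "turnover_fit"))
  flagged <- length(time) < 10
  tail_i <- time >= stats::quantile(time, 0.6)
  ht <- pmax(heights, 1e-9 * max(heights))
  lf <- stats::lm(log(ht[tail_i]) ~ time[tail_i])
  ks0 <- max(1e-3, -unname(lf$coefficients[2]))
  As0 <- exp(unname(lf$coefficients[1]))
  resid0 <- pmax(heights - As0 * exp(-ks0 * time), 1e-9 * max(heights))
  early <- time <= stats::quantile(time, 0.3)
  kf0 <- if (sum(early) >= 3) {
    ef <- stats::lm(log(resid0[early]) ~ time[early])
    max(2.5 * ks0, -ef$coefficients[2])
  } else 10 * ks0
  Af0 <- max(heights[1] - As0, 0.1 * As0)

  fit <- tryCatch(
    minpack.lm::nlsLM(
      heights ~ As * exp(-ks * time) + Af * exp(-ks * rho * time),
      start = list(As = As0, ks = ks0, Af = Af0,
                   rho = min(max(kf0 / ks0, 2.1), 500)),
      lower = c(0, 1e-4, 0, 2), upper = c(Inf, 50, Inf, 1000),
      control = minpack.lm::nls.lm.control(maxiter = 400)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # degenerate (effectively single-exponential) traces make the dual
    # model singular; fall back to the one-component fit
    single <- tryCatch(
      minpack.lm::nlsLM(heights ~ As * exp(-ks * time),
                        start = list(As = As0, ks = ks0),
                        lower = c(0, 1e-4),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(single))
      return(structure(list(flagged = TRUE, converged = FALSE),
                       class = "turnover_fit"))
    co <- stats::coef(single)
    return(structure(list(
      A_slow = unname(co["As"]), A_fast = 0,
      k_slow = unname(co["ks"]), k_fast = NA_real_,
      lifetimes = c(slow = 1 / unname(co["ks"]), fast = NA),
      slow_fraction = 1,
      vcov = NULL, flagged = flagged, converged = TRUE,
      degenerate = TRUE, fit = single), class = "turnover_fit"))
  }
  co <- stats::coef(fit)
  k_slow <- unname(co["ks"]); k_fast <- unname(co["ks"] * co["rho"])
  at_bound <- co["rho"] < 2.001 || co["ks"] < 2e-4
  structure(list(
    A_slow = unname(co["As"]), A_fast = unname(co["Af"]),
    k_slow = k_slow, k_fast = k_fast,
    lifetimes = c(slow = 1 / k_slow, fast = 1 / k_fast),
    slow_fraction = unname(co["As"] / (co["As"] + co["Af"])),
    vcov = tryCatch(stats::vcov(fit), error = function(e) NULL),
    flagged = flagged || at_bound, converged = TRUE, fit = fit),
    class = "turnover_fit")
}

#' @export
print.turnover_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Turnover fit: did not converge\n")
    return(invisible(x))
  }
  cat("Dual-exponential turnover fit\n")
  cat(sprintf("  slow: A = %.3g, k = %.3g /min (lifetime %.2f min)\n",
              x$A_slow, x$k_slow, 1 / x$k_slow))
  cat(sprintf("  fast: A = %.3g, k = %.3g /min (lifetime %.2f min)\n",
              x$A_fast, x$k_fast, 1 / x$k_fast))
  cat(sprintf("  slow fraction: %.3f%s\n", x$slow_fraction,
              if (x$flagged) "  [flagged]" else ""))
  invisible(x)
}

#' @export
coef.turnover_fit <- function(object, ...) {
  c(A_slow = object$A_slow, k_slow = object$k_slow,
    A_fast = object$A_fast, k_fast = object$k_fast)
}

#' Fit the line speed from tracked peak centers
#'
#' Ordinary least-squares fit of the peak center (distance from the pole)
#' against time. Poleward motion (decreasing distance) is reported as a
#' positive speed.
#'
#' @param time minutes since activation.
#' @param centers peak centers, micrometres from the pole.
#' @return object of class `line_speed_fit`: `speed` (um/min, poleward
#'   positive), `se`, `initial_position` (um, the fitted center at t = 0),
#'   `n`, `flagged` (fewer than 5 valid frames).
#' @export
fit_speed <- function(time, centers) {
  ok <- is.finite(time) & is.finite(centers)
  n <- sum(ok)
  if (n < 2)
    return(structure(list(speed = NA, se = NA, initial_position = NA,
                          n = n, flagged = TRUE), class = "line_speed_fit"))
  fit <- stats::lm(centers[ok] ~ time[ok])
  # noiseless traces fit exactly; the SE summary warning is immaterial
  sm <- suppressWarnings(summary(fit)$coefficients)
  structure(list(speed = -unname(sm[2, 1]), se = unname(sm[2, 2]),
                 initial_position = unname(sm[1, 1]), n = n,
                 flagged = n < 5, lm = fit),
            class = "line_speed_fit")
}

#' @export
print.line_speed_fit <- function(x, ...) {
  cat(sprintf("Line speed: %.3g +/- %.3g um/min poleward (n = %d frames)%s\n",
              x$speed, x$se, x$n, if (x$flagged) "  [flagged]" else ""))
  cat(sprintf("  initial position: %.3g um from the pole\n",
              x$initial_position))
  invisible(x)
}

#' Analyse a photoconversion movie
#'
#' Runs the full analysis chain: per-frame line profile and tracked Gaussian
#' peak, opposite-side background fit, bleach correction, linear fit of the
#' peak center (line speed) and dual-exponential fit of the corrected peak
#' height (turnover).
#'
#' @param movie a [photoconversion_movie()].
#' @param bleach bleaching calibration: a function of time (minutes) or a
#'   per-frame vector, normalised to 1 at activation. Default: derived from
#'   `bleach_rate`.
#' @param bleach_rate exponential bleaching rate (1/min) used when no
#'   calibration curve is given (default 0, no bleaching).
#' @param band_halfwidth,pole,radial_halfwidth_um passed to
#'   [extract_line_profile()].
#' @param window passed to [fit_peak()].
#' @return list with `speed` (a `line_speed_fit`), `turnover` (a
#'   `turnover_fit`), and the per-frame `track` table.
#' @export
analyze_movie <- function(movie, bleach = NULL, bleach_rate = 0,
                          band_halfwidth = 15, pole = 1,
                          radial_halfwidth_um = NULL, window = 5) {
  fr0 <- movie$activation_frame
  frames <- fr0:length(movie$frames)
  t_min <- (frames - fr0) * movie$frame_interval / 60
  ctr <- hgt <- opp <- rep(NA_real_, length(frames))
  prev <- NULL
  if (!is.null(movie$activation_line)) {
    p1 <- movie$pole_tracks[[pole]][fr0, ]
    p2 <- movie$pole_tracks[[c(2, 1)[pole]]][fr0, ]
    u <- (p2 - p1) / sqrt(sum((p2 - p1)^2))
    mid <- colMeans(movie$activation_line)
    prev <- sum((mid - p1) * u)
  }
  prev_opp <- NULL
  for (i in seq_along(frames)) {
    prof <- extract_line_profile(movie, frames[i], band_halfwidth, pole,
                                 radial_halfwidth_um)
    pk <- fit_peak(prof, prev, window)
    if (pk$ok) {
      ctr[i] <- pk$center; hgt[i] <- pk$height
      prev <- pk$center
    }
    # background: Gaussian fit at the mirrored position on the other
    # half-spindle
    L <- attr(prof, "pole_distance")
    mirror <- L - (prev %||% (L / 2))
    opp_fit <- fit_peak(prof, prev_opp %||% mirror, window)
    opp[i] <- if (opp_fit$ok && abs(opp_fit$center - mirror) < L / 4) {
      prev_opp <- opp_fit$center
      opp_fit$height
    } else stats::median(prof$intensity)
  }
  bl <- if (is.function(bleach)) bleach(t_min)
        else if (!is.null(bleach)) rep_len(bleach, length(t_min))
        else exp(-bleach_rate * t_min)
  corr <- correct_height(hgt, opp, bl)
  list(speed = fit_speed(t_min, ctr),
       turnover = fit_turnover(t_min, corr),
       track = data.frame(frame = frames, t_min = t_min, center = ctr,
                          height = hgt, opposite = opp, corrected = corr))
}
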