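#' Configuration for the synthetic spindle generator
#'
#' Defines the study conditions emulated by [generate_spindle()]: a spindle
#' geometry, KMT and non-KMT counts, the KMT minus-end density along
#' streamlines (Gaussian pole peak + bulk constant), the non-KMT length
#' scale, and the angular noise about the director field.
#'
#' @param geometry a [spindle_geometry()]; the default (semi-axes 5.5 x 3 um,
#'   poles 9 um apart) matches a metaphase HeLa spindle.
#' @param n_kmts,n_nonkmts microtubule counts.
#' @param n_kinetochores number of kinetochores; KMTs are distributed over
#'   them round-robin.
#' @param peak_amp,peak_center,peak_sd,bulk_const parameters of the
#'   (unnormalised) minus-end density
#'   `n(s) = peak_amp * exp(-(s - peak_center)^2 / (2 peak_sd^2)) +
#'   bulk_const`; the defaults put roughly half the minus ends in a peak
#'   ~1 um from the pole.
#' @param kappa von Mises concentration of the angular noise applied in the
#'   doubled-angle (nematic) representation; `Inf` = perfectly aligned,
#'   0 = planar-isotropic. The default targets a planar order parameter
#'   `S = I1(kappa)/I0(kappa) ~ 0.86`.
#' @param nonkmt_mean_length mean of the exponential non-KMT length
#'   distribution, um.
#' @param dimension `"3d"` (azimuthally rotated planes) or `"2d"` (all MTs
#'   in the central plane).
#' @param seed integer seed; a fixed seed gives bit-reproducible output.
#' @return list of class `synthetic_spindle_config`.
#' @export
synthetic_spindle_config <- function(geometry = spindle_geometry(5.5, 3),
                                     n_kmts = 400, n_nonkmts = 800,
                                     n_kinetochores = 40,
                                     peak_amp = 0.30, peak_center = 1.0,
                                     peak_sd = 0.5, bulk_const = 0.12,
                                     kappa = 4, nonkmt_mean_length = 2.0,
                                     dimension = c("3d", "2d"),
                                     seed = 1L) {
  dimension <- match.arg(dimension)
  stopifnot(n_kmts >= 0, n_nonkmts >= 0, peak_sd > 0, kappa >= 0,
            peak_amp >= 0, bulk_const >= 0, nonkmt_mean_length > 0)
  structure(list(geometry = geometry, n_kmts = n_kmts,
                 n_nonkmts = n_nonkmts, n_kinetochores = n_kinetochores,
                 peak_amp = peak_amp, peak_center = peak_center,
                 peak_sd = peak_sd, bulk_const = bulk_const,
                 kappa = kappa, nonkmt_mean_length = nonkmt_mean_length,
                 dimension = dimension, seed = as.integer(seed)),
            class = "synthetic_spindle_config")
}

#' Generate a synthetic spindle reconstruction with known ground truth
#'
#' Lays microtubules along streamlines of the geometry's director field with
#' von Mises angular noise (in the doubled-angle representation, respecting
#' the headless symmetry). Kinetochores are placed near the metaphase plate;
#' each KMT's minus-end arc-length position is drawn from the configured
#' density `n(s)` truncated to its streamline. Non-KMT minus ends are placed
#' uniformly in the spindle, with exponential lengths, growing away from the
#' nearer pole along the director.
#'
#' @param cfg a [synthetic_spindle_config()].
#' @param field optional pre-solved [solve_director()] field for
#'   `cfg$geometry` (solved at 0.1 um spacing if omitted).
#' @return list with `reconstruction` (a [spindle_reconstruction()]) and
#'   `truth`: the generating `kappa`, target planar order parameter
#'   `S_planar = I1(kappa)/I0(kappa)`, per-KMT `s_minus`, `s_kin`,
#'   streamline assignments, the density parameters, non-KMT lengths, the
#'   director `field` and the kinetochore streamlines.
#' @export
generate_spindle <- function(cfg, field = NULL) {
  stopifnot(inherits(cfg, "synthetic_spindle_config"))
  set.seed(cfg$seed)
  geom <- cfg$geometry
  field <- field %||% solve_director(geom, spacing = 0.1, tol = 1e-6)

  # kinetochores near the metaphase plate, alternating sides, radial
  # offsets within the streamline-safe band
  nk <- cfg$n_kinetochores
  side <- rep(c(-1, 1), length.out = nk)
  kx <- side * stats::runif(nk, 0.2, 0.6)
  kw <- stats::runif(nk, 0.1, 0.7 * geom$b)   # radial offset (unsigned)
  kphi <- if (cfg$dimension == "3d") stats::runif(nk, 0, 2 * pi) else
    sample(c(0, pi), nk, replace = TRUE)
  pole_of <- ifelse(side < 0, 1L, 2L)

  # per-kinetochore streamline in its meridional plane
  sls <- vector("list", nk)
  s_kin <- numeric(nk)
  for (k in seq_len(nk)) {
    sls[[k]] <- trace_streamline(field, c(geom$center[1] + kx[k],
                                          geom$center[2] + kw[k]),
                                 pole = pole_of[k])
    s_kin[k] <- max(sls[[k]]$s)
  }

  nfun <- function(s) cfg$peak_amp *
    exp(-(s - cfg$peak_center)^2 / (2 * cfg$peak_sd^2)) + cfg$bulk_const

  kin_assign <- rep(seq_len(nk), length.out = cfg$n_kmts)
  s_minus <- vapply(kin_assign, function(k)
    sample_density(nfun, 0, s_kin[k]), numeric(1))

  mts <- vector("list", cfg$n_kmts + cfg$n_nonkmts)
  for (i in seq_len(cfg$n_kmts)) {
    k <- kin_assign[i]
    mts[[i]] <- noisy_mt_along_streamline(sls[[k]], s_minus[i], s_kin[k],
                                          cfg$kappa, kphi[k], geom)
  }

  # non-KMTs: minus end uniform in the (meridional half-plane) spindle,
  # exponential length, growing away from the nearer pole
  nonkmt_len <- stats::rexp(cfg$n_nonkmts, 1 / cfg$nonkmt_mean_length) + 0.1
  for (i in seq_len(cfg$n_nonkmts)) {
    repeat {
      p <- c(stats::runif(1, geom$center[1] - geom$a, geom$center[1] + geom$a),
             stats::runif(1, geom$center[2] + 0.02,
                          geom$center[2] + 0.9 * geom$b))
      rel <- ((p[1] - geom$center[1]) / geom$a)^2 +
        ((p[2] - geom$center[2]) / geom$b)^2
      if (rel < 0.8) break
    }
    phi <- if (cfg$dimension == "3d") stats::runif(1, 0, 2 * pi) else
      sample(c(0, pi), 1)
    mts[[cfg$n_kmts + i]] <-
      noisy_mt_walk(field, p, nonkmt_len[i], cfg$kappa, phi, geom)
  }

  # 3D embedding of kinetochores
  kin3 <- t(vapply(seq_len(nk), function(k) {
    xy <- streamline_point(sls[[k]], s_kin[k])
    c(xy[1], xy[2] * cos(kphi[k]), xy[2] * sin(kphi[k]))
  }, numeric(3)))
  kin_df <- data.frame(id = seq_len(nk), x = kin3[, 1], y = kin3[, 2],
                       z = kin3[, 3])
  for (i in seq_len(cfg$n_kmts))
    mts[[i]]$kinetochore_id <- kin_assign[i]

  poles <- cbind(geom$defects, 0)
  rec <- spindle_reconstruction(mts, poles, kin_df,
                                meta = list(source = "synthetic",
                                            seed = cfg$seed))
  truth <- list(kappa = cfg$kappa,
                S_planar = if (is.infinite(cfg$kappa)) 1 else
                  besselI(cfg$kappa, 1) / besselI(cfg$kappa, 0),
                s_minus = s_minus, s_kin = s_kin[kin_assign],
                kin_assign = kin_assign, kin_s_kin = s_kin,
                pole_of = pole_of,
                density = list(peak_amp = cfg$peak_amp,
                               peak_center = cfg$peak_center,
                               peak_sd = cfg$peak_sd,
                               bulk_const = cfg$bulk_const),
                nonkmt_lengths = nonkmt_len,
                field = field, streamlines = sls, config = cfg)
  list(reconstruction = rec, truth = truth)
}

# rejection sampler from an arbitrary positive density on [lo, hi]
sample_density <- function(f, lo, hi) {
  gx <- seq(lo, hi, length.out = 256)
  fmax <- max(f(gx)) * 1.05
  repeat {
    x <- stats::runif(1, lo, hi)
    if (stats::runif(1) * fmax <= f(x)) return(x)
  }
}

# KMT polyline: walk along a streamline from s_minus to s_kin with von
# Mises angular noise, then rotate the meridional plane by phi about the
# spindle axis
noisy_mt_along_streamline <- function(sl, s_minus, s_kin, kappa, phi, geom,
                                      h = 0.1) {
  sg <- seq(s_minus, s_kin, by = h)
  if (sg[length(sg)] < s_kin) sg <- c(sg, s_kin)
  base <- streamline_point(sl, sg)
  n <- nrow(base)
  if (n < 2) {
    sg <- c(s_minus, s_kin)
    base <- streamline_point(sl, sg)
    n <- 2
  }
  d <- base[-1, , drop = FALSE] - base[-n, , drop = FALSE]
  len <- sqrt(rowSums(d^2))
  ang <- atan2(d[, 2], d[, 1])
  noise <- rvonmises(n - 1, 0, kappa) / 2
  ang <- ang + noise
  pts <- cbind(base[1, 1] + cumsum(c(0, len * cos(ang))),
               base[1, 2] + cumsum(c(0, len * sin(ang))))
  p3 <- cbind(pts[, 1], pts[, 2] * cos(phi), pts[, 2] * sin(phi))
  mt_polyline(p3, plus_end = n, minus_end = 1, cls = "kmt",
              kinetochore_id = 1L)   # id patched by the caller
}

# non-KMT polyline: noisy walk from the minus end along the director,
# oriented away from the nearer pole, truncated at the ellipse
noisy_mt_walk <- function(field, p0, length_um, kappa, phi, geom, h = 0.1) {
  n_steps <- max(1, ceiling(length_um / h))
  pts <- matrix(NA_real_, n_steps + 1, 2)
  pts[1, ] <- p0
  d2 <- rowSums((geom$defects - rep(p0, each = 2))^2)
  away <- p0 - geom$defects[which.min(d2), ]
  prev <- away / sqrt(sum(away^2))
  p <- p0
  n <- 1L
  for (j in seq_len(n_steps)) {
    th <- director_angle(field, p) + rvonmises(1, 0, kappa) / 2
    dir <- c(cos(th), sin(th))
    if (sum(dir * prev) < 0) dir <- -dir
    pn <- p + h * dir
    if (!inside_ellipse(pn, geom)) break
    p <- pn; prev <- dir; n <- n + 1L
    pts[n, ] <- p
  }
  if (n < 2) {   # ensure a valid 2-point polyline
    pts[2, ] <- p0 + (h / 2) * prev
    if (!inside_ellipse(pts[2, ], geom)) pts[2, ] <- p0 - (h / 2) * prev
    n <- 2L
  }
  pts <- pts[seq_len(n), , drop = FALSE]
  p3 <- cbind(pts[, 1], pts[, 2] * cos(phi), pts[, 2] * sin(phi))
  mt_polyline(p3, plus_end = n, minus_end = 1, cls = "non-kmt")
}

#' Configuration for the synthetic photoconversion movie generator
#'
#' @param v speed of the marked line as a function of distance from pole 1
#'   (um/min); either a function of `s` or a single number. The default,
#'   `v(s) = 0.4 * pmax(s, 1.5)`, is the bulk flux-balance speed with a
#'   treadmilling pole region.
#' @param slow_fraction,k_slow,k_fast dual-exponential turnover parameters:
#'   amplitude fraction of the slow (KMT) pool and the two rates (1/min).
#'   Defaults match two-photon photoconversion measurements in HeLa
#'   (slow fraction 0.26; lifetimes 2.8 min and 0.26 min).
#' @param bleach_rate acquisition bleaching rate, 1/min.
#' @param gamma,cauchy_p activation line profile
#'   `1 / (1 + (x / gamma)^2)^cauchy_p` across the line (um); the exponent
#'   generalises the Cauchy shape.
#' @param amp peak amplitude at activation (arbitrary units).
#' @param background spindle autofluorescence level (bleaches with the
#'   signal); `dark` camera offset (does not bleach).
#' @param noise_sd additive Gaussian noise.
#' @param line_s0 initial line distance from pole 1, um.
#' @param pixel_size um/px; `frame_interval` s; `duration` min.
#' @param pole_pole pole-pole distance, um; `height` image height, um.
#' @param seed integer seed.
#' @return list of class `synthetic_movie_config`.
#' @export
synthetic_movie_config <- function(v = function(s) 0.4 * pmax(s, 1.5),
                                   slow_fraction = 0.26,
                                   k_slow = 1 / 2.8, k_fast = 1 / 0.26,
                                   bleach_rate = 0.1,
                                   gamma = 0.3, cauchy_p = 1, amp = 1,
                                   background = 0.15, dark = 0.02,
                                   noise_sd = 0.02, line_s0 = 3,
                                   pixel_size = 0.1, frame_interval = 5,
                                   duration = 2.5, pole_pole = 9,
                                   height = 7, seed = 1L) {
  if (is.numeric(v)) { v0 <- v; v <- function(s) rep(v0, length(s)) }
  stopifnot(k_slow > 0, k_fast > 0, slow_fraction >= 0, slow_fraction <= 1,
            gamma > 0, pixel_size > 0, frame_interval > 0)
  structure(list(v = v, slow_fraction = slow_fraction, k_slow = k_slow,
                 k_fast = k_fast, bleach_rate = bleach_rate, gamma = gamma,
                 cauchy_p = cauchy_p, amp = amp, background = background,
                 dark = dark, noise_sd = noise_sd, line_s0 = line_s0,
                 pixel_size = pixel_size, frame_interval = frame_interval,
                 duration = duration, pole_pole = pole_pole,
                 height = height, seed = as.integer(seed)),
            class = "synthetic_movie_config")
}

#' Generate a synthetic photoconversion movie with known ground truth
#'
#' Renders a photoconverted line with the configured activation profile that
#' advects at the prescribed speed field `v(s)`, decays as the configured
#' dual exponential, bleaches, and sits on a bleaching spindle-shaped
#' background plus camera dark level and Gaussian noise.
#'
#' @param cfg a [synthetic_movie_config()].
#' @return list with `movie` (a [photoconversion_movie()]) and `truth`
#'   (per-frame true peak center/amplitude and the generating parameters).
#' @export
generate_movie <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_movie_config"))
  set.seed(cfg$seed)
  px <- cfg$pixel_size
  margin <- 1.5
  width <- cfg$pole_pole + 2 * margin
  nx <- round(width / px); ny <- round(cfg$height / px)
  pole1 <- c(margin, cfg$height / 2)
  pole2 <- c(margin + cfg$pole_pole, cfg$height / 2)
  n_frames <- floor(cfg$duration * 60 / cfg$frame_interval) + 1
  t_min <- (seq_len(n_frames) - 1) * cfg$frame_interval / 60

  # advect the line center: ds/dt = -v(s), integrated at fine steps
  s0 <- cfg$line_s0
  centers <- numeric(n_frames)
  centers[1] <- s0
  dt <- 0.002
  s <- s0; tcur <- 0
  for (i in 2:n_frames) {
    while (tcur < t_min[i] - 1e-12) {
      s <- max(s - cfg$v(s) * dt, 0)
      tcur <- tcur + dt
    }
    centers[i] <- s
  }
  amp_t <- cfg$amp * (cfg$slow_fraction * exp(-cfg$k_slow * t_min) +
                        (1 - cfg$slow_fraction) * exp(-cfg$k_fast * t_min))
  bleach_t <- exp(-cfg$bleach_rate * t_min)

  a <- cfg$pole_pole / 2 + 0.8; b <- cfg$height / 2 - 0.6
  xc <- (seq_len(nx) - 0.5) * px
  yc <- (seq_len(ny) - 0.5) * px
  cx <- (pole1[1] + pole2[1]) / 2; cy <- pole1[2]
  inside <- outer(yc, xc, function(y, x)
    ((x - cx) / a)^2 + ((y - cy) / b)^2 <= 1)

  frames <- vector("list", n_frames)
  for (i in seq_len(n_frames)) {
    x_line <- pole1[1] + centers[i]
    prof <- 1 / (1 + ((xc - x_line) / cfg$gamma)^2)^cfg$cauchy_p
    stripe <- matrix(prof, ny, nx, byrow = TRUE)
    f <- (cfg$background + amp_t[i] * stripe) * bleach_t[i]
    f[!inside] <- 0
    f <- f + cfg$dark
    if (cfg$noise_sd > 0)
      f <- f + matrix(stats::rnorm(nx * ny, 0, cfg$noise_sd), ny, nx)
    frames[[i]] <- f
  }
  tracks <- list(matrix(pole1, n_frames, 2, byrow = TRUE),
                 matrix(pole2, n_frames, 2, byrow = TRUE))
  mv <- photoconversion_movie(
    frames, px, cfg$frame_interval, tracks, activation_frame = 1,
    activation_line = rbind(c(pole1[1] + s0, cy - b), c(pole1[1] + s0, cy + b)),
    meta = list(source = "synthetic", seed = cfg$seed))
  list(movie = mv,
       truth = list(centers = centers, amplitude = amp_t,
                    bleach = bleach_t, t_min = t_min, config = cfg))
}

#' Generate a synthetic orientation map from a director field
#'
#' Per-pixel angle = field angle + wrapped Gaussian noise; the weight plane
#' is a microtubule-density proxy (1 inside the spindle, 0 outside).
#'
#' @param field a [solve_director()] result.
#' @param noise_sd wrapped Gaussian angular noise, radians.
#' @param seed integer seed.
#' @return object of class `orientation_map` (grid axes `x`, `y`, `angle`,
#'   `weight`, `poles`, `spacing`).
#' @export
generate_orientation_map <- function(field, noise_sd = 0, seed = 1L) {
  set.seed(seed)
  ang <- field$theta
  def <- field$role != "outside"
  if (noise_sd > 0)
    ang[def] <- wrap_nematic(ang[def] + stats::rnorm(sum(def), 0, noise_sd))
  w <- matrix(0, nrow(ang), ncol(ang))
  w[def] <- 1
  structure(list(x = field$x, y = field$y, angle = ang, weight = w,
                 poles = field$geometry$defects,
                 spacing = field$spacing),
            class = "orientation_map")
}

#' @export
print.orientation_map <- function(x, ...) {
  cat(sprintf("Orientation map: %d x %d px (%.3g um), %d weighted pixels\n",
              length(x$x), length(x$y), x$spacing, sum(x$weight > 0)))
  invisible(x)
}
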