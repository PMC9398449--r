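#' Resample microtubules into short segments and compute projected angles
#'
#' Each microtubule polyline is resampled at equal arc-length steps; each
#' resulting segment contributes its midpoint and its orientation angle in
#' the projected XY (spindle axis x radial axis) plane, modulo pi. The
#' reconstruction is first moved into the spindle frame: origin at the
#' midpoint of the poles, x axis along the pole-pole line.
#'
#' @param rec a [spindle_reconstruction()].
#' @param cls which MTs to use: `"all"`, `"kmt"` or `"non-kmt"`.
#' @param segment_len segment length in micrometres (default 0.1).
#' @param rotate extra rotation angle about the spindle axis (radians)
#'   applied to the 3D points before projection.
#' @return data.frame with columns `x`, `y` (projected midpoint), `angle`
#'   (radians in `(-pi/2, pi/2]`), `len` (segment length) and `mt`.
#' @export
segment_angles <- function(rec, cls = c("all", "kmt", "non-kmt"),
                           segment_len = 0.1, rotate = 0) {
  cls <- match.arg(cls)
  stopifnot(segment_len > 0)
  basis <- spindle_frame(rec$poles)
  keep <- vapply(rec$mts, function(m) cls == "all" || m$cls == cls,
                 logical(1))
  out <- vector("list", sum(keep))
  j <- 0L
  for (i in which(keep)) {
    p <- rec$mts[[i]]$points
    q <- sweep(p, 2, basis$origin) %*% basis$R   # rows: (x, y, z) spindle frame
    if (rotate != 0) {
      yz <- q[, 2:3] %*% rbind(c(cos(rotate), sin(rotate)),
                               c(-sin(rotate), cos(rotate)))
      q[, 2:3] <- yz
    }
    r <- resample_polyline(q, segment_len)
    if (nrow(r) < 2) next
    n <- nrow(r)
    d <- r[-1, , drop = FALSE] - r[-n, , drop = FALSE]
    len2d <- sqrt(d[, 1]^2 + d[, 2]^2)
    ok <- len2d > 1e-12
    if (!any(ok)) next
    mid <- (r[-1, , drop = FALSE] + r[-n, , drop = FALSE]) / 2
    j <- j + 1L
    out[[j]] <- data.frame(
      x = mid[ok, 1], y = mid[ok, 2],
      angle = wrap_nematic(atan2(d[ok, 2], d[ok, 1])),
      len = sqrt(rowSums(d[ok, , drop = FALSE]^2)), mt = i)
  }
  if (j == 0L)
    return(data.frame(x = numeric(0), y = numeric(0), angle = numeric(0),
                      len = numeric(0), mt = integer(0)))
  do.call(rbind, out[seq_len(j)])
}

# orthonormal spindle frame: x along pole 1 -> pole 2, origin at midpoint
spindle_frame <- function(poles) {
  origin <- colMeans(poles)
  ex <- poles[2, ] - poles[1, ]
  ex <- ex / sqrt(sum(ex^2))
  # keep the projection plane as close to the lab XY plane as possible
  ref <- if (abs(ex[2]) < 0.9) c(0, 1, 0) else c(0, 0, 1)
  ey <- ref - sum(ref * ex) * ex
  ey <- ey / sqrt(sum(ey^2))
  ez <- c(ex[2] * ey[3] - ex[3] * ey[2],
          ex[3] * ey[1] - ex[1] * ey[3],
          ex[1] * ey[2] - ex[2] * ey[1])
  list(origin = origin, R = cbind(ex, ey, ez))
}

# resample a polyline (rows = points) at equal arc-length steps
resample_polyline <- function(p, ds) {
  n <- nrow(p)
  seg <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-n, , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  L <- s[n]
  if (L <= 0) return(p[1, , drop = FALSE])
  si <- seq(0, L, by = ds)
  if (si[length(si)] < L) si <- c(si, L)
  apply(p, 2, function(col)
    stats::approx(s, col, xout = si, ties = "ordered")$y)
}

#' Circular mean orientation of a nematic angle set
#'
#' The mean of headless angles is taken in the doubled-angle representation:
#' `arg(sum w exp(2 i theta)) / 2`, returned in `(-pi/2, pi/2]`. A perfectly
#' balanced set (resultant length ~ 0) has no defined mean and returns `NA`
#' with a warning.
#'
#' @param angles numeric vector of angles (radians).
#' @param weights optional non-negative weights.
#' @return mean angle in radians, or `NA` if undefined.
#' @export
mean_orientation <- function(angles, weights = NULL) {
  if (length(angles) == 0) stop_kfiber("empty angle set")
  w <- weights %||% rep(1, length(angles))
  z <- sum(w * exp(2i * angles))
  if (Mod(z) / sum(w) < 1e-12) {
    warning("resultant length ~ 0: mean orientation undefined")
    return(NA_real_)
  }
  wrap_nematic(Arg(z) / 2)
}

#' Scalar nematic order parameter
#'
#' Degree of alignment about the mean orientation. The default estimator is
#' the uniaxial form `S = <(3 cos^2(theta - <theta>) - 1)/2>`, which is 1
#' for perfect alignment, 0 for 3D-isotropic angle sets, and -0.5 for angles
#' all perpendicular to the mean. The planar estimator `<cos 2(theta -
#' <theta>)>` is also provided: it is the natural choice when the angles are
#' confined to a plane (it is 0 for planar-isotropic sets, where the
#' uniaxial form gives 1/4).
#'
#' @inheritParams mean_orientation
#' @param mean mean orientation; computed from the data if `NULL`.
#' @param estimator `"uniaxial"` (default) or `"planar"`.
#' @return S (dimensionless).
#' @export
order_parameter <- function(angles, mean = NULL, weights = NULL,
                            estimator = c("uniaxial", "planar")) {
  estimator <- match.arg(estimator)
  if (length(angles) == 0) stop_kfiber("empty angle set")
  w <- weights %||% rep(1, length(angles))
  m <- mean %||% mean_orientation(angles, w)
  d <- angles - m
  if (estimator == "uniaxial")
    sum(w * (3 * cos(d)^2 - 1) / 2) / sum(w)
  else
    sum(w * cos(2 * d)) / sum(w)
}

#' Rotationally averaged orientation field of a reconstruction
#'
#' Rotates the reconstruction about the spindle axis in increments of
#' pi/`n_rot` radians, projects each copy into the spindle-radial plane, and
#' accumulates segment angles into square bins, yielding the binned mean
#' orientation, per-bin order parameter and segment count.
#'
#' @inheritParams segment_angles
#' @param bin bin size in micrometres (default 0.1).
#' @param n_rot number of rotations over pi radians (default 10, i.e. steps
#'   of pi/10; rotations over the full circle are redundant for a headless
#'   field).
#' @return object of class `binned_orientation_field`: bin centers `x`, `y`,
#'   matrices `mean_angle`, `S` (uniaxial), `count` (segments per bin).
#' @export
rotational_average <- function(rec, cls = c("all", "kmt", "non-kmt"),
                               bin = 0.1, segment_len = 0.1, n_rot = 10) {
  cls <- match.arg(cls)
  rots <- seq(0, 2 * pi - pi / n_rot, by = pi / n_rot)
  segs <- do.call(rbind, lapply(rots, function(a)
    segment_angles(rec, cls = cls, segment_len = segment_len, rotate = a)))
  bin_orientation(segs, bin)
}

# accumulate a segment table into a binned orientation field
bin_orientation <- function(segs, bin) {
  xr <- range(segs$x); yr <- range(segs$y)
  xb <- seq(floor(xr[1] / bin) * bin, ceiling(xr[2] / bin) * bin, by = bin)
  yb <- seq(floor(yr[1] / bin) * bin, ceiling(yr[2] / bin) * bin, by = bin)
  if (length(xb) < 2) xb <- c(xb, xb + bin)
  if (length(yb) < 2) yb <- c(yb, yb + bin)
  ix <- findInterval(segs$x, xb, rightmost.closed = TRUE)
  iy <- findInterval(segs$y, yb, rightmost.closed = TRUE)
  nx <- length(xb) - 1; ny <- length(yb) - 1
  id <- (ix - 1) * ny + iy
  zc <- rowsum(cos(2 * segs$angle), id)
  zs <- rowsum(sin(2 * segs$angle), id)
  cnt <- rowsum(rep(1, nrow(segs)), id)
  ids <- as.integer(rownames(zc))
  mean_angle <- S <- count <- matrix(NA_real_, ny, nx)
  count[ids] <- cnt
  mean_angle[ids] <- wrap_nematic(atan2(zs, zc) / 2)
  # uniaxial S from the doubled-angle resultant:
  # <cos 2(theta - <theta>)> = |resultant| / n, and
  # S = (1 + 3 <cos 2 delta>) / 4 for in-plane angles
  r2 <- sqrt(zc^2 + zs^2) / cnt
  S[ids] <- (1 + 3 * r2) / 4
  structure(list(x = (xb[-1] + xb[-length(xb)]) / 2,
                 y = (yb[-1] + yb[-length(yb)]) / 2,
                 mean_angle = mean_angle, S = S, count = count, bin = bin),
            class = "binned_orientation_field")
}

#' @export
print.binned_orientation_field <- function(x, ...) {
  occ <- sum(!is.na(x$count))
  cat(sprintf("Binned orientation field: %d x %d bins (%.3g um), %d occupied\n",
              length(x$x), length(x$y), x$bin, occ))
  cat(sprintf("  segment-weighted mean S = %.3f\n",
              sum(x$S * x$count, na.rm = TRUE) / sum(x$count, na.rm = TRUE)))
  invisible(x)
}

#' Register and average orientation maps
#'
#' Rescales each map along the spindle axis (to a common pole-pole distance)
#' and the radial axis (to a common width, measured by a moment-based
#' ellipse fit to the thresholded weight image), then averages the angle
#' fields in the doubled-angle representation, weighted by the local weight.
#'
#' @param maps list of `orientation_map` objects (see
#'   [generate_orientation_map()]).
#' @param threshold_quantile weight quantile used to segment the spindle
#'   for the ellipse fit (default 0.5).
#' @return an averaged `orientation_map` on the common grid.
#' @export
register_spindles <- function(maps, threshold_quantile = 0.5) {
  stopifnot(length(maps) >= 1)
  geomfit <- lapply(maps, function(m) {
    tryCatch(map_scale(m, threshold_quantile), error = function(e) {
      warning("skipping map: ", conditionMessage(e))
      NULL
    })
  })
  ok <- !vapply(geomfit, is.null, logical(1))
  if (!any(ok)) stop_kfiber("no registrable maps")
  maps <- maps[ok]; geomfit <- geomfit[ok]
  L0 <- mean(vapply(geomfit, `[[`, numeric(1), "pp"))
  W0 <- mean(vapply(geomfit, `[[`, numeric(1), "width"))
  ref <- maps[[1]]
  sx <- L0 / geomfit[[1]]$pp; sy <- W0 / geomfit[[1]]$width
  x0 <- ref$x * sx; y0 <- ref$y * sy
  acc_c <- acc_s <- acc_w <- matrix(0, length(y0), length(x0))
  G <- expand.grid(y = y0, x = x0)
  for (k in seq_along(maps)) {
    m <- maps[[k]]
    # target grid point (x, y) pulls from source point (x / sx, y / sy)
    sxk <- L0 / geomfit[[k]]$pp; syk <- W0 / geomfit[[k]]$width
    val <- map_interp(m, G$x / sxk, G$y / syk)
    w <- val$w
    w[is.na(w)] <- 0
    acc_c <- acc_c + matrix(ifelse(is.na(val$c), 0, w * val$c), length(y0))
    acc_s <- acc_s + matrix(ifelse(is.na(val$s), 0, w * val$s), length(y0))
    acc_w <- acc_w + matrix(w, length(y0))
  }
  ang <- matrix(NA_real_, length(y0), length(x0))
  pos <- acc_w > 0
  ang[pos] <- wrap_nematic(atan2(acc_s[pos], acc_c[pos]) / 2)
  structure(list(x = x0, y = y0, angle = ang, weight = acc_w / length(maps),
                 poles = rbind(c(-L0 / 2, 0), c(L0 / 2, 0)),
                 spacing = diff(x0[1:2])),
            class = "orientation_map")
}

map_scale <- function(m, q) {
  pp <- sqrt(sum((m$poles[1, ] - m$poles[2, ])^2))
  thr <- stats::quantile(m$weight[m$weight > 0], q, na.rm = TRUE)
  mask <- which(!is.na(m$weight) & m$weight >= thr, arr.ind = TRUE)
  if (nrow(mask) < 10)
    stop_kfiber("weight threshold yields no closed region")
  yy <- m$y[mask[, 1]]
  # filled ellipse: sd(y) = b/2, so width (2b) = 4 sd
  list(pp = pp, width = 4 * stats::sd(yy))
}

# bilinear interpolation of (cos2, sin2, weight) from a map
map_interp <- function(m, px, py) {
  ix <- findInterval(px, m$x, all.inside = TRUE)
  iy <- findInterval(py, m$y, all.inside = TRUE)
  dx <- diff(m$x[1:2]); dy <- diff(m$y[1:2])
  fx <- pmin(pmax((px - m$x[ix]) / dx, 0), 1)
  fy <- pmin(pmax((py - m$y[iy]) / dy, 0), 1)
  out_c <- out_s <- out_w <- numeric(length(px))
  accw <- numeric(length(px))
  c2 <- cos(2 * m$angle); s2 <- sin(2 * m$angle)
  inx <- px >= min(m$x) & px <= max(m$x) & py >= min(m$y) & py <= max(m$y)
  for (k in list(c(0, 0), c(1, 0), c(0, 1), c(1, 1))) {
    w <- (if (k[1] == 0) 1 - fx else fx) * (if (k[2] == 0) 1 - fy else fy)
    idx <- cbind(iy + k[2], ix + k[1])
    cc <- c2[idx]; ss <- s2[idx]; ww <- m$weight[idx]
    okk <- !is.na(cc)
    out_c <- out_c + ifelse(okk, w * cc, 0)
    out_s <- out_s + ifelse(okk, w * ss, 0)
    out_w <- out_w + ifelse(okk & !is.na(ww), w * ww, 0)
    accw <- accw + ifelse(okk, w, 0)
  }
  bad <- accw <= 0 | !inx
  list(c = ifelse(bad, NA, out_c / pmax(accw, 1e-12)),
       s = ifelse(bad, NA, out_s / pmax(accw, 1e-12)),
       w = ifelse(bad, NA, out_w))
}

#' Fit the spindle geometry to a measured orientation field
#'
#' Two-stage chi-squared fit of the nematic model to a binned orientation
#' field or orientation map. Stage 1 fits the elliptical boundary (semi-axes
#' and center) with the aster defects pinned at the ellipse edge; stage 2
#' fixes the boundary and fits the defect positions along the spindle axis
#' and the defect core radius. The statistic is
#' `chi^2 = sum w_i wrap_pi(theta_obs,i - theta_model,i)^2` over occupied
#' bins, with weights `w_i` the per-bin segment count (or map weight).
#'
#' @param field a `binned_orientation_field` or `orientation_map`.
#' @param spacing grid spacing for the model solves (default 0.25 um).
#' @param defect_radius initial defect core radius (stage-2 start).
#' @param solver_tol residual tolerance for the model solves during
#'   optimisation.
#' @param maxit_boundary,maxit_defects Nelder-Mead iteration caps for the
#'   two stages.
#' @return list with the fitted [spindle_geometry()], `chi2`, per-stage
#'   optimiser diagnostics, and the number of bins used.
#' @export
fit_geometry <- function(field, spacing = 0.25, defect_radius = 0.5,
                         solver_tol = 1e-4, maxit_boundary = 120,
                         maxit_defects = 80) {
  dat <- field_points(field)
  if (nrow(dat) < 10)
    stop_kfiber("need at least 10 occupied bins to fit a geometry")

  chi2_of <- function(geom) {
    fld <- tryCatch(
      solve_director(geom, spacing = spacing, tol = solver_tol,
                     max_iter = 20000),
      error = function(e) NULL)
    if (is.null(fld)) return(1e12)
    ins <- inside_ellipse(cbind(dat$x, dat$y), geom)
    # bins outside the trial ellipse contribute the worst-case deviation
    dev2 <- rep((pi / 2)^2, nrow(dat))
    if (any(ins)) {
      th <- tryCatch(director_angle(fld, cbind(dat$x[ins], dat$y[ins])),
                     error = function(e) rep(NA_real_, sum(ins)))
      d <- wrap_nematic(dat$angle[ins] - th)
      dev2[ins] <- ifelse(is.na(d), (pi / 2)^2, d^2)
    }
    sum(dat$w * dev2)
  }

  # stage 1: ellipse, defects pinned at the edge
  cx0 <- sum(dat$x * dat$w) / sum(dat$w)
  cy0 <- sum(dat$y * dat$w) / sum(dat$w)
  a0 <- (max(dat$x) - min(dat$x)) / 2
  b0 <- (max(dat$y) - min(dat$y)) / 2
  edge_geom <- function(p) {
    a <- p[1]; b <- p[2]
    if (!is.finite(a) || !is.finite(b) || a < 2.5 * spacing ||
        b < 2.5 * spacing || a > 10 * a0 || b > 10 * b0)
      return(NULL)
    rad <- min(defect_radius, 0.4 * b)
    d <- a - rad - spacing - dist_edge_margin(a, b, rad)
    tryCatch(spindle_geometry(a, b, c(p[3], p[4]),
                              defects = rbind(c(p[3] - d, p[4]),
                                              c(p[3] + d, p[4])),
                              defect_radius = rad),
             error = function(e) NULL)
  }
  f1 <- function(p) {
    g <- edge_geom(p)
    if (is.null(g)) return(1e12)
    chi2_of(g)
  }
  o1 <- stats::optim(c(a0, b0, cx0, cy0), f1,
                     control = list(maxit = maxit_boundary, reltol = 1e-3))
  g1 <- edge_geom(o1$par)

  # stage 2: boundary fixed, fit defect offset and core radius
  a <- o1$par[1]; b <- o1$par[2]; ctr <- o1$par[3:4]
  mk2 <- function(p) {
    off <- p[1]; rad <- p[2]
    tryCatch(spindle_geometry(a, b, ctr,
                              defects = rbind(c(ctr[1] - off, ctr[2]),
                                              c(ctr[1] + off, ctr[2])),
                              defect_radius = rad),
             error = function(e) NULL)
  }
  f2 <- function(p) {
    g <- mk2(p)
    if (is.null(g) || 2 * p[2] / spacing < 3) return(1e12)
    chi2_of(g)
  }
  start2 <- c(sqrt(sum((g1$defects[2, ] - ctr)^2)), g1$defect_radius)
  o2 <- stats::optim(start2, f2,
                     control = list(maxit = maxit_defects, reltol = 1e-3))
  best <- mk2(o2$par)
  if (is.null(best) || o2$convergence > 1)
    stop_kfiber("geometry fit did not converge")
  list(geometry = best, chi2 = o2$value, stage1 = o1, stage2 = o2,
       n_bins = nrow(dat))
}

# safety margin so stage-1 edge defects stay valid
dist_edge_margin <- function(a, b, rad) 0.05 * min(a, b)

# flatten a field/map into (x, y, angle, w)
field_points <- function(field) {
  if (inherits(field, "binned_orientation_field")) {
    idx <- which(!is.na(field$mean_angle), arr.ind = TRUE)
    data.frame(x = field$x[idx[, 2]], y = field$y[idx[, 1]],
               angle = field$mean_angle[idx],
               w = field$count[idx])
  } else if (inherits(field, "orientation_map")) {
    idx <- which(!is.na(field$angle) & field$weight > 0, arr.ind = TRUE)
    data.frame(x = field$x[idx[, 2]], y = field$y[idx[, 1]],
               angle = field$angle[idx],
               w = field$weight[idx])
  } else stop_kfiber("unsupported field type")
}
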