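#' Solve the steady-state nematic director field in a spindle geometry
#'
#' At steady state in the one-constant active-nematic approximation the
#' director angle is harmonic: the field solves the Laplace equation in the
#' spindle bulk, subject to tangential anchoring on the elliptical boundary
#' and radial anchoring inside the two aster defect cores. The solution is
#' determined entirely by the geometry; it has no material parameters.
#'
#' The solver relaxes the director angle on a regular grid with a
#' checkerboard successive-over-relaxation (SOR) scheme. Angle differences
#' between neighbouring cells are always wrapped modulo pi, which respects
#' the headless n -> -n symmetry (equivalent to relaxing in the doubled-angle
#' representation) and avoids wrapping artifacts around the defects.
#' Boundary and defect cells are re-imposed at every iteration.
#'
#' @param geom a [spindle_geometry()].
#' @param spacing grid spacing in micrometres. Must resolve the defect core
#'   (at least 3 cells across a core diameter).
#' @param tol convergence tolerance on the maximum interior residual, in
#'   radians: the residual of a cell is the mean wrapped angle difference to
#'   its neighbours (zero for a discretely harmonic field).
#' @param max_iter maximum number of SOR sweeps.
#' @param boundary_anchoring `"tangential"` (the physical case) or
#'   `"radial"` (useful for constructing analytically radial test fields).
#' @return An object of class `director_field`: grid axes `x`, `y`, matrix
#'   `theta` (radians, rows = y, cols = x, `NA` outside the ellipse), a
#'   `role` matrix (`"bulk"`, `"boundary"`, `"defect"`, `"outside"`), the
#'   final `residual` and iteration count, and the geometry.
#' @examples
#' geom <- spindle_geometry(a = 4, b = 2.5, defect_radius = 0.4)
#' fld <- solve_director(geom, spacing = 0.2)
#' fld
#' @export
solve_director <- function(geom, spacing = 0.1, tol = 1e-6, max_iter = 100000,
                           boundary_anchoring = c("tangential", "radial")) {
  stopifnot(inherits(geom, "spindle_geometry"))
  boundary_anchoring <- match.arg(boundary_anchoring)
  if (2 * geom$defect_radius / spacing < 3)
    stop_kfiber("grid spacing too coarse: need >= 3 cells across a defect core")

  cx <- geom$center[1]; cy <- geom$center[2]
  x <- seq(cx - geom$a - spacing, cx + geom$a + spacing, by = spacing)
  y <- seq(cy - geom$b - spacing, cy + geom$b + spacing, by = spacing)
  nx <- length(x); ny <- length(y)
  X <- matrix(x, ny, nx, byrow = TRUE)
  Y <- matrix(y, ny, nx)

  inside <- ((X - cx) / geom$a)^2 + ((Y - cy) / geom$b)^2 <= 1
  role <- matrix("outside", ny, nx)
  role[inside] <- "bulk"

  # boundary cells: inside cells with at least one 4-neighbour outside
  nb_out <- shift_mat(!inside, 1, 0) | shift_mat(!inside, -1, 0) |
    shift_mat(!inside, 0, 1) | shift_mat(!inside, 0, -1)
  role[inside & nb_out] <- "boundary"

  # defect core cells
  for (i in 1:2) {
    d2 <- (X - geom$defects[i, 1])^2 + (Y - geom$defects[i, 2])^2
    role[inside & d2 <= geom$defect_radius^2] <- "defect"
  }

  theta <- matrix(NA_real_, ny, nx)
  # fixed cells
  bmask <- role == "boundary"
  if (boundary_anchoring == "tangential") {
    # ellipse tangent direction: perpendicular to the gradient of the
    # implicit equation, i.e. t = (-(y-cy)/b^2, (x-cx)/a^2)
    theta[bmask] <- wrap_nematic(atan2((X[bmask] - cx) / geom$a^2,
                                       -(Y[bmask] - cy) / geom$b^2))
  } else {
    theta[bmask] <- wrap_nematic(atan2(Y[bmask] - cy, X[bmask] - cx))
  }
  for (i in 1:2) {
    d2 <- (X - geom$defects[i, 1])^2 + (Y - geom$defects[i, 2])^2
    dmask <- role == "defect" & d2 <= geom$defect_radius^2
    theta[dmask] <- wrap_nematic(atan2(Y[dmask] - geom$defects[i, 2],
                                       X[dmask] - geom$defects[i, 1]))
  }
  # initialise the bulk from a nematic superposition of the two aster
  # fields: this seeds the correct topological winding around each defect
  # core, so the relaxation starts in the physical basin rather than
  # trapping metastable defect pairs
  bidx <- which(role == "bulk")
  ic <- is2 <- numeric(length(bidx))
  for (i in 1:2) {
    dx <- X[bidx] - geom$defects[i, 1]
    dy <- Y[bidx] - geom$defects[i, 2]
    phi <- atan2(dy, dx)
    w <- 1 / (dx^2 + dy^2 + 1e-12)
    ic <- ic + w * cos(2 * phi)
    is2 <- is2 + w * sin(2 * phi)
  }
  theta[bidx] <- wrap_nematic(atan2(is2, ic) / 2)

  free <- role == "bulk"
  defined <- role != "outside"
  # checkerboard colouring
  parity <- (row(theta) + col(theta)) %% 2 == 0
  omega <- 2 / (1 + sin(pi / max(nx, ny)))

  # Phase 1: relax the doubled-angle vector (cos 2theta, sin 2theta) with
  # per-step renormalisation. This gradient-flow-like phase settles the
  # topology (defect windings, pi-wall removal) that a pure wrapped-angle
  # scheme initialised far from the solution can miss.
  u <- cos(2 * theta); v <- sin(2 * theta)
  u[!defined] <- NA; v[!defined] <- NA
  fix_u <- cos(2 * theta[!free & defined])
  fix_v <- sin(2 * theta[!free & defined])
  for (k in seq_len(2000L)) {
    nu <- neighbour_mean(u, defined)
    nv <- neighbour_mean(v, defined)
    mag <- sqrt(nu^2 + nv^2)
    ok <- free & !is.na(mag) & mag > 0
    un <- u; vn <- v
    un[ok] <- nu[ok] / mag[ok]
    vn[ok] <- nv[ok] / mag[ok]
    chg <- max(abs(un[free] - u[free]), abs(vn[free] - v[free]), na.rm = TRUE)
    u <- un; v <- vn
    if (chg < 1e-4) break
  }
  theta[free] <- wrap_nematic(atan2(v[free], u[free]) / 2)

  # Phase 2: wrapped-angle checkerboard SOR; its fixed point is the discrete
  # harmonic angle field (zero mean wrapped neighbour difference).
  res <- Inf; it <- 0L
  while (it < max_iter) {
    for (colr in c(TRUE, FALSE)) {
      upd <- free & (parity == colr)
      delta <- neighbour_pull(theta, defined)
      theta[upd] <- wrap_nematic(theta[upd] + omega * delta[upd])
    }
    it <- it + 1L
    if (it %% 10 == 0 || it == max_iter) {
      delta <- neighbour_pull(theta, defined)
      res <- max(abs(delta[free]), na.rm = TRUE)
      if (res <= tol) break
    }
  }
  if (res > tol)
    stop_kfiber(sprintf(
      "director relaxation did not converge: residual %.3g > tol %.3g after %d sweeps",
      res, tol, it))

  structure(list(x = x, y = y, theta = theta, role = role,
                 spacing = spacing, geometry = geom,
                 residual = res, iterations = it,
                 boundary_anchoring = boundary_anchoring),
            class = "director_field")
}

# shift a matrix by (di, dj), padding with FALSE/NA
shift_mat <- function(m, di, dj, fill = if (is.logical(m)) FALSE else NA) {
  n <- matrix(fill, nrow(m), ncol(m))
  ri <- seq_len(nrow(m)); ci <- seq_len(ncol(m))
  rs <- ri - di; cs <- ci - dj
  ok_r <- rs >= 1 & rs <= nrow(m); ok_c <- cs >= 1 & cs <= ncol(m)
  n[ri[ok_r], ci[ok_c]] <- m[rs[ok_r], cs[ok_c]]
  n
}

# mean of defined neighbours (for vector-component relaxation)
neighbour_mean <- function(m, defined) {
  num <- matrix(0, nrow(m), ncol(m))
  cnt <- matrix(0, nrow(m), ncol(m))
  for (sh in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    tn <- shift_mat(m, sh[1], sh[2])
    dn <- shift_mat(defined, sh[1], sh[2])
    tn[!dn | is.na(tn)] <- 0
    num <- num + tn
    cnt <- cnt + dn
  }
  out <- num / pmax(cnt, 1)
  out[cnt == 0] <- NA_real_
  out
}

# mean wrapped angular pull of defined neighbours on each cell
neighbour_pull <- function(theta, defined) {
  num <- matrix(0, nrow(theta), ncol(theta))
  cnt <- matrix(0, nrow(theta), ncol(theta))
  for (sh in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    tn <- shift_mat(theta, sh[1], sh[2])
    dn <- shift_mat(defined, sh[1], sh[2])
    d <- wrap_nematic(tn - theta)
    d[!dn | is.na(d)] <- 0
    num <- num + d
    cnt <- cnt + dn
  }
  out <- num / pmax(cnt, 1)
  out[cnt == 0] <- NA_real_
  out
}

#' @export
print.director_field <- function(x, ...) {
  cat("Nematic director field\n")
  cat(sprintf("  grid: %d x %d cells, spacing %.3g um\n",
              length(x$x), length(x$y), x$spacing))
  cat(sprintf("  interior cells: %d bulk, %d boundary, %d defect\n",
              sum(x$role == "bulk"), sum(x$role == "boundary"),
              sum(x$role == "defect")))
  cat(sprintf("  converged in %d sweeps, interior residual %.3g rad\n",
              x$iterations, x$residual))
  invisible(x)
}

#' @export
plot.director_field <- function(x, stride = 3, len = NULL, ...) {
  len <- len %||% (0.8 * x$spacing * stride)
  ii <- seq(1, length(x$y), by = stride)
  jj <- seq(1, length(x$x), by = stride)
  graphics::plot(NA, xlim = range(x$x), ylim = range(x$y), asp = 1,
                 xlab = "spindle axis (um)", ylab = "radial axis (um)", ...)
  for (i in ii) for (j in jj) {
    th <- x$theta[i, j]
    if (!is.na(th)) {
      dx <- len / 2 * cos(th); dy <- len / 2 * sin(th)
      graphics::segments(x$x[j] - dx, x$y[i] - dy, x$x[j] + dx, x$y[i] + dy)
    }
  }
  graphics::points(x$geometry$defects, pch = 19, col = 2)
  invisible(x)
}

#' Director angle at arbitrary points
#'
#' Bilinear interpolation of the field in the doubled-angle representation
#' `(cos 2 theta, sin 2 theta)`, which is smooth across the headless-angle
#' wrap. Cells outside the domain are ignored (weights renormalised).
#'
#' @param field a [solve_director()] result.
#' @param p numeric 2-vector or n x 2 matrix of points.
#' @return angle(s) in `(-pi/2, pi/2]`.
#' @export
director_angle <- function(field, p) {
  p <- matrix(p, ncol = 2)
  ix <- findInterval(p[, 1], field$x, all.inside = TRUE)
  iy <- findInterval(p[, 2], field$y, all.inside = TRUE)
  fx <- (p[, 1] - field$x[ix]) / field$spacing
  fy <- (p[, 2] - field$y[iy]) / field$spacing
  c2 <- cos(2 * field$theta); s2 <- sin(2 * field$theta)
  acc_c <- acc_s <- acc_w <- numeric(nrow(p))
  for (k in list(c(0, 0), c(1, 0), c(0, 1), c(1, 1))) {
    w <- (if (k[1] == 0) 1 - fx else fx) * (if (k[2] == 0) 1 - fy else fy)
    idx <- cbind(iy + k[2], ix + k[1])
    cc <- c2[idx]; ss <- s2[idx]
    ok <- !is.na(cc)
    acc_c <- acc_c + ifelse(ok, w * cc, 0)
    acc_s <- acc_s + ifelse(ok, w * ss, 0)
    acc_w <- acc_w + ifelse(ok, w, 0)
  }
  if (any(acc_w <= 0))
    stop_kfiber("point outside the director field domain")
  wrap_nematic(atan2(acc_s, acc_c) / 2)
}

#' Trace a streamline of the director field to a pole
#'
#' Integrates the curve everywhere tangent to the (headless) director from a
#' starting point to the target pole with a fixed-step midpoint scheme. The
#' orientation ambiguity is resolved at every step by choosing the sign that
#' decreases the distance to the target pole. Integration stops on entering
#' the defect core; within the core the field is radial, so the arc-length
#' coordinate is completed by the straight segment to the pole center.
#'
#' @param field a [solve_director()] result.
#' @param start 2-vector inside the ellipse.
#' @param pole which defect to integrate toward (1 or 2, or `"nearest"`).
#' @param step integration step in micrometres (default half the grid
#'   spacing).
#' @param max_steps safety cap on the number of steps.
#' @return An object of class `streamline`: `points` (n x 2, ordered from
#'   the pole outward), `s` (arc length from the pole center, strictly
#'   increasing), and `pole` (the defect index).
#' @export
trace_streamline <- function(field, start, pole = "nearest",
                             step = field$spacing / 2, max_steps = 100000) {
  geom <- field$geometry
  start <- as.numeric(start)
  if (!inside_ellipse(start, geom))
    stop_kfiber("streamline start point lies outside the ellipse")
  if (identical(pole, "nearest")) {
    d2 <- rowSums((geom$defects - rep(start, each = 2))^2)
    pole <- which.min(d2)
  }
  pc <- geom$defects[pole, ]
  pts <- matrix(NA_real_, max_steps + 1, 2)
  pts[1, ] <- start
  p <- start
  n <- 1L
  prev_dir <- NULL
  while (sqrt(sum((p - pc)^2)) > geom$defect_radius) {
    if (n > max_steps)
      stop_kfiber("streamline exceeded max_steps without reaching the pole")
    th1 <- director_angle(field, p)
    d1 <- c(cos(th1), sin(th1))
    ref <- if (is.null(prev_dir)) pc - p else prev_dir
    if (sum(d1 * ref) < 0) d1 <- -d1
    ph <- p + (step / 2) * d1
    if (!inside_ellipse(ph, geom)) ph <- p   # fall back to Euler at the rim
    th2 <- director_angle(field, ph)
    d2 <- c(cos(th2), sin(th2))
    if (sum(d2 * d1) < 0) d2 <- -d2
    pn <- p + step * d2
    if (!inside_ellipse(pn, geom)) {
      # boundary-hugging trajectories may graze outside by a fraction of a
      # step (tangential anchoring keeps the true streamline on the rim);
      # project such points back just inside the ellipse, but treat larger
      # excursions as a genuine field/geometry inconsistency
      rel <- sqrt(((pn[1] - geom$center[1]) / geom$a)^2 +
                  ((pn[2] - geom$center[2]) / geom$b)^2)
      if ((rel - 1) * min(geom$a, geom$b) > step)
        stop_kfiber("streamline exited the ellipse; geometry and field inconsistent")
      pn <- geom$center + (pn - geom$center) * (1 - 1e-9) / rel
    }
    prev_dir <- d2
    p <- pn
    n <- n + 1L
    pts[n, ] <- p
    # stall guard: require net progress toward the pole
    if (n %% 200L == 0L) {
      d_now <- sqrt(sum((p - pc)^2))
      d_then <- sqrt(sum((pts[n - 199L, ] - pc)^2))
      if (d_then - d_now < step)
        stop_kfiber("streamline stalled without approaching the pole")
    }
  }
  pts <- pts[seq_len(n), , drop = FALSE]
  # drop repeated points (rim projection can stall a step) so s stays
  # strictly increasing
  if (n > 1) {
    dup <- c(FALSE, rowSums(abs(pts[-1, , drop = FALSE] -
                                  pts[-n, , drop = FALSE])) < 1e-12)
    pts <- pts[!dup, , drop = FALSE]
    n <- nrow(pts)
  }
  # order from the pole outward and build the arc-length coordinate with
  # s = 0 at the pole center (radial inside the core)
  pts <- pts[n:1, , drop = FALSE]
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-n, , drop = FALSE])^2))
  s0 <- sqrt(sum((pts[1, ] - pc)^2))
  s <- s0 + c(0, cumsum(seg))
  structure(list(points = pts, s = s, pole = pole, step = step),
            class = "streamline")
}

#' @export
print.streamline <- function(x, ...) {
  cat(sprintf("Streamline to pole %d: %d points, s in [%.3g, %.3g] um\n",
              x$pole, nrow(x$points), min(x$s), max(x$s)))
  invisible(x)
}

#' Arc-length coordinate of a point along its streamline
#'
#' Traces the streamline from `point` to the pole and returns the distance
#' from the pole along that streamline (the coordinate `s`, with `s = 0` at
#' the pole center).
#'
#' @inheritParams trace_streamline
#' @param point 2-vector inside the ellipse.
#' @return arc length in micrometres.
#' @export
streamline_position <- function(field, point, pole = "nearest",
                                step = field$spacing / 2) {
  sl <- trace_streamline(field, point, pole = pole, step = step)
  sl$s[length(sl$s)]
}

#' Seed streamlines across the spindle equator
#'
#' Places seeds on the equatorial midplane line (perpendicular to the
#' spindle axis through the ellipse center) at the given spacing, symmetric
#' about the axis, and traces one streamline per seed toward each pole.
#'
#' @inheritParams trace_streamline
#' @param spacing seed spacing in micrometres (default 0.5).
#' @param halfwidth half-extent of the seed line in micrometres. Defaults to
#'   `b - defect_radius`: trajectories seeded within one core radius of the
#'   rim ride the rim separatrix toward the boundary vertex instead of the
#'   pole and are excluded.
#' @return list of `streamline` objects; each carries attributes `seed`
#'   (the seed y-offset) and `pole`.
#' @export
seed_streamlines <- function(field, spacing = 0.5, halfwidth = NULL,
                             step = field$spacing / 2) {
  stopifnot(spacing > 0)
  geom <- field$geometry
  halfwidth <- halfwidth %||% (geom$b - geom$defect_radius)
  w <- floor(halfwidth / spacing + 1e-9) * spacing
  offs <- seq(-w, w, by = spacing)
  out <- list()
  for (off in offs) {
    seed <- c(geom$center[1], geom$center[2] + off)
    for (pl in 1:2) {
      sl <- trace_streamline(field, seed, pole = pl, step = step)
      attr(sl, "seed") <- off
      out[[length(out) + 1L]] <- sl
    }
  }
  out
}
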