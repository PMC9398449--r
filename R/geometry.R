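#' Spindle geometry: elliptical boundary with two aster defects
#'
#' The spindle is modelled in a 2D plane containing the spindle axis as an
#' elliptical domain with tangential director anchoring at the boundary and
#' two finite-radius +1 ("aster") defects with radial anchoring representing
#' the poles. The spindle axis is the x axis of the plane; all lengths are in
#' micrometres.
#'
#' @param a,b ellipse semi-axis lengths along the spindle (x) and radial (y)
#'   axes, in micrometres.
#' @param center 2-vector, ellipse center.
#' @param defects 2x2 matrix of defect (pole) centers, one row per defect.
#'   Defaults to two points on the spindle axis at `x = center[1] +- 0.82 a`.
#' @param defect_radius radius of the circular defect cores, in micrometres.
#'   Within a core the director is radial about the core center.
#' @return An object of class `spindle_geometry`.
#' @examples
#' geom <- spindle_geometry(a = 5.5, b = 3)
#' geom
#' @export
spindle_geometry <- function(a, b, center = c(0, 0),
                             defects = NULL, defect_radius = 0.5) {
  if (!is.numeric(a) || !is.numeric(b) || a <= 0 || b <= 0)
    stop_kfiber("ellipse semi-axes must be positive")
  center <- as.numeric(center)
  if (length(center) != 2 || any(!is.finite(center)))
    stop_kfiber("center must be a finite 2-vector")
  if (is.null(defects)) {
    d <- 0.82 * a
    defects <- rbind(center + c(-d, 0), center + c(d, 0))
  }
  defects <- matrix(as.numeric(defects), ncol = 2)
  if (nrow(defects) != 2 || any(!is.finite(defects)))
    stop_kfiber("exactly two finite defect centers are required")
  # implicit ellipse coordinate; < 1 means strictly inside
  rel <- ((defects[, 1] - center[1]) / a)^2 + ((defects[, 2] - center[2]) / b)^2
  if (any(rel >= 1))
    stop_kfiber("defect centers must lie strictly inside the ellipse")
  if (defect_radius <= 0)
    stop_kfiber("defect_radius must be positive")
  bd <- vapply(seq_len(2), function(i)
    dist_to_ellipse(defects[i, ], a, b, center), numeric(1))
  if (defect_radius >= min(bd))
    stop_kfiber("defect_radius must be smaller than the defect-boundary distance")
  structure(list(a = a, b = b, center = center,
                 defects = defects, defect_radius = defect_radius),
            class = "spindle_geometry")
}

#' @export
print.spindle_geometry <- function(x, ...) {
  cat("Spindle geometry (ellipse + two aster defects)\n")
  cat(sprintf("  semi-axes: a = %.3g um (spindle), b = %.3g um (radial)\n",
              x$a, x$b))
  cat(sprintf("  center: (%.3g, %.3g) um\n", x$center[1], x$center[2]))
  cat(sprintf("  defects: (%.3g, %.3g) and (%.3g, %.3g) um, core radius %.3g um\n",
              x$defects[1, 1], x$defects[1, 2],
              x$defects[2, 1], x$defects[2, 2], x$defect_radius))
  invisible(x)
}

# minimum distance from an interior point to the ellipse boundary (numeric,
# parametric minimisation is ample for validation purposes)
dist_to_ellipse <- function(p, a, b, center) {
  f <- function(t) {
    q <- c(center[1] + a * cos(t), center[2] + b * sin(t))
    sum((q - p)^2)
  }
  t0 <- atan2((p[2] - center[2]) / b, (p[1] - center[1]) / a)
  opt <- stats::optimize(f, interval = c(t0 - pi / 2, t0 + pi / 2))
  sqrt(opt$objective)
}

# is a point (or points, rowwise) inside the ellipse?
inside_ellipse <- function(p, geom) {
  p <- matrix(p, ncol = 2)
  ((p[, 1] - geom$center[1]) / geom$a)^2 +
    ((p[, 2] - geom$center[2]) / geom$b)^2 <= 1
}
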