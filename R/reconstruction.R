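#' Construct a microtubule polyline
#'
#' @param points n x 3 numeric matrix of vertex coordinates in micrometres,
#'   ordered along the microtubule.
#' @param plus_end,minus_end indices of the two termini (1 or `nrow(points)`).
#' @param cls `"kmt"` or `"non-kmt"`.
#' @param kinetochore_id id of the attached kinetochore; required for KMTs,
#'   must be absent for non-KMTs.
#' @return object of class `mt_polyline`.
#' @export
mt_polyline <- function(points, plus_end = nrow(points), minus_end = 1,
                        cls = c("non-kmt", "kmt"), kinetochore_id = NULL) {
  cls <- match.arg(cls)
  points <- matrix(as.numeric(points), ncol = 3)
  if (nrow(points) < 2)
    stop_kfiber("a microtubule polyline needs at least 2 points")
  if (any(!is.finite(points)))
    stop_kfiber("non-finite coordinates in microtubule polyline")
  n <- nrow(points)
  if (!plus_end %in% c(1L, n) || !minus_end %in% c(1L, n) ||
      plus_end == minus_end)
    stop_kfiber("plus_end and minus_end must be the two distinct termini")
  if (mt_arclength(points) <= 0)
    stop_kfiber("polyline has zero arc length")
  if (cls == "kmt" && is.null(kinetochore_id))
    stop_kfiber("a KMT must reference a kinetochore id")
  if (cls == "non-kmt" && !is.null(kinetochore_id))
    stop_kfiber("a non-KMT cannot reference a kinetochore id")
  structure(list(points = points, plus_end = as.integer(plus_end),
                 minus_end = as.integer(minus_end), cls = cls,
                 kinetochore_id = kinetochore_id),
            class = "mt_polyline")
}

mt_arclength <- function(points) {
  n <- nrow(points)
  sum(sqrt(rowSums((points[-1, , drop = FALSE] -
                      points[-n, , drop = FALSE])^2)))
}

#' Assemble a validated spindle reconstruction
#'
#' A reconstruction holds per-microtubule 3D polylines with end labels and
#' KMT classification, the two pole positions (mother-centriole centers),
#' and the kinetochore positions. All coordinates are in micrometres in a
#' right-handed frame; by convention the spindle axis is the line through
#' the two poles.
#'
#' @param mts list of [mt_polyline()] objects.
#' @param poles 2 x 3 numeric matrix of pole coordinates.
#' @param kinetochores data.frame with columns `id`, `x`, `y`, `z`.
#' @param meta optional list of provenance metadata.
#' @return object of class `spindle_reconstruction`.
#' @export
spindle_reconstruction <- function(mts, poles, kinetochores = NULL,
                                   meta = list()) {
  poles <- matrix(as.numeric(poles), ncol = 3)
  if (nrow(poles) != 2 || any(!is.finite(poles)))
    stop_kfiber("exactly two finite pole positions are required")
  if (is.null(kinetochores))
    kinetochores <- data.frame(id = integer(0), x = numeric(0),
                               y = numeric(0), z = numeric(0))
  if (!all(c("id", "x", "y", "z") %in% names(kinetochores)))
    stop_kfiber("kinetochores need columns id, x, y, z")
  if (anyDuplicated(kinetochores$id))
    stop_kfiber("duplicate kinetochore ids")
  for (i in seq_along(mts)) {
    mt <- mts[[i]]
    if (!inherits(mt, "mt_polyline"))
      stop_kfiber(sprintf("mts[[%d]] is not an mt_polyline", i))
    if (mt$cls == "kmt" && !mt$kinetochore_id %in% kinetochores$id)
      stop_kfiber(sprintf("KMT %d references unknown kinetochore id %s",
                          i, mt$kinetochore_id))
  }
  structure(list(mts = mts, poles = poles, kinetochores = kinetochores,
                 meta = meta),
            class = "spindle_reconstruction")
}

#' @export
print.spindle_reconstruction <- function(x, ...) {
  cls <- vapply(x$mts, function(m) m$cls, character(1))
  cat("Spindle reconstruction\n")
  cat(sprintf("  %d MTs (%d KMTs, %d non-KMTs), %d kinetochores\n",
              length(x$mts), sum(cls == "kmt"), sum(cls == "non-kmt"),
              nrow(x$kinetochores)))
  pp <- sqrt(sum((x$poles[1, ] - x$poles[2, ])^2))
  cat(sprintf("  pole-pole distance: %.2f um\n", pp))
  invisible(x)
}

#' @export
summary.spindle_reconstruction <- function(object, ...) {
  cls <- vapply(object$mts, function(m) m$cls, character(1))
  lens <- vapply(object$mts, function(m) mt_arclength(m$points), numeric(1))
  out <- list(n_mts = length(object$mts), n_kmts = sum(cls == "kmt"),
              n_kinetochores = nrow(object$kinetochores),
              pole_pole = sqrt(sum((object$poles[1, ] - object$poles[2, ])^2)),
              mean_length_kmt = mean(lens[cls == "kmt"]),
              mean_length_nonkmt = mean(lens[cls == "non-kmt"]))
  class(out) <- "summary.spindle_reconstruction"
  out
}

#' @export
print.summary.spindle_reconstruction <- function(x, ...) {
  cat(sprintf("MTs: %d (%d KMTs); kinetochores: %d\n",
              x$n_mts, x$n_kmts, x$n_kinetochores))
  cat(sprintf("pole-pole: %.2f um; mean length KMT %.2f um, non-KMT %.2f um\n",
              x$pole_pole, x$mean_length_kmt, x$mean_length_nonkmt))
  invisible(x)
}

#' Write / read a spindle reconstruction
#'
#' The exchange format is plain columnar text plus a JSON sidecar: vertices
#' go to `<path>.csv` (columns `mt_id`, `point_idx`, `x_um`, `y_um`, `z_um`,
#' one row per polyline vertex, grouped by MT id) and poles, kinetochores and
#' per-MT attributes (class, end labels, kinetochore assignment) go to
#' `<path>.json`. Coordinates are written with 17 significant digits so a
#' round trip reproduces all fields bit-exactly.
#'
#' @param rec a [spindle_reconstruction()].
#' @param path file path prefix (without extension).
#' @return `write_reconstruction` returns `path` invisibly;
#'   `read_reconstruction` returns the validated reconstruction.
#' @export
write_reconstruction <- function(rec, path) {
  stopifnot(inherits(rec, "spindle_reconstruction"))
  vert <- do.call(rbind, lapply(seq_along(rec$mts), function(i) {
    p <- rec$mts[[i]]$points
    data.frame(mt_id = i, point_idx = seq_len(nrow(p)),
               x_um = p[, 1], y_um = p[, 2], z_um = p[, 3])
  }))
  fmt <- function(v) sprintf("%.17g", v)
  vert$x_um <- fmt(vert$x_um); vert$y_um <- fmt(vert$y_um)
  vert$z_um <- fmt(vert$z_um)
  utils::write.csv(vert, paste0(path, ".csv"), row.names = FALSE,
                   quote = FALSE)
  side <- list(
    poles = apply(rec$poles, 1, fmt, simplify = FALSE),
    kinetochores = list(id = rec$kinetochores$id,
                        x = fmt(rec$kinetochores$x),
                        y = fmt(rec$kinetochores$y),
                        z = fmt(rec$kinetochores$z)),
    mts = lapply(rec$mts, function(m)
      list(plus_end = m$plus_end, minus_end = m$minus_end, cls = m$cls,
           kinetochore_id = m$kinetochore_id)),
    meta = rec$meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

#' @rdname write_reconstruction
#' @export
read_reconstruction <- function(path) {
  csv <- paste0(path, ".csv"); js <- paste0(path, ".json")
  if (!file.exists(csv) || !file.exists(js))
    stop_kfiber("reconstruction files not found at path prefix ", path)
  vert <- utils::read.csv(csv)
  need <- c("mt_id", "point_idx", "x_um", "y_um", "z_um")
  if (!all(need %in% names(vert)))
    stop_kfiber("vertex table missing columns: ",
                paste(setdiff(need, names(vert)), collapse = ", "))
  if (any(!is.finite(as.matrix(vert[, c("x_um", "y_um", "z_um")]))))
    stop_kfiber("non-finite coordinates in vertex table")
  side <- jsonlite::read_json(js)
  kin <- data.frame(
    id = vapply(side$kinetochores$id, as.integer, integer(1)),
    x = vapply(side$kinetochores$x, as.numeric, numeric(1)),
    y = vapply(side$kinetochores$y, as.numeric, numeric(1)),
    z = vapply(side$kinetochores$z, as.numeric, numeric(1)))
  poles <- do.call(rbind, lapply(side$poles, function(p)
    vapply(p, as.numeric, numeric(1))))
  mts <- vector("list", length(side$mts))
  for (i in seq_along(side$mts)) {
    m <- side$mts[[i]]
    pts <- as.matrix(vert[vert$mt_id == i, c("x_um", "y_um", "z_um")])
    pts <- pts[order(vert$point_idx[vert$mt_id == i]), , drop = FALSE]
    dimnames(pts) <- NULL
    if (identical(m$cls, "kmt") && is.null(m$kinetochore_id))
      stop_kfiber(sprintf("MT %d is labelled KMT but has no kinetochore_id", i))
    mts[[i]] <- mt_polyline(pts, plus_end = m$plus_end,
                            minus_end = m$minus_end, cls = m$cls,
                            kinetochore_id = m$kinetochore_id)
  }
  spindle_reconstruction(mts, poles, kin,
                         meta = side$meta %||% list())
}

#' Classify microtubules as kinetochore microtubules
#'
#' A microtubule with a terminus within `attach_radius` of a kinetochore
#' (closed threshold, `<=`) is labelled a KMT; that terminus becomes the
#' plus end (the kinetochore-embedded end) and the opposite terminus the
#' minus end. Ties are broken by the nearest kinetochore. The operation is
#' idempotent; with no kinetochores every MT is labelled non-KMT.
#'
#' @param rec a [spindle_reconstruction()].
#' @param attach_radius attachment distance threshold in micrometres. The
#'   value used by any particular reconstruction pipeline is a property of
#'   that pipeline; it must be supplied by the user.
#' @return the reconstruction with updated `cls`, end labels and
#'   kinetochore assignments.
#' @export
classify_kmts <- function(rec, attach_radius) {
  stopifnot(inherits(rec, "spindle_reconstruction"))
  if (!is.numeric(attach_radius) || attach_radius <= 0)
    stop_kfiber("attach_radius must be a positive distance in micrometres")
  kin <- rec$kinetochores
  if (nrow(kin) == 0) {
    rec$mts <- lapply(rec$mts, function(m) {
      m$cls <- "non-kmt"; m$kinetochore_id <- NULL; m
    })
    return(rec)
  }
  kxyz <- as.matrix(kin[, c("x", "y", "z")])
  rec$mts <- lapply(rec$mts, function(m) {
    n <- nrow(m$points)
    ends <- m$points[c(1, n), , drop = FALSE]
    d2 <- cross_dist2(ends, kxyz)
    best <- arrayInd(which.min(d2), dim(d2))
    if (sqrt(d2[best]) <= attach_radius) {
      m$cls <- "kmt"
      m$kinetochore_id <- kin$id[best[2]]
      m$plus_end <- c(1L, n)[best[1]]
      m$minus_end <- c(1L, n)[c(2L, 1L)[best[1]]]
    } else {
      m$cls <- "non-kmt"
      m$kinetochore_id <- NULL
    }
    m
  })
  rec
}

#' KMT minus-end distances to the pole
#'
#' Euclidean 3D distance from each KMT minus end to the pole of its
#' half-spindle. Each KMT is assigned to the pole on its kinetochore's side
#' of the equatorial plane (the perpendicular bisector of the pole-pole
#' segment); a kinetochore exactly on the plane falls to the pole nearer the
#' minus end. Also reports the fraction of minus ends within `threshold`
#' (closed interval, `<=`).
#'
#' @param rec a [spindle_reconstruction()] with at least one KMT.
#' @param threshold distance defining "near the pole", micrometres
#'   (default 1.7).
#' @return data.frame (`mt`, `kinetochore_id`, `pole`, `distance`) with the
#'   near-pole fraction in attribute `fraction_within`.
#' @export
minus_end_pole_distances <- function(rec, threshold = 1.7) {
  stopifnot(inherits(rec, "spindle_reconstruction"))
  is_kmt <- vapply(rec$mts, function(m) m$cls == "kmt", logical(1))
  if (!any(is_kmt))
    stop_kfiber("reconstruction contains no KMTs")
  axis_mid <- colMeans(rec$poles)
  axis_dir <- rec$poles[2, ] - rec$poles[1, ]
  rows <- lapply(which(is_kmt), function(i) {
    m <- rec$mts[[i]]
    minus <- m$points[m$minus_end, ]
    kin <- rec$kinetochores
    kp <- as.numeric(kin[kin$id == m$kinetochore_id, c("x", "y", "z")])
    side <- sum((kp - axis_mid) * axis_dir)
    pole <- if (side > 0) 2L else if (side < 0) 1L else
      which.min(c(sum((minus - rec$poles[1, ])^2),
                  sum((minus - rec$poles[2, ])^2)))
    data.frame(mt = i, kinetochore_id = m$kinetochore_id, pole = pole,
               distance = sqrt(sum((minus - rec$poles[pole, ])^2)))
  })
  out <- do.call(rbind, rows)
  attr(out, "fraction_within") <- mean(out$distance <= threshold)
  attr(out, "threshold") <- threshold
  out
}
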