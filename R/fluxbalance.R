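#' Minus-end density along streamlines
#'
#' Builds the histogram density of KMT minus-end arc-length positions `s`
#' (micrometres from the pole along the streamline) and fits it to a
#' Gaussian peaked near the pole plus a constant bulk term:
#' `n(s) = A exp(-(s - mu)^2 / (2 sigma^2)) + c0`. Following the upstream
#' counting rule, a minus end at `s` is counted only if its plus end
#' (kinetochore) lies at larger `s`.
#'
#' @param s_minus numeric vector of minus-end arc-length coordinates.
#' @param s_kin matching vector of kinetochore (plus-end) coordinates.
#' @param bin histogram bin width in micrometres (default 0.25).
#' @param density if `TRUE` (default) normalise counts to a probability
#'   density per streamline-micrometre.
#' @return object of class `minus_end_profile`: bin centers `s`, density
#'   `n`, the fit parameters (`amp`, `mu`, `sigma`, `c0`), `fit_valid`, and
#'   an evaluation function `n_fun(s)`.
#' @export
minus_end_density <- function(s_minus, s_kin, bin = 0.25, density = TRUE) {
  if (length(s_minus) != length(s_kin))
    stop_kfiber("s_minus and s_kin must have equal length")
  keep <- s_kin > s_minus
  s <- s_minus[keep]
  if (length(s) < 20)
    stop_kfiber("need at least 20 KMTs for a stable density estimate")
  breaks <- seq(0, max(s_kin) + bin, by = bin)
  h <- graphics::hist(s, breaks = breaks, plot = FALSE)
  n <- if (density) h$density else h$counts
  ctr <- h$mids

  fit <- tryCatch({
    occ <- ctr <= max(s)   # drop trailing empty bins beyond the data
    f <- minpack.lm::nlsLM(
      n ~ amp * exp(-(ctr - mu)^2 / (2 * sigma^2)) + c0,
      data = data.frame(ctr = ctr[occ], n = n[occ]),
      start = list(amp = max(n), mu = ctr[which.max(n)],
                   sigma = 2 * bin, c0 = stats::median(n[n > 0])),
      lower = c(0, 0, bin / 4, 0),
      upper = c(10 * max(n), max(ctr), max(ctr), max(n)),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    stats::coef(f)
  }, error = function(e) NULL)

  valid <- !is.null(fit) && sum(n > 0) >= 4
  if (!valid) fit <- c(amp = NA, mu = NA, sigma = NA, c0 = NA)
  structure(list(s = ctr, n = n, bin = bin,
                 amp = unname(fit["amp"]), mu = unname(fit["mu"]),
                 sigma = unname(fit["sigma"]), c0 = unname(fit["c0"]),
                 fit_valid = valid, n_obs = length(s),
                 s_max = max(s_kin)),
            class = "minus_end_profile")
}

#' Evaluate the fitted minus-end density
#'
#' @param profile a `minus_end_profile`.
#' @param s positions (micrometres).
#' @param use_fit evaluate the parametric fit (default) or interpolate the
#'   raw histogram.
#' @return density values.
#' @export
profile_density <- function(profile, s, use_fit = TRUE) {
  if (use_fit && profile$fit_valid) {
    profile$amp * exp(-(s - profile$mu)^2 / (2 * profile$sigma^2)) +
      profile$c0
  } else {
    stats::approx(profile$s, profile$n, xout = s, rule = 2)$y
  }
}

#' @export
print.minus_end_profile <- function(x, ...) {
  cat(sprintf("Minus-end profile: %d minus ends, %d bins of %.3g um\n",
              x$n_obs, length(x$s), x$bin))
  if (x$fit_valid)
    cat(sprintf("  fit: %.3g * exp(-(s - %.3g)^2 / (2 * %.3g^2)) + %.3g\n",
                x$amp, x$mu, x$sigma, x$c0))
  else cat("  parametric fit invalid (degenerate histogram)\n")
  invisible(x)
}

#' @export
plot.minus_end_profile <- function(x, ...) {
  graphics::plot(x$s, x$n, type = "h", xlab = "s (um from pole)",
                 ylab = "minus-end density", ...)
  if (x$fit_valid) {
    ss <- seq(0, max(x$s), length.out = 200)
    graphics::lines(ss, profile_density(x, ss), col = 2, lwd = 2)
  }
  invisible(x)
}

#' Recruitment models for new KMT minus ends
#'
#' `recruitment_nucleate()` encodes de novo nucleation at the kinetochore:
#' the bulk source `j(s)` is identically zero and new minus ends appear at
#' the kinetochore position. `capture_recruitment()` encodes conversion of
#' existing non-KMTs: `j(s)` is proportional to the non-KMT minus-end
#' density times the probability that a non-KMT nucleated at `s` grows long
#' enough to reach the kinetochore before catastrophe, modelled as an
#' exponential survival in the required growth length,
#' `P_reach = exp(-(s_kin - s) / reach_length)`. `recruitment_hybrid()`
#' mixes the two with a captured fraction `f`.
#'
#' @param nonkmt_density function of `s` giving non-KMT minus-end density
#'   (any positive multiple; normalisation is fixed internally).
#' @param reach_length survival length constant of the growth-to-capture
#'   probability, micrometres (`Inf` makes every non-KMT reachable).
#' @param s_kin kinetochore arc-length position (upper end of the domain).
#' @param f captured fraction in `[0, 1]`.
#' @return object of class `recruitment_model` with fields `kind`, `j`
#'   (function of `s`, unnormalised shape; zero for pure nucleation) and
#'   `fraction_captured`.
#' @export
capture_recruitment <- function(nonkmt_density, reach_length = Inf,
                                s_kin = NULL) {
  stopifnot(is.function(nonkmt_density))
  jfun <- function(s) {
    p <- if (is.infinite(reach_length)) 1
         else exp(-pmax((s_kin %||% max(s)) - s, 0) / reach_length)
    pmax(nonkmt_density(s), 0) * p
  }
  structure(list(kind = "capture", j = jfun, fraction_captured = 1,
                 reach_length = reach_length),
            class = "recruitment_model")
}

#' @rdname capture_recruitment
#' @export
recruitment_nucleate <- function() {
  structure(list(kind = "nucleate", j = function(s) rep(0, length(s)),
                 fraction_captured = 0),
            class = "recruitment_model")
}

#' @rdname capture_recruitment
#' @export
recruitment_hybrid <- function(capture, f) {
  stopifnot(inherits(capture, "recruitment_model"), f >= 0, f <= 1)
  structure(list(kind = if (f == 0) "nucleate" else if (f == 1) "capture"
                 else "hybrid",
                 j = capture$j, fraction_captured = f,
                 reach_length = capture$reach_length),
            class = "recruitment_model")
}

#' Solve the steady-state flux balance for the minus-end speed profile
#'
#' At steady state the gain, transport and loss of KMT minus ends balance at
#' every position along a streamline:
#' `j(s) + v(s) dn/ds + n(s) dv/ds - r n(s) = 0`,
#' i.e. in conservative form `d(n v)/ds = r n - j`. Minus ends move toward
#' the pole (decreasing `s`), and no minus-end flux passes through the pole,
#' so the flux at `s` is the net detachment-minus-recruitment downstream:
#' `n(s) v(s) = integral_0^s (r n - j) ds'`, and `v = flux / n`. The bulk
#' recruitment shape is normalised so that total recruitment is
#' `fraction_captured * r * integral n ds` (the remainder of the detachment
#' loss is replaced by nucleation at the kinetochore, which enters as the
#' boundary flux at `s_kin`).
#'
#' @param profile a `minus_end_profile` (or any object accepted by
#'   [profile_density()]).
#' @param model a `recruitment_model`.
#' @param r detachment rate, 1/min (default 0.4).
#' @param s_kin kinetochore end of the domain (default: the profile's
#'   maximum observed coordinate).
#' @param s_pole pole-region boundary `s_p` for the treadmilling profile,
#'   micrometres (default 1.5).
#' @param n_grid grid resolution.
#' @param use_fit evaluate `n(s)` from the parametric fit (default) or the
#'   raw histogram.
#' @return object of class `speed_profile`: grid `s`, speed `v` (um/min,
#'   positive toward the pole), treadmilling speed `v_tread`, tubulin speed
#'   `v_tub`, the inputs, and interpolating functions `v_fun`, `v_tub_fun`.
#' @export
solve_speed <- function(profile, model = recruitment_nucleate(), r = 0.4,
                        s_kin = NULL, s_pole = 1.5, n_grid = 400,
                        use_fit = TRUE) {
  stopifnot(inherits(model, "recruitment_model"), r > 0)
  s_kin <- s_kin %||% profile$s_max
  s <- seq(0, s_kin, length.out = n_grid)
  n <- profile_density(profile, s, use_fit = use_fit)
  if (any(n < 0)) stop_kfiber("negative minus-end density")
  total_n <- cumtrapz(s, n)[n_grid]

  jraw <- model$j(s)
  f <- model$fraction_captured
  j <- if (f > 0 && any(jraw > 0)) {
    jraw * f * r * total_n / cumtrapz(s, jraw)[n_grid]
  } else rep(0, n_grid)

  flux <- cumtrapz(s, r * n - j)
  tiny <- n <= 1e-9 * max(n)
  v <- ifelse(tiny, NA_real_, flux / n)
  if (any(tiny))
    warning("minus-end density ~ 0 on part of the domain; speed masked there")
  v <- pmax(v, 0)

  sp <- structure(list(s = s, v = v, n = n, j = j, r = r,
                       s_kin = s_kin, s_pole = s_pole,
                       fraction_captured = f,
                       model_kind = model$kind),
                  class = "speed_profile")
  treadmill_profile(sp, s_pole)
}

#' Add the pole treadmilling profile to a speed profile
#'
#' Minus-end depolymerases act only in the pole region (`s <= s_p`). There,
#' tubulin continues to incorporate at the plus end at the speed it had at
#' the pole boundary, so it treadmills through the KMT at
#' `v_tread(s) = max(0, v(s_p) - v(s))` for `s <= s_p` and 0 beyond; the
#' tubulin speed is `v_tub = v + v_tread`, constant and equal to `v(s_p)`
#' throughout the pole region.
#'
#' @param sp a `speed_profile`.
#' @param s_pole pole-region boundary, micrometres.
#' @return the profile with `v_tread`, `v_tub`, `v_fun`, `v_tub_fun` set.
#' @export
treadmill_profile <- function(sp, s_pole = sp$s_pole %||% 1.5) {
  stopifnot(inherits(sp, "speed_profile"))
  v_at_sp <- stats::approx(sp$s, sp$v, xout = s_pole, rule = 2)$y
  vt <- ifelse(sp$s <= s_pole, pmax(0, v_at_sp - sp$v), 0)
  sp$s_pole <- s_pole
  sp$v_tread <- vt
  sp$v_tub <- sp$v + vt
  ok <- !is.na(sp$v)
  sp$v_fun <- stats::approxfun(sp$s[ok], sp$v[ok], rule = 2)
  sp$v_tub_fun <- stats::approxfun(sp$s[ok], sp$v_tub[ok], rule = 2)
  sp
}

#' @export
print.speed_profile <- function(x, ...) {
  cat(sprintf("Minus-end speed profile (%s recruitment, r = %.3g /min)\n",
              x$model_kind, x$r))
  cat(sprintf("  domain: s in [0, %.3g] um; pole region s <= %.3g um\n",
              x$s_kin, x$s_pole))
  cat(sprintf("  v at mid-spindle: %.3g um/min; v_tub in pole region: %.3g um/min\n",
              x$v_fun(x$s_kin / 2), x$v_tub_fun(0)))
  invisible(x)
}

#' @export
plot.speed_profile <- function(x, ...) {
  graphics::plot(x$s, x$v, type = "l", xlab = "s (um from pole)",
                 ylab = "speed (um/min)", ...)
  graphics::lines(x$s, x$v_tub, col = 2)
  graphics::abline(v = x$s_pole, lty = 3)
  graphics::legend("topleft", c("v (minus end)", "v_tub (tubulin)"),
                   col = 1:2, lty = 1, bty = "n")
  invisible(x)
}

#' Residual of the steady-state balance equation
#'
#' Substitutes `(n, v, j, r)` back into the conservative form
#' `d(n v)/ds = r n - j` and returns the maximum absolute residual relative
#' to the dominant term. The derivative and source are discretised
#' consistently (interval difference of the flux against the trapezoidal
#' interval mean of the source), so an exact steady state has residual at
#' rounding level regardless of grid resolution.
#'
#' @param sp a `speed_profile`.
#' @return maximum relative residual (dimensionless).
#' @export
flux_residual <- function(sp) {
  ok <- !is.na(sp$v)
  s <- sp$s[ok]; nv <- sp$n[ok] * sp$v[ok]
  rhs <- sp$r * sp$n[ok] - sp$j[ok]
  m <- length(s)
  ds <- diff(s)
  dnv <- diff(nv) / ds
  src <- (rhs[-1] + rhs[-m]) / 2
  dom <- max(abs(rhs))
  max(abs(dnv - src)) / dom
}
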