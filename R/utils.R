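# Internal angular helpers. Nematic (headless) angles live on (-pi/2, pi/2];
# differences are always taken modulo pi.

# wrap an angle (or difference) into (-pi/2, pi/2]
wrap_nematic <- function(x) {
  y <- (x + pi / 2) %% pi
  # map 0 -> pi so that -pi/2 wraps to +pi/2 (half-open interval)
  y[y == 0] <- pi
  y - pi / 2
}

# wrap into (-pi, pi]
wrap_circular <- function(x) {
  y <- (x + pi) %% (2 * pi)
  y[y == 0] <- 2 * pi
  y - pi
}

# von Mises sampler (Best & Fisher 1979 rejection scheme); kappa = 0 gives
# the uniform circular distribution, kappa = Inf a point mass at mu.
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (n == 0) return(numeric(0))
  if (!is.finite(kappa)) return(rep(mu, n))
  if (kappa < 1e-10) return(stats::runif(n, -pi, pi) + mu)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    k <- sum(ok)
    if (k > 0) {
      out[got + seq_len(k)] <- sign(u3[ok] - 0.5) * acos(f[ok])
      got <- got + k
    }
  }
  wrap_circular(out + mu)
}

# squared Euclidean distances between rows of a and rows of b
cross_dist2 <- function(a, b) {
  outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * a %*% t(b)
}

# cumulative trapezoid integral of y over x, starting at 0
cumtrapz <- function(x, y) {
  n <- length(x)
  c(0, cumsum(diff(x) * (y[-1] + y[-n]) / 2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_kfiber <- function(...) stop(..., call. = FALSE)
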