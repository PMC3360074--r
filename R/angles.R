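# Circular helpers shared across the package. Directions are full-circle
# (0, 2*pi], never orientations mod pi: a contour travels along its edges, and
# collapsing direction to orientation would let the creation process turn
# around by 180 degrees.

#' Wrap angles
#'
#' `wrap_pi()` maps angles to the half-open interval (-pi, pi] (the convention
#' used for viewing angles and direction differences); `wrap_2pi()` maps to
#' \[0, 2*pi) (the convention used for stored edge directions).
#'
#' @param x Numeric vector of angles in radians.
#' @return Numeric vector of wrapped angles.
#' @examples
#' wrap_pi(c(pi, -pi, 3 * pi / 2))
#' wrap_2pi(-pi / 2)
#' @export
wrap_pi <- function(x) {
  r <- x %% (2 * pi)
  r[r > pi] <- r[r > pi] - 2 * pi
  r
}

#' @rdname wrap_pi
#' @export
wrap_2pi <- function(x) x %% (2 * pi)

#' Von Mises density
#'
#' Density of the von Mises distribution parametrized by an angular scale
#' `sigma` rather than the concentration: `kappa = 1 / sigma^2`, so that for
#' small `sigma` the density approaches a Gaussian with standard deviation
#' `sigma` wrapped on the circle.
#'
#' @param x Angles (radians) at which to evaluate the density.
#' @param mu Circular mean (radians).
#' @param sigma Angular scale in radians, strictly positive.
#' @return Density values; the density integrates to 1 over any interval of
#'   length `2*pi`.
#' @examples
#' von_mises_density(0, mu = 0, sigma = 0.3)
#' @export
von_mises_density <- function(x, mu = 0, sigma) {
  check_positive_scalar(sigma, "sigma")
  kappa <- 1 / sigma^2
  # exponentially-scaled Bessel keeps large kappa (small sigma) finite
  exp(kappa * (cos(x - mu) - 1)) / (2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
}

# Best & Fisher (1979) rejection sampler; exact for all concentrations.
rvon_mises <- function(n, mu = 0, sigma) {
  check_positive_scalar(sigma, "sigma")
  kappa <- 1 / sigma^2
  if (n == 0L) return(numeric(0))
  if (kappa < 1e-8) return(wrap_pi(runif(n, -pi, pi) + mu))
  tau <- 1 + sqrt(1 + 4 * kappa^2)
  rho <- (tau - sqrt(2 * tau)) / (2 * kappa)
  r <- (1 + rho^2) / (2 * rho)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    u2 <- runif(m)
    ok <- (c0 * (2 - c0) - u2 > 0) | (log(c0 / u2) + 1 - c0 >= 0)
    k <- sum(ok)
    if (k > 0L) {
      sgn <- sign(runif(k) - 0.5)
      out[(got + 1L):(got + k)] <- sgn * acos(f[ok])
      got <- got + k
    }
  }
  wrap_pi(out + mu)
}

# Quantile function via fine-grid CDF inversion (used for equal-probability
# binning in goodness-of-fit checks).
qvon_mises <- function(p, mu = 0, sigma, n_grid = 4096L) {
  grid <- seq(-pi, pi, length.out = n_grid + 1L)
  dens <- von_mises_density(grid, mu = 0, sigma = sigma)
  mids <- cumsum((dens[-1] + dens[-length(dens)]) / 2 * diff(grid))
  cdf <- c(0, mids / mids[length(mids)])
  wrap_pi(stats::approx(cdf, grid, xout = p, ties = "ordered")$y + mu)
}

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single finite value > 0.", name),
          class = "afield_parameter_error")
  }
  invisible(x)
}
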