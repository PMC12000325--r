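#' Wrap angles into (-pi, pi]
#'
#' @param x angles in radians.
#' @return angles wrapped into `(-pi, pi]`.
#' @export
wrap_angle <- function(x) {
  need <- !(x > -pi & x <= pi)
  if (any(need, na.rm = TRUE)) {
    y <- (x[need] + pi) %% (2 * pi) - pi
    # map the -pi representative to +pi so the range is (-pi, pi]
    y[y == -pi] <- pi
    x[need] <- y
  }
  x
}

#' Circular distance between two angles
#'
#' Absolute angular separation, i.e. `|wrap(a - b)|`, always in `[0, pi]`.
#'
#' @param a,b angles in radians (vectorised).
#' @return distances in `[0, pi]`.
#' @export
circular_distance <- function(a, b) abs(wrap_angle(a - b))

#' Circular mean of a set of angles
#'
#' Mean direction of the resultant vector. Undefined (error) when the
#' resultant length falls below `tol`, e.g. for perfectly balanced angles.
#'
#' @param theta angles in radians, or complex phase vectors.
#' @param tol minimal resultant length (mean vector modulus) considered
#'   defined; default `1e-12`.
#' @return the mean angle in `(-pi, pi]`.
#' @export
circ_mean <- function(theta, tol = 1e-12) {
  z <- if (is.complex(theta)) theta / Mod(theta) else exp(1i * theta)
  r <- mean(z)
  if (Mod(r) < tol) {
    stop("circular mean undefined: resultant length below tolerance")
  }
  Arg(r)
}

#' Sample from a von Mises distribution
#'
#' Best & Fisher (1979) rejection sampler. `kappa = 0` falls back to the
#' uniform distribution on the circle.
#'
#' @param n number of draws.
#' @param mu mean direction (radians).
#' @param kappa concentration (>= 0).
#' @return `n` angles in `(-pi, pi]`.
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 0) stop_cfg("`kappa` must be >= 0")
  if (kappa < 1e-10) return(wrap_angle(runif(n, -pi, pi)))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- runif(1); u2 <- runif(1); u3 <- runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (u2 < cc * (2 - cc) || log(cc) - log(u2) + 1 - cc >= 0) {
      out[i] <- mu + sign(u3 - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  wrap_angle(out)
}
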