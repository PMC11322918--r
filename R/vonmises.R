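#' Sample from a von Mises distribution
#'
#' Best & Fisher (1979) wrapped-Cauchy rejection sampler. `kappa = 0`
#' degenerates to the uniform circular distribution; `kappa = Inf` to a
#' point mass at `mu`.
#'
#' @param n Number of draws.
#' @param mu Mean direction (radians).
#' @param kappa Concentration (>= 0).
#' @return Angles in radians, wrapped to `[0, 2*pi)`.
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  stopifnot(n >= 0, kappa >= 0)
  if (n == 0) return(numeric(0))
  if (!is.finite(kappa)) return(rep((mu %% (2 * pi)), n))
  if (kappa < 1e-9) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- stats::runif(1); u2 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      u3 <- stats::runif(1)
      out[i] <- mu + sign(u3 - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  out %% (2 * pi)
}

#' Sample axial angles (degrees) from a doubled-angle von Mises
#'
#' Fiber orientations are axial: theta and theta + 180 deg are the same
#' fiber. The standard model doubles the angle, samples a von Mises with
#' mean `2 * mean_angle` and concentration `kappa`, and halves the result.
#'
#' @param n Number of angles.
#' @param mean_angle Mean orientation (degrees, axial).
#' @param kappa Concentration of the doubled-angle von Mises.
#' @return Angles in degrees, wrapped to `[0, 180)`.
#' @export
sample_axial_angles <- function(n, mean_angle = 90, kappa = 2) {
  doubled <- rvonmises(n, mu = 2 * mean_angle * pi / 180, kappa = kappa)
  wrap_axial(doubled * 90 / pi)
}
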