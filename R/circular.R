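# Circular helpers shared by orientation and polarity analyses.
# Degrees at the interface, radians internally; wrap-around by modular
# arithmetic, never clamping.

wrap_360 <- function(deg) deg %% 360          # [0, 360)
wrap_180 <- function(deg) deg %% 180          # [0, 180) axial
wrap_signed <- function(deg) {                # (-180, 180]
  out <- deg %% 360
  out[out > 180] <- out[out > 180] - 360
  out
}

#' Mean resultant length of a von Mises distribution
#'
#' `A1(kappa) = I1(kappa) / I0(kappa)`, the population value of the mean
#' resultant length (and hence of the polarity index) for a von Mises sample
#' with concentration `kappa`. Used as the closed-form target in
#' parameter-recovery checks.
#'
#' @param kappa concentration parameter (>= 0).
#' @return mean resultant length in [0, 1).
#' @export
von_mises_resultant <- function(kappa) {
  stopifnot(all(kappa >= 0))
  # scaled Bessel ratio is stable for large kappa
  besselI(kappa, 1, expon.scaled = TRUE) / besselI(kappa, 0, expon.scaled = TRUE)
}

#' Draw from a von Mises distribution
#'
#' Best–Fisher rejection sampler for the circular normal distribution with
#' mean direction `mu_deg` and concentration `kappa`. `kappa = 0` reduces to
#' the uniform distribution on the circle.
#'
#' @param n number of draws.
#' @param mu_deg mean direction in degrees.
#' @param kappa concentration (>= 0).
#' @return angles in degrees in (-180, 180].
#' @export
rvonmises_deg <- function(n, mu_deg = 0, kappa = 1) {
  stopifnot(n >= 0, kappa >= 0)
  if (n == 0) return(numeric(0))
  if (kappa < 1e-10) return(wrap_signed(stats::runif(n, 0, 360)))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(16L, ceiling((n - length(out)) * 1.5))
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    zz <- cos(pi * u1)
    f <- (1 + r * zz) / (r + zz)
    cc <- kappa * (r - f)
    keep <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    th <- sign(u3[keep] - 0.5) * acos(pmin(pmax(f[keep], -1), 1))
    out <- c(out, th)
  }
  wrap_signed(mu_deg + rad2deg(out[seq_len(n)]))
}
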