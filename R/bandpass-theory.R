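#' Band-pass specification
#'
#' Describes a band-pass filter's frequency band. The central frequency uses
#' the arithmetic-midpoint convention, `f0 = (f_low + f_high) / 2`, under
#' which the bands 0.1-10, 0.1-5 and 0.1-2 Hz have central frequencies of
#' approximately 5, 2.5 and 1 Hz and a quality factor of about 0.5 each.
#' The quality factor is `Q = f0 / (f_high - f_low)`.
#'
#' @param f_low lower cutoff frequency, Hz (>= 0; exactly 0 only in the
#'   degenerate Q = 0.5 case used by the closed-form theory).
#' @param f_high upper cutoff frequency, Hz (> f_low).
#' @return object of class `band_spec` with fields `f_low`, `f_high`, `f0`,
#'   `delta_f`, `q`.
#' @examples
#' band_spec(0.1, 10)  # f0 = 5.05 Hz, Q = 0.51
#' band_spec_center(5, 0.5)  # the widest band centred on 5 Hz
#' @export
band_spec <- function(f_low, f_high) {
  stopifnot(is.numeric(f_low), is.numeric(f_high),
            length(f_low) == 1, length(f_high) == 1)
  if (!(f_low >= 0 && f_high > f_low))
    stop("band_spec requires 0 <= f_low < f_high")
  delta_f <- f_high - f_low
  f0 <- (f_low + f_high) / 2
  structure(
    list(f_low = f_low, f_high = f_high, f0 = f0,
         delta_f = delta_f, q = f0 / delta_f),
    class = "band_spec"
  )
}

#' @rdname band_spec
#' @param f0 central frequency, Hz (> 0).
#' @param q quality factor (>= 0.5 for the closed-form phase/delay branch).
#' @export
band_spec_center <- function(f0, q) {
  stopifnot(is.numeric(f0), is.numeric(q), length(f0) == 1, length(q) == 1)
  if (f0 <= 0 || q <= 0) stop("f0 and q must be positive")
  delta_f <- f0 / q
  if (f0 - delta_f / 2 < 0)
    stop("q < 0.5 implies a negative lower cutoff for this f0")
  band_spec(f0 - delta_f / 2, f0 + delta_f / 2)
}

#' @export
print.band_spec <- function(x, ...) {
  cat(sprintf("band-pass %.3g-%.3g Hz  (f0 = %.4g Hz, bandwidth = %.4g Hz, Q = %.4g)\n",
              x$f_low, x$f_high, x$f0, x$delta_f, x$q))
  invisible(x)
}

check_q_branch <- function(band) {
  if (band$q < 0.5)
    stop("quality factor Q = ", signif(band$q, 4),
         " < 0.5: sqrt(4*Q^2 - 1) is not real; closed-form phase/delay ",
         "expressions are restricted to Q >= 0.5")
  invisible(band)
}

#' Transfer function of the idealized second-order band-pass filter
#'
#' Evaluates the complex frequency response
#' \deqn{H(s) = \frac{(\omega_0/Q)\, s}{s^2 + (\omega_0/Q)\, s + \omega_0^2},
#'   \quad s = j\omega,}
#' where \eqn{\omega_0 = 2\pi f_0} is the angular central frequency of the
#' passband and Q the quality factor. Gain is exactly 1 with zero phase at
#' `f = f0` and 0 at DC.
#'
#' @param band a [band_spec].
#' @param f frequency (or vector of frequencies), Hz, all >= 0.
#' @return complex vector of responses.
#' @export
bp_transfer_function <- function(band, f) {
  stopifnot(inherits(band, "band_spec"), is.numeric(f))
  if (any(f < 0)) stop("negative frequency")
  w0 <- 2 * pi * band$f0
  s <- 1i * 2 * pi * f
  (w0 / band$q) * s / (s^2 + (w0 / band$q) * s + w0^2)
}

#' Phase response of the second-order band-pass filter
#'
#' Closed form for the argument of [bp_transfer_function]:
#' \deqn{\phi(\omega) = \pi/2
#'   - \arctan\!\big(2Q\omega/\omega_0 + \sqrt{4Q^2-1}\big)
#'   - \arctan\!\big(2Q\omega/\omega_0 - \sqrt{4Q^2-1}\big).}
#' The result is wrapped to \eqn{(-\pi, \pi]}; the expression itself already
#' lies in \eqn{(-\pi/2, \pi/2]}, running from \eqn{+\pi/2} at DC through 0 at
#' resonance to \eqn{-\pi/2} at high frequency. Requires `Q >= 0.5` so the
#' square root is real.
#'
#' @inheritParams bp_transfer_function
#' @return phase in radians.
#' @export
bp_phase_response <- function(band, f) {
  stopifnot(inherits(band, "band_spec"), is.numeric(f))
  if (any(f < 0)) stop("negative frequency")
  check_q_branch(band)
  q <- band$q
  r <- sqrt(4 * q^2 - 1)
  u <- 2 * q * f / band$f0           # 2*Q*omega/omega0 (f ratio == omega ratio)
  phi <- pi / 2 - atan(u + r) - atan(u - r)
  ((phi + pi) %% (2 * pi)) - pi      # wrap to (-pi, pi]
}

#' Analytic group delay of the second-order band-pass filter
#'
#' Closed form for \eqn{\tau_g(\omega) = -d\phi/d\omega}:
#' \deqn{\tau_g(\omega) = \frac{2Q}{\omega_0}\left(
#'   \frac{1}{1 + \big(2Q\omega/\omega_0 + \sqrt{4Q^2-1}\big)^2} +
#'   \frac{1}{1 + \big(2Q\omega/\omega_0 - \sqrt{4Q^2-1}\big)^2}\right).}
#' Strictly positive for all frequencies; at DC it reduces to
#' \eqn{1/(Q\,\omega_0)}. For a fixed Q the low-frequency delay grows as the
#' central frequency falls, which is why narrowing a PPG pass band (lowering
#' f0) delays the pulse wave more.
#'
#' @inheritParams bp_transfer_function
#' @return group delay in seconds.
#' @export
group_delay_analytic <- function(band, f) {
  stopifnot(inherits(band, "band_spec"), is.numeric(f))
  if (any(f < 0)) stop("negative frequency")
  check_q_branch(band)
  q <- band$q
  w0 <- 2 * pi * band$f0
  r <- sqrt(4 * q^2 - 1)
  u <- 2 * q * f / band$f0
  (2 * q / w0) * (1 / (1 + (u + r)^2) + 1 / (1 + (u - r)^2))
}

#' Group delay from sampled phase by numerical differentiation
#'
#' Estimates \eqn{\tau_g = -d\phi/d\omega} from phase samples on an angular
#' frequency grid. The phase is unwrapped before differencing; interior points
#' use central differences, the two edge points one-sided differences.
#'
#' @param phase phase samples, radians (may be wrapped).
#' @param omega strictly increasing angular frequency grid, rad/s, length >= 3.
#' @return group delay in seconds at each grid point.
#' @export
group_delay_numeric <- function(phase, omega) {
  stopifnot(is.numeric(phase), is.numeric(omega),
            length(phase) == length(omega))
  if (length(omega) < 3) stop("need at least 3 grid points")
  if (any(diff(omega) <= 0)) stop("omega grid must be strictly increasing")
  phi <- signal::unwrap(phase)
  n <- length(phi)
  tau <- numeric(n)
  tau[1] <- -(phi[2] - phi[1]) / (omega[2] - omega[1])
  tau[n] <- -(phi[n] - phi[n - 1]) / (omega[n] - omega[n - 1])
  i <- 2:(n - 1)
  tau[i] <- -(phi[i + 1] - phi[i - 1]) / (omega[i + 1] - omega[i - 1])
  tau
}
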