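#' Digital IIR band-pass filter specification
#'
#' Describes one cell of the filter grid: family, overall band-pass order,
#' band, sampling rate and ripple/attenuation parameters. "Order" is the
#' band-pass order: an order-N band-pass has N poles, i.e. it is derived from
#' a low-pass prototype of order N/2.
#'
#' Ripple parameters are never hidden defaults of the design backend: the
#' passband ripple (Chebyshev I, Elliptic) defaults to 1 dB and the stopband
#' attenuation (Chebyshev II, Elliptic) to 40 dB, both settable here. Note the
#' Chebyshev II convention: its band edges are the *stopband* edges, so a
#' "0.1-10 Hz" Chebyshev II filter has a much narrower passband than the other
#' families — this is exactly why it distorts the pulse waveform so strongly.
#'
#' @param family one of `"butterworth"`, `"bessel"`, `"elliptic"`,
#'   `"chebyshev1"`, `"chebyshev2"`.
#' @param order even integer >= 2 (2, 4 and 6 in the study grid).
#' @param band a [band_spec]; `f_high` must be below `fs / 2`.
#' @param fs sampling rate, Hz.
#' @param passband_ripple_db passband ripple, dB (Chebyshev I, Elliptic).
#' @param stopband_atten_db stopband attenuation, dB (Chebyshev II, Elliptic).
#' @param bessel_norm Bessel prototype normalization: `"delay"` (Thomson's
#'   convention; unit DC delay, maximally flat delay, -3 dB point above the
#'   nominal band edge) or `"mag"` (-3 dB at the band edges, like the other
#'   families).
#' @return object of class `filter_spec`.
#' @export
filter_spec <- function(family = c("butterworth", "bessel", "elliptic",
                                   "chebyshev1", "chebyshev2"),
                        order, band, fs,
                        passband_ripple_db = 1, stopband_atten_db = 40,
                        bessel_norm = c("delay", "mag")) {
  family <- match.arg(family)
  stopifnot(inherits(band, "band_spec"), is.numeric(order), is.numeric(fs))
  order <- as.integer(order)
  if (order < 2L || order %% 2L != 0L)
    stop("band-pass order must be an even integer >= 2")
  if (band$f_high >= fs / 2)
    stop("upper cutoff must lie below the Nyquist frequency fs/2")
  structure(
    list(family = family, order = order, band = band, fs = fs,
         passband_ripple_db = passband_ripple_db,
         stopband_atten_db = stopband_atten_db,
         bessel_norm = match.arg(bessel_norm)),
    class = "filter_spec"
  )
}

#' @export
print.filter_spec <- function(x, ...) {
  cat(sprintf("%s band-pass, order %d, %.3g-%.3g Hz at fs = %g Hz\n",
              x$family, x$order, x$band$f_low, x$band$f_high, x$fs))
  invisible(x)
}

# Reverse Bessel polynomial coefficients theta_n(s), ascending powers:
# a_k = (2n-k)! / (2^(n-k) k! (n-k)!), k = 0..n.
reverse_bessel_coefs <- function(n) {
  k <- 0:n
  exp(lfactorial(2 * n - k) - (n - k) * log(2) - lfactorial(k) - lfactorial(n - k))
}

# Analog Bessel low-pass prototype in zero-pole-gain form.
# norm = "delay": Thomson's normalization (as in MATLAB's besself) — poles
# are the reverse Bessel polynomial roots unchanged, giving unit group delay
# at DC and maximally flat delay; the -3 dB point then lies above the
# nominal edge (1.36 rad/s at order 2, 1.76 at order 3), so the realized
# band-pass keeps its delay flat across the pass band.
# norm = "mag": poles rescaled so the -3 dB point sits at 1 rad/s, making
# the band edges directly comparable with the other families at the cost of
# some delay flatness.
bessel_prototype <- function(n, norm = c("delay", "mag")) {
  norm <- match.arg(norm)
  p <- polyroot(reverse_bessel_coefs(n))
  k <- Re(prod(-p))
  if (norm == "mag") {
    gain_at <- function(w) Mod(k / prod(1i * w - p))
    w3 <- stats::uniroot(function(w) gain_at(w) - 1 / sqrt(2),
                         interval = c(1e-3, 10), tol = 1e-12)$root
    p <- p / w3
  }
  signal::Zpg(zero = complex(0), pole = p, gain = Re(prod(-p)))
}

# Closed-form order-1 analog prototypes for families whose generic design
# routines in `signal` mis-handle the degenerate first order.
order1_prototype <- function(family, rp, rs) {
  a <- switch(family,
    # first-order Chebyshev II: attenuation rs at the stopband edge w = 1
    chebyshev2 = 1 / sqrt(10^(rs / 10) - 1),
    # first-order elliptic degenerates to first-order Chebyshev I:
    # passband ripple rp at w = 1
    elliptic = 1 / sqrt(10^(rp / 10) - 1),
    stop("no order-1 prototype for ", family))
  signal::Zpg(zero = complex(0), pole = complex(real = -a), gain = a)
}

# Normalized analog low-pass prototype (cutoff 1 rad/s) in zero-pole-gain
# form. Only prototype polynomials of degree <= order/2 are ever rooted;
# the band transform and bilinear discretization then stay in factored form,
# which keeps high-order band-pass designs numerically exact.
analog_prototype <- function(family, n, rp, rs, bessel_norm = "delay") {
  switch(family,
    butterworth = {
      k <- seq_len(n)
      p <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
      signal::Zpg(zero = complex(0), pole = p, gain = Re(prod(-p)))
    },
    bessel = bessel_prototype(n, bessel_norm),
    chebyshev1 = signal::as.Zpg(signal::cheby1(n, rp, 1, "low", plane = "s")),
    chebyshev2 = if (n == 1) order1_prototype("chebyshev2", rp, rs)
      else signal::as.Zpg(signal::cheby2(n, rs, 1, "low", plane = "s")),
    elliptic = if (n == 1) order1_prototype("elliptic", rp, rs)
      else signal::as.Zpg(signal::ellip(n, rp, rs, 1, "low", plane = "s"))
  )
}

# Band transform + bilinear discretization of an analog low-pass prototype.
prototype_to_digital <- function(proto, band, fs) {
  w_warp <- 2 * fs * tan(pi * c(band$f_low, band$f_high) / fs)
  bp <- signal::sftrans(proto, W = w_warp, stop = FALSE)
  signal::bilinear(bp, T = 1 / fs)
}

# Group roots into conjugate pairs (and pair up leftover reals). Robust to
# polyroot noise: roots within a magnitude-relative tolerance of the real
# axis count as real; each positive-imaginary root is symmetrized with its
# exact conjugate and its (noisy) negative-imaginary partner consumed.
# Returns a list of length-1 or length-2 complex vectors.
conjugate_pairs <- function(v, tol = 1e-6) {
  if (length(v) == 0) return(list())
  is_real <- abs(Im(v)) <= tol * pmax(1, Mod(v))
  reals <- sort(Re(v[is_real]))
  cplx <- v[!is_real]
  pos <- cplx[Im(cplx) > 0]
  neg <- cplx[Im(cplx) < 0]
  pairs <- list()
  for (p in pos) {
    pairs <- c(pairs, list(c(p, Conj(p))))
    if (length(neg)) neg <- neg[-which.min(Mod(neg - Conj(p)))]
  }
  for (q in neg) pairs <- c(pairs, list(c(Conj(q), q)))
  i <- 1
  while (i + 1 <= length(reals)) {
    pairs <- c(pairs, list(complex(real = reals[c(i, i + 1)])))
    i <- i + 2
  }
  if (i == length(reals)) pairs <- c(pairs, list(complex(real = reals[i])))
  pairs
}

poly_from_roots <- function(r) {
  if (length(r) == 0) return(1)
  if (length(r) == 1) return(Re(c(1, -r)))
  Re(c(1, -(r[1] + r[2]), r[1] * r[2]))
}

# Convert zero-pole-gain form to cascaded second-order sections.
# Pole pairs are ordered with those closest to the unit circle applied last;
# each is matched with the nearest remaining zero pair. Overall gain goes into
# the first section.
zpg_to_sos <- function(zpg) {
  z <- zpg$zero
  p <- zpg$pole
  if (length(z) > length(p)) stop("more zeros than poles")
  z <- c(z, rep(0 + 0i, length(p) - length(z)))  # pad with z = 0 (delay-free)
  ppairs <- conjugate_pairs(p)
  zpairs <- conjugate_pairs(z)
  ord <- order(vapply(ppairs, function(pp) max(Mod(pp)), numeric(1)))
  ppairs <- ppairs[ord]
  sos <- matrix(0, nrow = length(ppairs), ncol = 6)
  for (i in seq_along(ppairs)) {
    pp <- ppairs[[i]]
    ctr <- mean(pp)
    if (length(zpairs)) {
      d <- vapply(zpairs, function(zz) Mod(mean(zz) - ctr), numeric(1))
      j <- which.min(d)
      b <- poly_from_roots(zpairs[[j]])
      zpairs <- zpairs[-j]
    } else b <- 1
    a <- poly_from_roots(pp)
    sos[i, ] <- c(b, rep(0, 3 - length(b)), a, rep(0, 3 - length(a)))
  }
  sos[1, 1:3] <- sos[1, 1:3] * Re(zpg$gain)
  sos
}

#' Design a digital IIR band-pass filter
#'
#' Realizes a [filter_spec] as a stable causal digital band-pass filter in
#' cascaded-biquad (second-order-section) form. All families use the bilinear
#' transform with frequency pre-warping. Butterworth, Chebyshev I/II and
#' Elliptic designs are delegated to the `signal` package; Bessel prototypes
#' (reverse Bessel polynomial poles normalized to a -3 dB cutoff of 1 rad/s)
#' and the degenerate order-1 Chebyshev II / Elliptic prototypes are built
#' from their closed forms and then band-transformed and discretized with
#' `signal::sftrans()` / `signal::bilinear()`.
#'
#' @param spec a [filter_spec].
#' @return object of class `digital_filter`: list with `sos` (n x 6 matrix of
#'   biquad coefficients `b0 b1 b2 a0 a1 a2`), `zpg` (zeros/poles/gain) and
#'   the originating `spec`.
#' @export
design_filter <- function(spec) {
  stopifnot(inherits(spec, "filter_spec"))
  n <- spec$order %/% 2L                     # low-pass prototype order
  proto <- analog_prototype(spec$family, n, spec$passband_ripple_db,
                            spec$stopband_atten_db, spec$bessel_norm)
  zpg <- prototype_to_digital(proto, spec$band, spec$fs)
  if (max(Mod(zpg$pole)) >= 1)
    stop("designed filter is unstable (pole on or outside the unit circle)")
  structure(list(sos = zpg_to_sos(zpg), zpg = zpg, spec = spec),
            class = "digital_filter")
}

#' @export
print.digital_filter <- function(x, ...) {
  print(x$spec)
  cat(sprintf("  %d second-order section(s), max pole modulus %.6f\n",
              nrow(x$sos), max(Mod(x$zpg$pole))))
  invisible(x)
}

#' Apply a digital filter causally
#'
#' Forward-only filtering with zero initial state, section by section through
#' the biquad cascade. Output at sample n depends only on inputs at samples
#' <= n; the filter's full (frequency-dependent) group delay is therefore
#' present in the output, which is the effect under study. Never substitutes
#' forward-backward (zero-phase) filtering.
#'
#' @param filter a `digital_filter` from [design_filter].
#' @param x numeric signal (length >= 1).
#' @return filtered signal, same length as `x`.
#' @export
apply_causal <- function(filter, x) {
  stopifnot(inherits(filter, "digital_filter"))
  if (length(x) == 0) stop("empty signal")
  y <- as.numeric(x)
  for (i in seq_len(nrow(filter$sos))) {
    b <- filter$sos[i, 1:3]
    a <- filter$sos[i, 4:6]
    y <- as.numeric(signal::filter(b, a, y))
  }
  y
}

#' Complex frequency response of a designed digital filter
#'
#' @param filter a `digital_filter`.
#' @param f frequencies, Hz, within `[0, fs/2)`.
#' @return complex response at each frequency.
#' @export
filter_response <- function(filter, f) {
  stopifnot(inherits(filter, "digital_filter"))
  fs <- filter$spec$fs
  if (any(f < 0 | f >= fs / 2)) stop("frequencies must lie in [0, fs/2)")
  z1 <- exp(-1i * 2 * pi * f / fs)           # z^-1
  h <- rep(1 + 0i, length(f))
  for (i in seq_len(nrow(filter$sos))) {
    b <- filter$sos[i, 1:3]
    a <- filter$sos[i, 4:6]
    h <- h * (b[1] + b[2] * z1 + b[3] * z1^2) / (a[1] + a[2] * z1 + a[3] * z1^2)
  }
  h
}

#' Group delay of a realized digital filter
#'
#' Measures the digital filter's group delay as the negative derivative of its
#' unwrapped phase response, evaluated on a frequency grid (the same numerical
#' scheme as [group_delay_numeric]). The grid should be dense enough that the
#' phase advances by less than pi between adjacent points.
#'
#' @param filter a `digital_filter`.
#' @param f_grid strictly increasing frequency grid, Hz, inside `(0, fs/2)`.
#' @return data.frame with `freq_hz` and `tau_g_s` (group delay, seconds).
#' @export
digital_group_delay <- function(filter, f_grid) {
  stopifnot(inherits(filter, "digital_filter"))
  fs <- filter$spec$fs
  if (any(f_grid <= 0 | f_grid >= fs / 2))
    stop("frequency grid must lie strictly inside (0, fs/2)")
  h <- filter_response(filter, f_grid)
  tau <- group_delay_numeric(Arg(h), 2 * pi * f_grid)
  data.frame(freq_hz = f_grid, tau_g_s = tau)
}
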