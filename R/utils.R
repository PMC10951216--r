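#' Centered moving average with shrunken edge windows
#'
#' Computes a symmetric moving average of width `n` samples. Interior samples
#' average over `floor((n-1)/2)` points to the left and `ceiling((n-1)/2)` to
#' the right; near the edges the window is truncated to the available samples,
#' so no phase shift is introduced anywhere.
#'
#' @param x numeric vector.
#' @param n window width in samples (>= 1).
#' @return numeric vector, same length as `x`.
#' @keywords internal
moving_average <- function(x, n) {
  stopifnot(is.numeric(x), length(x) >= 1)
  n <- as.integer(round(n))
  if (n < 1) stop("moving average window must span at least 1 sample")
  if (n == 1) return(x)
  len <- length(x)
  left <- (n - 1L) %/% 2L
  right <- n - 1L - left
  cs <- cumsum(c(0, x))
  i <- seq_len(len)
  lo <- pmax(i - left, 1L)
  hi <- pmin(i + right, len)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Indices of strict interior local maxima
#' @keywords internal
local_maxima <- function(x) {
  d <- diff(x)
  which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
}

#' Indices of strict interior local minima
#' @keywords internal
local_minima <- function(x) {
  d <- diff(x)
  which(d[-length(d)] < 0 & d[-1] >= 0) + 1L
}

#' Two-sided periodogram in per-bin power units
#'
#' Power per frequency bin, `|FFT|^2 / n^2`, so a pure sinusoid of amplitude A
#' contributes A^2/4 at its bin and white noise of variance s^2 a flat floor
#' of s^2/n per bin. Used both to calibrate the generator's noise level and to
#' verify it, so that decibel levels quoted relative to the systolic spectral
#' peak are self-consistent.
#'
#' @param x numeric signal.
#' @param fs sampling rate, Hz.
#' @return data.frame with columns `freq_hz`, `power` (positive frequencies,
#'   DC excluded).
#' @export
ppg_periodogram <- function(x, fs) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2 / n^2
  k <- seq_len(floor(n / 2))
  data.frame(freq_hz = k * fs / n, power = p[k + 1L])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
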