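#' Estimate the DC component of a PPG signal by moving average
#'
#' The slowly varying (DC) component is the centered moving average over a
#' window of `round(window_s * fs)` samples — 320 samples for the default 1 s
#' window at 320 Hz. Edge windows shrink to the available samples.
#'
#' @param x numeric signal.
#' @param fs sampling rate, Hz.
#' @param window_s window width, seconds.
#' @return DC series, same length as `x`.
#' @export
estimate_dc <- function(x, fs, window_s = 1.0) {
  if (length(x) == 0) stop("empty signal")
  n <- round(window_s * fs)
  if (n < 1) stop("DC window must span at least 1 sample")
  moving_average(x, n)
}

new_ppg_signal <- function(samples, fs, stage, provenance) {
  structure(list(samples = samples, fs = fs, stage = stage,
                 provenance = provenance),
            class = "ppg_signal")
}

#' @export
print.ppg_signal <- function(x, ...) {
  cat(sprintf("ppg_signal [%s]: %d samples at %g Hz (%s)\n",
              x$stage, length(x$samples), x$fs,
              paste(x$provenance, collapse = " -> ")))
  invisible(x)
}

as_samples <- function(x) {
  if (inherits(x, "ppg_signal") || inherits(x, "ppg_record")) x$samples
  else as.numeric(x)
}

#' Invert a raw PPG record and remove its DC component
#'
#' Raw PPG is recorded with inverted polarity (more blood absorbs more light,
#' so pulses point downward). This step negates the raw signal and subtracts
#' its moving-average DC estimate ([estimate_dc]), yielding the pulsatile AC
#' component with systolic peaks pointing upward and near-zero local mean.
#'
#' @param raw a `ppg_record` with polarity `"raw-inverted"`, or a numeric
#'   vector (then `fs` must be given).
#' @param fs sampling rate, Hz (taken from the record when omitted).
#' @param dc_window_s DC moving-average window, seconds.
#' @return a `ppg_signal` at stage `"ac"`.
#' @export
invert_and_remove_dc <- function(raw, fs = NULL, dc_window_s = 1.0) {
  if (inherits(raw, "ppg_record")) {
    if (!identical(raw$polarity, "raw-inverted"))
      stop("record polarity is not raw-inverted")
    fs <- raw$fs
    id <- raw$id %||% "record"
    x <- raw$samples
  } else {
    if (is.null(fs)) stop("fs must be supplied for a bare numeric signal")
    id <- "signal"
    x <- as.numeric(raw)
  }
  inv <- -x
  ac <- inv - estimate_dc(inv, fs, dc_window_s)
  new_ppg_signal(ac, fs, "ac", c(id, "invert", "remove_dc"))
}

#' Smooth the AC signal into the reference signal
#'
#' The reference signal — the comparison baseline for every distortion
#' metric — is a short centered moving average (default 10 samples) of the
#' AC signal. It follows the pulse contour essentially unchanged (the
#' systolic peak moves by at most one sample) while suppressing
#' high-frequency noise by roughly the window length, and being symmetric it
#' introduces no phase shift of its own.
#'
#' @param ac a `ppg_signal` at stage `"ac"`, or numeric vector.
#' @param fs sampling rate, Hz (taken from the signal object when omitted).
#' @param window_samples moving-average window length, samples.
#' @return a `ppg_signal` at stage `"reference"`.
#' @export
smooth_reference <- function(ac, fs = NULL, window_samples = 10) {
  if (window_samples < 1) stop("window_samples must be >= 1")
  if (inherits(ac, "ppg_signal")) {
    fs <- ac$fs
    prov <- ac$provenance
    x <- ac$samples
  } else {
    if (is.null(fs)) stop("fs must be supplied for a bare numeric signal")
    prov <- "signal"
    x <- as.numeric(ac)
  }
  new_ppg_signal(moving_average(x, window_samples), fs, "reference",
                 c(prov, sprintf("smooth_ma%d", window_samples)))
}

#' Normalize a pulse signal to the systolic-wave amplitude
#'
#' Subtracts the per-record baseline (median of the detected beat-onset
#' amplitudes) and divides by the mean systolic peak amplitude above that
#' baseline, so the pulse wave nominally spans 0-1 relative units. Per-record
#' (not per-beat) scaling preserves beat-to-beat amplitude structure. The
#' transform is invariant to positive affine changes of the input, which is
#' what makes signals processed by different filters comparable.
#'
#' @param x a `ppg_signal` or numeric vector.
#' @param fs sampling rate, Hz (taken from the signal object when omitted).
#' @param beats optional beat segmentation from [detect_beats]; detected
#'   internally when omitted.
#' @return a `ppg_signal` at stage `"normalized"`.
#' @export
normalize_to_systolic <- function(x, fs = NULL, beats = NULL) {
  if (inherits(x, "ppg_signal")) {
    fs <- x$fs
    prov <- x$provenance
    sig <- x$samples
  } else {
    if (is.null(fs)) stop("fs must be supplied for a bare numeric signal")
    prov <- "signal"
    sig <- as.numeric(x)
  }
  if (is.null(beats)) beats <- detect_beats(sig, fs)
  baseline <- stats::median(sig[beats$onsets])
  as_mean <- mean(sig[beats$peaks] - baseline)
  if (!is.finite(as_mean) || as_mean <= 0)
    stop("no usable systolic amplitude found for normalization")
  new_ppg_signal((sig - baseline) / as_mean, fs, "normalized",
                 c(prov, "normalize_systolic"))
}
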