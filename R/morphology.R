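#' Detect beats (systolic peaks and pulse-foot onsets)
#'
#' Systolic peaks are local maxima exceeding an adaptive prominence threshold
#' — 40% of the local amplitude range, tracked in 2-s blocks and interpolated
#' across the record — with a minimum separation of 0.33 s (180 bpm). Each
#' beat's onset (the pulse foot) is the minimum between the preceding peak
#' and the current one.
#'
#' @param x numeric signal (>= 2 s long) with pulses pointing upward.
#' @param fs sampling rate, Hz.
#' @param min_separation_s minimum peak separation, s.
#' @param threshold_frac fraction of the rolling amplitude range a peak must
#'   exceed (above the rolling minimum).
#' @param block_s block length for the rolling range estimate, s.
#' @return list with `peaks`, `onsets` (sample indices), `peak_times`,
#'   `onset_times` (s), and `fs`.
#' @export
detect_beats <- function(x, fs, min_separation_s = 0.33,
                         threshold_frac = 0.4, block_s = 2) {
  x <- as_samples(x)
  n <- length(x)
  if (n < 2 * fs) stop("signal must be at least 2 s long")
  if (max(x) == min(x)) stop("no beats detected (flat signal)")

  # rolling amplitude range via block min/max, interpolated per sample
  nb <- max(2L, ceiling(n / round(block_s * fs)))
  edges <- floor(seq(0, n, length.out = nb + 1))
  centers <- (edges[-1] + edges[-(nb + 1)]) / 2
  bmin <- bmax <- numeric(nb)
  for (b in seq_len(nb)) {
    idx <- (edges[b] + 1):edges[b + 1]
    bmin[b] <- min(x[idx]); bmax[b] <- max(x[idx])
  }
  rmin <- stats::approx(centers, bmin, xout = seq_len(n), rule = 2)$y
  rmax <- stats::approx(centers, bmax, xout = seq_len(n), rule = 2)$y
  thr <- rmin + threshold_frac * (rmax - rmin)

  cand <- local_maxima(x)
  cand <- cand[x[cand] > thr[cand]]
  if (!length(cand)) stop("no beats detected")

  # greedy minimum-separation enforcement, tallest peaks first
  min_sep <- round(min_separation_s * fs)
  keep <- integer(0)
  for (i in cand[order(x[cand], decreasing = TRUE)]) {
    if (!length(keep) || all(abs(keep - i) >= min_sep)) keep <- c(keep, i)
  }
  peaks <- sort(keep)

  onsets <- integer(length(peaks))
  med_period <- if (length(peaks) > 1) stats::median(diff(peaks)) else n
  for (k in seq_along(peaks)) {
    from <- if (k == 1) max(1L, peaks[1] - round(1.2 * med_period)) else peaks[k - 1]
    seg <- x[from:peaks[k]]
    onsets[k] <- from + which.min(seg) - 1L
  }
  # a first beat truncated mid-upstroke has no genuine preceding trough
  # (its "onset" sits on the signal edge): drop it
  if (length(peaks) > 1 && onsets[1] <= 1L) {
    peaks <- peaks[-1]
    onsets <- onsets[-1]
  }
  list(peaks = peaks, onsets = onsets,
       peak_times = (peaks - 1) / fs, onset_times = (onsets - 1) / fs,
       fs = fs)
}

#' Detect fiducial points within one beat segment
#'
#' Within a segment running from one pulse foot to the next, finds the
#' systolic peak (global maximum), then searches between the peak and 80% of
#' the beat period for the dicrotic notch: the local minimum with the most
#' prominent rise to the first local maximum after it (the diastolic peak).
#' Amplitudes are measured above the beat's onset amplitude. The notch and
#' diastolic peak are marked absent when no interior minimum-maximum pair
#' rises by at least `presence_frac` (default 1%) of the systolic amplitude.
#'
#' @param segment numeric samples of one beat, onset first.
#' @param fs sampling rate, Hz.
#' @param presence_frac minimum notch-to-diastolic rise, as a fraction of the
#'   systolic amplitude, for the notch to count as present.
#' @return one-row data.frame: `onset_time` (0), `systolic_peak_time`,
#'   `systolic_amplitude`, `notch_time`, `diastolic_peak_time`,
#'   `diastolic_amplitude`, `notch_rise` (all times s relative to segment
#'   start, amplitudes above onset), `delta_t` (onset to notch, s).
#' @export
detect_fiducials <- function(segment, fs, presence_frac = 0.01) {
  segment <- as.numeric(segment)
  n <- length(segment)
  if (n < 5) stop("malformed beat segment")
  ip <- which.max(segment)
  if (ip <= 1 || ip >= n) stop("segment has no interior systolic peak")
  onset_amp <- segment[1]
  sys_amp <- segment[ip] - onset_amp
  if (sys_amp <= 0) stop("segment has no interior systolic peak")

  lim <- min(n, max(ip + 2L, round(0.8 * n)))
  notch_i <- NA_integer_; dia_i <- NA_integer_; best_rise <- 0
  sub <- segment[ip:lim]
  for (m in local_minima(sub)) {
    rest <- sub[m:length(sub)]
    lm <- local_maxima(rest)
    if (!length(lm)) next
    rise <- rest[lm[1]] - rest[1]
    if (rise > best_rise) {
      best_rise <- rise
      notch_i <- ip + m - 1L
      dia_i <- notch_i + lm[1] - 1L
    }
  }
  present <- !is.na(notch_i) && best_rise >= presence_frac * sys_amp
  data.frame(
    onset_time = 0,
    systolic_peak_time = (ip - 1) / fs,
    systolic_amplitude = sys_amp,
    notch_time = if (present) (notch_i - 1) / fs else NA_real_,
    diastolic_peak_time = if (present) (dia_i - 1) / fs else NA_real_,
    diastolic_amplitude = if (present) segment[dia_i] - onset_amp else NA_real_,
    notch_rise = if (present) best_rise else NA_real_,
    delta_t = if (present) (notch_i - 1) / fs else NA_real_
  )
}

#' Dawber-style classification of a beat
#'
#' Grades the prominence of the diastolic wave: class 1 has a distinct notch
#' and diastolic peak (notch-to-diastolic rise above `class1_frac` of the
#' systolic amplitude), class 2 a visible notch with a weak diastolic wave
#' (rise in `(presence, class1_frac]`), classes 3-4 no detectable notch.
#' The reflection index and compensated ejection time are computable only for
#' classes 1 and 2.
#'
#' @param fiducials a one-row data.frame from [detect_fiducials].
#' @param class1_frac rise fraction separating class 1 from class 2.
#' @return list with `class` (1, 2 or 3) and `eligible` (logical: RI/ETc
#'   computable).
#' @export
classify_dawber <- function(fiducials, class1_frac = 0.10) {
  stopifnot(is.data.frame(fiducials), nrow(fiducials) == 1)
  if (is.na(fiducials$notch_rise) || is.na(fiducials$diastolic_amplitude) ||
      is.na(fiducials$delta_t))
    return(list(class = 3L, eligible = FALSE))
  frac <- fiducials$notch_rise / fiducials$systolic_amplitude
  cls <- if (frac > class1_frac) 1L else 2L
  # amplitudes must be physiologic: 0 < A_d <= A_s
  ok <- fiducials$diastolic_amplitude > 0 &&
    fiducials$diastolic_amplitude <= fiducials$systolic_amplitude
  list(class = cls, eligible = ok)
}

#' Skewness signal quality index
#'
#' The third standardized moment of the sample distribution,
#' \deqn{S_{SQI} = \frac{1}{N}\sum_{i=1}^{N}
#'   \left[\frac{x_i - \hat\mu_x}{\sigma}\right]^3,}
#' with the empirical mean and the population (divisor-N) standard deviation.
#' Higher skewness reflects a more asymmetric, detail-rich pulse waveform;
#' the index is invariant to positive affine rescaling of the signal.
#'
#' @param x numeric signal, length >= 3, non-zero variance.
#' @return S_SQI, dimensionless.
#' @export
skewness_sqi <- function(x) {
  x <- as_samples(x)
  if (length(x) < 3) stop("need at least 3 samples")
  mu <- mean(x)
  sigma <- sqrt(mean((x - mu)^2))
  if (sigma == 0) stop("zero variance: skewness undefined")
  mean(((x - mu) / sigma)^3)
}

#' Heart rate from systolic peak times
#'
#' `60 / median(inter-beat interval)`, in beats per minute.
#'
#' @param peak_times systolic peak times, s (>= 2 beats).
#' @return heart rate, bpm.
#' @export
heart_rate <- function(peak_times) {
  if (length(peak_times) < 2) stop("need at least 2 beats for a heart rate")
  60 / stats::median(diff(sort(peak_times)))
}

#' Reflection index from per-beat fiducials
#'
#' Per beat, `100 * A_d / A_s` (diastolic over systolic amplitude, both above
#' the beat onset); the record value is the mean over eligible (Dawber class
#' 1-2) beats. A marker of peripheral arteriolar tone.
#'
#' @param fiducials data.frame of beat fiducials with columns
#'   `diastolic_amplitude`, `systolic_amplitude` and logical `eligible`.
#' @return RI in percent.
#' @export
reflection_index <- function(fiducials) {
  el <- fiducials[which(fiducials$eligible), ]
  if (nrow(el) == 0) stop("no eligible beats: reflection index undefined")
  mean(100 * el$diastolic_amplitude / el$systolic_amplitude)
}

#' Compensated ejection time from per-beat fiducials
#'
#' Per beat, \eqn{ETc = \Delta T / \sqrt{HR/60}} in ms, where \eqn{\Delta T}
#' is the time from the systolic upstroke onset to the dicrotic notch (aortic
#' valve closure); the record value is the mean over eligible beats. A
#' heart-rate-normalized surrogate for left-ventricular ejection time.
#'
#' @param fiducials data.frame of beat fiducials with columns `delta_t` (s)
#'   and logical `eligible`.
#' @param hr heart rate, bpm (> 0).
#' @return ETc in ms.
#' @export
ejection_time_compensated <- function(fiducials, hr) {
  if (hr <= 0) stop("heart rate must be positive")
  el <- fiducials[which(fiducials$eligible), ]
  if (nrow(el) == 0) stop("no eligible beats: ETc undefined")
  mean(el$delta_t * 1000) / sqrt(hr / 60)
}

#' Compute the full morphological index set of a pulse signal
#'
#' Runs the morphology chain on one processed signal: trims the filter
#' start-up transient, detects beats, normalizes to the systolic amplitude,
#' extracts per-beat fiducials and computes S_SQI (over the whole trimmed,
#' normalized record), RI, ETc and HR. RI and ETc are `NA` when no beat is
#' eligible (Dawber class 3-4 throughout, e.g. after notch-destroying
#' filtering).
#'
#' @param x a `ppg_signal`, `ppg_record`-like samples, or numeric vector.
#' @param fs sampling rate, Hz (taken from the signal object when omitted).
#' @param transient_s seconds discarded from the start before analysis
#'   (causal-filter settling).
#' @return object of class `index_set`: list with `s_sqi`, `ri_pct`,
#'   `etc_ms`, `hr_bpm`, `n_beats`, `n_eligible`, `dawber_class` (modal class
#'   over beats) and the per-beat `fiducials` data.frame (absolute times
#'   within the trimmed signal).
#' @export
compute_indices <- function(x, fs = NULL, transient_s = 2) {
  if (inherits(x, "ppg_signal")) fs <- x$fs
  if (is.null(fs)) stop("fs must be supplied for a bare numeric signal")
  sig <- as_samples(x)
  from <- round(transient_s * fs) + 1L
  if (from >= length(sig) - 2 * fs) stop("signal too short after transient trim")
  sig <- sig[from:length(sig)]

  beats <- detect_beats(sig, fs)
  norm <- normalize_to_systolic(sig, fs, beats = beats)
  y <- norm$samples

  k <- length(beats$peaks)
  fid <- NULL
  for (b in seq_len(k - 1L)) {
    seg <- y[beats$onsets[b]:beats$onsets[b + 1L]]
    row <- detect_fiducials(seg, fs)
    cls <- classify_dawber(row)
    row$dawber_class <- cls$class
    row$eligible <- cls$eligible
    # absolute times within the trimmed signal
    t0 <- (beats$onsets[b] - 1) / fs
    for (col in c("onset_time", "systolic_peak_time", "notch_time",
                  "diastolic_peak_time"))
      row[[col]] <- row[[col]] + t0
    row$beat <- b
    fid <- rbind(fid, row)
  }
  if (is.null(fid)) stop("no complete beats found")
  # drop fragments: beats with an implausibly small systolic amplitude
  fid <- fid[fid$systolic_amplitude >= 0.3 * stats::median(fid$systolic_amplitude), ]
  if (nrow(fid) == 0) stop("no complete beats found")

  hr <- heart_rate(beats$peak_times)
  n_el <- sum(fid$eligible)
  structure(
    list(
      s_sqi = skewness_sqi(y),
      ri_pct = if (n_el > 0) reflection_index(fid) else NA_real_,
      etc_ms = if (n_el > 0) ejection_time_compensated(fid, hr) else NA_real_,
      hr_bpm = hr,
      n_beats = nrow(fid),
      n_eligible = n_el,
      dawber_class = as.integer(names(which.max(table(fid$dawber_class)))),
      fiducials = fid,
      transient_s = transient_s
    ),
    class = "index_set"
  )
}

#' @export
print.index_set <- function(x, ...) {
  cat(sprintf(
    "index_set: S_SQI %.4f | RI %s | ETc %s | HR %.1f bpm | %d beats (%d eligible, class %d)\n",
    x$s_sqi,
    if (is.na(x$ri_pct)) "NA" else sprintf("%.1f%%", x$ri_pct),
    if (is.na(x$etc_ms)) "NA" else sprintf("%.0f ms", x$etc_ms),
    x$hr_bpm, x$n_beats, x$n_eligible, x$dawber_class))
  invisible(x)
}
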