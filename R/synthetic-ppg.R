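#' Beat template for the synthetic PPG generator
#'
#' One pulse is modeled as the sum of two Gaussians: a systolic (direct
#' ejection) wave and a diastolic (reflected) wave. The trough between them is
#' the dicrotic notch. The default widths make the waves overlap the way real
#' fingertip pulses do, so the notch is a shallow dip (a few percent of the
#' systolic amplitude) riding on the falling systolic limb rather than a deep
#' cleft; this overlap is what makes the notch fragile under narrow-band
#' filtering.
#'
#' @param systolic_amplitude systolic Gaussian amplitude, relative units
#'   (fixed at 1 before any scaling).
#' @param systolic_center systolic peak position, s from beat onset.
#' @param systolic_width systolic Gaussian standard deviation, s.
#' @param diastolic_amplitude_ratio diastolic-to-systolic Gaussian amplitude
#'   ratio in `[0, 1]`; roughly the true reflection index / 100.
#' @param diastolic_center diastolic wave position, s from beat onset; must
#'   exceed `systolic_center`.
#' @param diastolic_width diastolic Gaussian standard deviation, s.
#' @return object of class `beat_template`.
#' @export
beat_template <- function(systolic_amplitude = 1,
                          systolic_center = 0.15,
                          systolic_width = 0.105,
                          diastolic_amplitude_ratio = 0.45,
                          diastolic_center = 0.455,
                          diastolic_width = 0.09) {
  if (systolic_width <= 0 || diastolic_width <= 0)
    stop("Gaussian widths must be positive")
  if (systolic_amplitude <= 0) stop("systolic amplitude must be positive")
  if (diastolic_amplitude_ratio < 0 || diastolic_amplitude_ratio > 1)
    stop("diastolic_amplitude_ratio must lie in [0, 1]")
  if (diastolic_center <= systolic_center)
    stop("diastolic_center must exceed systolic_center")
  structure(
    list(systolic_amplitude = systolic_amplitude,
         systolic_center = systolic_center,
         systolic_width = systolic_width,
         diastolic_amplitude_ratio = diastolic_amplitude_ratio,
         diastolic_center = diastolic_center,
         diastolic_width = diastolic_width),
    class = "beat_template"
  )
}

#' Noise specification for the synthetic PPG generator
#'
#' Broadband and harmonic noise levels are decibels relative to the systolic
#' spectral peak of the clean signal, measured on the per-bin periodogram of
#' the generated record itself ([ppg_periodogram]), so "-90 dB" means the
#' white-noise floor sits 90 dB below the tallest cardiac line in the power
#' spectrum. Discrete mains/electronics harmonics (default 30 and 50 Hz) and
#' a slow baseline drift can be added on top.
#'
#' @param broadband_level_db white-noise floor, dB relative to the systolic
#'   spectral peak (must be negative; `-Inf` disables).
#' @param harmonic_freqs frequencies of discrete interference lines, Hz.
#' @param harmonic_level_db per-line level, dB relative to the systolic
#'   spectral peak (`-Inf` disables).
#' @param drift_freq baseline drift frequency, Hz.
#' @param drift_amplitude baseline drift amplitude, relative units
#'   (0 disables).
#' @return object of class `noise_spec`.
#' @export
noise_spec <- function(broadband_level_db = -90,
                       harmonic_freqs = c(30, 50),
                       harmonic_level_db = -80,
                       drift_freq = 0.25,
                       drift_amplitude = 0.1) {
  if (is.finite(broadband_level_db) && broadband_level_db >= 0)
    stop("broadband_level_db must be negative (a level below the signal peak)")
  structure(
    list(broadband_level_db = broadband_level_db,
         harmonic_freqs = harmonic_freqs,
         harmonic_level_db = harmonic_level_db,
         drift_freq = drift_freq,
         drift_amplitude = drift_amplitude),
    class = "noise_spec"
  )
}

beat_mixture <- function(template, t) {
  template$systolic_amplitude * (
    exp(-(t - template$systolic_center)^2 / (2 * template$systolic_width^2)) +
    template$diastolic_amplitude_ratio *
      exp(-(t - template$diastolic_center)^2 / (2 * template$diastolic_width^2)))
}

# Ground-truth fiducials of the analytic two-Gaussian mixture, from dense
# numerical evaluation (10x oversampling), independent of the beat detector.
beat_truth <- function(template, period, fs, oversample = 10) {
  tt <- seq(0, period, by = 1 / (fs * oversample))
  y <- beat_mixture(template, tt)
  onset_amp <- y[1]
  ip <- which.max(y)
  sys_time <- tt[ip]
  sys_amp <- y[ip] - onset_amp
  lim <- max(which(tt <= 0.8 * period))
  notch_time <- NA_real_; dia_time <- NA_real_; dia_amp <- NA_real_
  if (ip < lim - 2) {
    sub <- y[ip:lim]
    mins <- local_minima(sub)
    best_rise <- 0
    for (m in mins) {
      rest <- sub[m:length(sub)]
      lm <- local_maxima(rest)
      if (!length(lm)) next
      rise <- rest[lm[1]] - rest[1]
      if (rise > best_rise) {
        best_rise <- rise
        notch_time <- tt[ip + m - 1L]
        dia_time <- tt[ip + m - 1L + lm[1] - 1L]
        dia_amp <- rest[lm[1]] - onset_amp
      }
    }
    # presence rule mirrors the detector: rise >= 1% of systolic amplitude
    if (best_rise < 0.01 * sys_amp) {
      notch_time <- NA_real_; dia_time <- NA_real_; dia_amp <- NA_real_
    }
  }
  data.frame(
    onset_time = 0, systolic_peak_time = sys_time, systolic_amplitude = sys_amp,
    notch_time = notch_time, diastolic_peak_time = dia_time,
    diastolic_amplitude = dia_amp,
    delta_t = notch_time,                     # onset at t = 0
    ri_true = if (is.na(dia_amp)) NA_real_ else 100 * dia_amp / sys_amp,
    onset_amplitude = onset_amp
  )
}

#' Generate one synthetic PPG beat with ground-truth fiducials
#'
#' Samples the two-Gaussian beat model over one period and returns the exact
#' fiducial points (systolic peak, dicrotic notch, diastolic peak) implied by
#' the analytic mixture, computed by dense numerical evaluation on a 10x
#' oversampled grid — not by the beat detector under test.
#'
#' @param template a [beat_template].
#' @param fs sampling rate, Hz (> 0).
#' @param period beat period, s (> `systolic_center`).
#' @return list with `samples` (length `round(fs * period)`), `fs`, `period`
#'   and `truth` (one-row data.frame of fiducials; notch/diastolic fields are
#'   `NA` when the mixture has no interior minimum-maximum pair, e.g. for
#'   `diastolic_amplitude_ratio = 0`).
#' @export
generate_beat <- function(template, fs, period) {
  stopifnot(inherits(template, "beat_template"))
  if (fs <= 0) stop("fs must be positive")
  if (period <= template$systolic_center)
    stop("period must exceed the systolic center time")
  n <- round(fs * period)
  t <- (seq_len(n) - 1) / fs
  list(samples = beat_mixture(template, t), fs = fs, period = period,
       truth = beat_truth(template, period, fs))
}

record_clean_truth <- function(template, onsets0, periods, n, fs,
                               oversample = 10) {
  # dense clean pulse train: superposed Gaussian pulses on the global axis,
  # so consecutive beats blend smoothly through their tails
  step <- 1 / (fs * oversample)
  nd <- n * oversample
  td <- (seq_len(nd) - 1) * step
  yd <- numeric(nd)
  add_gauss <- function(center, amp, width) {
    lo <- max(1L, floor((center - 6 * width) / step) + 1L)
    hi <- min(nd, ceiling((center + 6 * width) / step) + 1L)
    if (lo > hi) return(invisible())
    idx <- lo:hi
    yd[idx] <<- yd[idx] + amp * exp(-(td[idx] - center)^2 / (2 * width^2))
  }
  sys_centers <- onsets0 + template$systolic_center
  dia_centers <- onsets0 + template$diastolic_center
  for (b in seq_along(onsets0)) {
    add_gauss(sys_centers[b], template$systolic_amplitude,
              template$systolic_width)
    add_gauss(dia_centers[b], template$systolic_amplitude *
                template$diastolic_amplitude_ratio, template$diastolic_width)
  }
  clean <- yd[seq(1, nd, by = oversample)]

  # per-beat ground-truth fiducials from the dense clean signal, measured the
  # way a detector measures: onset = trough preceding the systolic peak,
  # amplitudes above the onset amplitude
  truth <- NULL
  rec_end <- n / fs
  for (b in seq_along(onsets0)) {
    p <- periods[b]
    if (onsets0[b] + p > rec_end + 1e-9) next      # incomplete beat
    win_lo <- max(0, sys_centers[b] - 0.6 * p)
    i_lo <- floor(win_lo / step) + 1L
    i_sc <- round(sys_centers[b] / step) + 1L
    i_on <- i_lo + which.min(yd[i_lo:i_sc]) - 1L
    i_hi <- min(nd, round((td[i_on] + 0.95 * p) / step) + 1L)
    seg <- yd[i_on:i_hi]
    ip <- which.max(seg[seq_len(min(length(seg), round(0.6 * p / step)))])
    onset_amp <- seg[1]
    sys_amp <- seg[ip] - onset_amp
    lim <- min(length(seg), round(0.8 * p / step))
    notch_i <- NA_integer_; dia_i <- NA_integer_; best_rise <- 0
    sub <- seg[ip:lim]
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
    present <- !is.na(notch_i) && best_rise >= 0.01 * sys_amp
    truth <- rbind(truth, data.frame(
      beat = b,
      onset_time = td[i_on],
      systolic_peak_time = td[i_on] + (ip - 1) * step,
      systolic_amplitude = sys_amp,
      notch_time = if (present) td[i_on] + (notch_i - 1) * step else NA_real_,
      diastolic_peak_time = if (present) td[i_on] + (dia_i - 1) * step else NA_real_,
      diastolic_amplitude = if (present) seg[dia_i] - onset_amp else NA_real_,
      notch_rise = if (present) best_rise else NA_real_,
      delta_t = if (present) (notch_i - 1) * step else NA_real_,
      ri_true = if (present) 100 * (seg[dia_i] - onset_amp) / sys_amp else NA_real_,
      onset_amplitude = onset_amp,
      period = p,
      hr_true = 60 / p))
  }
  list(clean = clean, truth = truth)
}

#' Generate a synthetic PPG record
#'
#' Builds a continuous pulse train by superposing the template's systolic and
#' diastolic Gaussians for each beat on the global time axis (beat starts are
#' spaced by per-beat periods jittered from the heart-rate distribution, so
#' neighboring pulses blend smoothly through their tails), then adds
#' broadband noise, discrete interference harmonics and baseline drift per
#' the [noise_spec], inverts the polarity (pulses point downward, as raw PPG
#' does) and adds a positive DC offset. Ground-truth fiducials of every
#' complete beat are computed from a 10x-oversampled evaluation of the clean
#' analytic train — onset at the true inter-beat trough, amplitudes above the
#' onset amplitude, exactly the quantities a fiducial detector estimates —
#' and carried through with absolute times. Fully reproducible: the same
#' parameters and seed yield the identical record.
#'
#' @param duration record length, s (ignored if `n_beats` given).
#' @param hr_mean mean heart rate, bpm, in `[30, 180]`.
#' @param hr_sd beat-to-beat heart-rate standard deviation, bpm.
#' @param template a [beat_template].
#' @param noise a [noise_spec].
#' @param fs sampling rate, Hz.
#' @param seed integer seed (required; the reproducibility contract).
#' @param n_beats optional number of beats instead of a duration.
#' @param dc_offset positive DC level added to the raw signal, relative units.
#' @return object of class `ppg_record`: list with `samples`, `fs`,
#'   `duration`, `polarity = "raw-inverted"`, `truth` (data.frame of per-beat
#'   fiducials with absolute times, true RI, true delta-T and true HR),
#'   `clean_ac` (the noise-free pulsatile component before inversion, offset
#'   and noise — truth support for fidelity checks), and the generating
#'   parameters.
#' @export
generate_record <- function(duration = 40, hr_mean = 75, hr_sd = 3,
                            template = beat_template(),
                            noise = noise_spec(),
                            fs = 320, seed, n_beats = NULL,
                            dc_offset = 10) {
  stopifnot(inherits(template, "beat_template"), inherits(noise, "noise_spec"))
  if (missing(seed)) stop("a seed is required for reproducibility")
  if (hr_mean < 30 || hr_mean > 180) stop("hr_mean must lie in [30, 180] bpm")
  if (fs <= 2 * max(c(noise$harmonic_freqs, 0)))
    stop("fs must exceed twice the highest harmonic frequency")
  n_target <- if (is.null(n_beats)) round(fs * duration) else NA_integer_
  if (is.null(n_beats) && duration < 60 / hr_mean * 0.9)
    stop("duration too short to hold a single beat")

  withr::with_seed(seed, {
    max_beats <- if (is.null(n_beats))
      ceiling(duration * hr_mean / 60 * 1.5) + 3 else n_beats
    hr_i <- pmin(pmax(stats::rnorm(max_beats, hr_mean, hr_sd), 30), 180)
    periods <- 60 / hr_i
    onsets0 <- cumsum(c(0, periods[-length(periods)]))
    n <- if (is.null(n_beats)) n_target else round(fs * sum(periods))
    ct <- record_clean_truth(template, onsets0, periods, n, fs)
    samples <- ct$clean
    truth <- ct$truth
    t <- (seq_len(n) - 1) / fs

    clean_ac <- samples - mean(samples)
    pgram <- ppg_periodogram(clean_ac, fs)
    p_peak <- max(pgram$power)

    wn <- numeric(n)
    if (is.finite(noise$broadband_level_db)) {
      sigma <- sqrt(n * p_peak * 10^(noise$broadband_level_db / 10))
      wn <- stats::rnorm(n, 0, sigma)
    }
    harm <- numeric(n)
    if (is.finite(noise$harmonic_level_db) && length(noise$harmonic_freqs)) {
      amp <- 2 * sqrt(p_peak * 10^(noise$harmonic_level_db / 10))
      for (fh in noise$harmonic_freqs)
        harm <- harm + amp * sin(2 * pi * fh * t + stats::runif(1, 0, 2 * pi))
    }
    drift <- if (noise$drift_amplitude > 0)
      noise$drift_amplitude * sin(2 * pi * noise$drift_freq * t +
                                  stats::runif(1, 0, 2 * pi))
    else numeric(n)

    raw <- dc_offset - samples - drift + wn + harm
  })

  structure(
    list(samples = raw, fs = fs, duration = length(raw) / fs,
         polarity = "raw-inverted", truth = truth, clean_ac = samples,
         template = template, noise = noise, seed = seed,
         hr_mean = hr_mean, hr_sd = hr_sd, dc_offset = dc_offset),
    class = "ppg_record"
  )
}

#' @export
print.ppg_record <- function(x, ...) {
  cat(sprintf("ppg_record: %.1f s at %g Hz (%d samples), polarity %s, %d true beats\n",
              x$duration, x$fs, length(x$samples), x$polarity,
              if (is.null(x$truth)) 0L else nrow(x$truth)))
  invisible(x)
}

#' Generate a synthetic PPG cohort
#'
#' Emulates a study cohort split into two morphology subgroups: class 1
#' (pronounced diastolic wave, diastolic ratio jittered in `[0.45, 0.60]`)
#' and class 2 (barely visible or absent diastolic wave, ratio in
#' `[0.02, 0.08]`). Per-record heart rate, template timing and widths are
#' jittered by the seeded generator; identical `(parameters, seed)` yield an
#' identical cohort.
#'
#' @param n_records number of records (> 0).
#' @param class1_fraction fraction of class-1 records, in `[0, 1]`.
#' @param seed integer seed.
#' @param duration record length, s.
#' @param fs sampling rate, Hz.
#' @param noise a [noise_spec] shared by all records.
#' @return list of [generate_record] outputs; each record additionally has
#'   `id` (e.g. `"rec03"`) and `morphology_class` (1 or 2).
#' @export
generate_cohort <- function(n_records = 20, class1_fraction = 0.5, seed,
                            duration = 40, fs = 320, noise = noise_spec()) {
  if (n_records <= 0) stop("n_records must be positive")
  if (class1_fraction < 0 || class1_fraction > 1)
    stop("class1_fraction must lie in [0, 1]")
  if (missing(seed)) stop("a seed is required for reproducibility")
  n1 <- round(n_records * class1_fraction)
  classes <- rep(c(1L, 2L), c(n1, n_records - n1))

  params <- withr::with_seed(seed, {
    data.frame(
      rec_seed = sample.int(.Machine$integer.max - 1L, n_records),
      hr_mean = stats::runif(n_records, 60, 88),
      ratio = ifelse(classes == 1L,
                     stats::runif(n_records, 0.45, 0.60),
                     stats::runif(n_records, 0.02, 0.08)),
      sys_center = 0.15 * stats::runif(n_records, 0.95, 1.05),
      sys_width = 0.105 * stats::runif(n_records, 0.95, 1.05),
      dia_center = 0.455 * stats::runif(n_records, 0.97, 1.03),
      dia_width = 0.09 * stats::runif(n_records, 0.95, 1.05)
    )
  })

  lapply(seq_len(n_records), function(i) {
    tmpl <- beat_template(
      systolic_center = params$sys_center[i],
      systolic_width = params$sys_width[i],
      diastolic_amplitude_ratio = params$ratio[i],
      diastolic_center = params$dia_center[i],
      diastolic_width = params$dia_width[i])
    rec <- generate_record(duration = duration, hr_mean = params$hr_mean[i],
                           hr_sd = 1.5, template = tmpl, noise = noise,
                           fs = fs, seed = params$rec_seed[i])
    rec$id <- sprintf("rec%02d", i)
    rec$morphology_class <- classes[i]
    rec
  })
}
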