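#' Index deviations between a filtered and a reference signal
#'
#' Every deviation is (filtered value) - (reference value): `delta_s_sqi`
#' (dimensionless), `delta_ri` (percentage points), `delta_etc` (ms). RI/ETc
#' deltas require eligibility on both branches; on a mismatch (e.g. the
#' filter destroyed the dicrotic notch) they are `NA` while `delta_s_sqi` is
#' still reported.
#'
#' @param filtered,reference `index_set` objects from [compute_indices] for
#'   the same record.
#' @return list with `delta_s_sqi`, `delta_ri`, `delta_etc`.
#' @export
index_deviation <- function(filtered, reference) {
  stopifnot(inherits(filtered, "index_set"), inherits(reference, "index_set"))
  both <- filtered$n_eligible > 0 && reference$n_eligible > 0
  list(
    delta_s_sqi = filtered$s_sqi - reference$s_sqi,
    delta_ri = if (both) filtered$ri_pct - reference$ri_pct else NA_real_,
    delta_etc = if (both) filtered$etc_ms - reference$etc_ms else NA_real_
  )
}

#' Systolic-peak time shift between filtered and reference signals
#'
#' Detects systolic peaks on both signals, matches each filtered-signal peak
#' to the nearest reference peak within `max_lag_s`, and returns the mean of
#' (filtered peak time - reference peak time) over matched pairs, in ms.
#' Positive values mean the filtered signal lags — the causal filter's group
#' delay at the cardiac frequencies.
#'
#' @param filtered,reference `ppg_signal` objects or numeric vectors.
#' @param fs sampling rate, Hz (taken from the signal objects when omitted).
#' @param transient_s seconds discarded from the start of both signals.
#' @param max_lag_s matching window half-width, s.
#' @return mean systolic-peak shift, ms.
#' @export
systolic_peak_shift <- function(filtered, reference, fs = NULL,
                                transient_s = 2, max_lag_s = 0.4) {
  if (inherits(filtered, "ppg_signal")) fs <- filtered$fs
  if (is.null(fs)) stop("fs must be supplied for bare numeric signals")
  xf <- as_samples(filtered)
  xr <- as_samples(reference)
  from <- round(transient_s * fs) + 1L
  xf <- xf[from:length(xf)]
  xr <- xr[from:length(xr)]
  tf <- detect_beats(xf, fs)$peak_times
  tr <- detect_beats(xr, fs)$peak_times
  shifts <- vapply(tf, function(t) {
    d <- t - tr
    j <- which.min(abs(d))
    if (abs(d[j]) <= max_lag_s) d[j] else NA_real_
  }, numeric(1))
  shifts <- shifts[!is.na(shifts)]
  if (!length(shifts)) stop("no matched systolic peak pairs")
  mean(shifts) * 1000
}

# Exact null distribution of the signed-rank statistic W+ over doubled ranks
# (doubling makes mid-ranks integral), by the shift algorithm: successive
# convolution of {0, 2r_i} increments. Returns probabilities over
# W+ in {0, 0.5, 1, ...} indexed by doubled value 0..sum(2r).
signed_rank_null <- function(ranks2) {
  total <- sum(ranks2)
  dist <- numeric(total + 1)
  dist[1] <- 1
  for (r in ranks2) {
    shifted <- c(numeric(r), dist[seq_len(total + 1 - r)])
    dist <- (dist + shifted) / 2
  }
  dist
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Two-sided signed-rank test on paired differences. Zero differences are
#' dropped; tied absolute differences receive mid-ranks. For n <= `exact_max`
#' (default 25) the p-value uses the exact null distribution of the
#' signed-rank statistic, computed by dynamic programming over doubled ranks
#' so that mid-ranks are handled exactly; for larger n a normal approximation
#' with tie-corrected variance is used. The two-sided rule doubles the
#' smaller tail (capped at 1), matching the convention of `stats::wilcox.test`.
#'
#' @param x numeric vector: the differences, or the first sample if `y` given.
#' @param y optional second sample; then the differences are `x - y`.
#' @param exact_max largest n for which the exact null is enumerated.
#' @return list with `statistic` (W+, rank sum of positive differences),
#'   `n` (non-zero differences) and `p_value`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_max = 25) {
  d <- if (is.null(y)) as.numeric(x) else as.numeric(x) - as.numeric(y)
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("all differences are zero: test degenerate")
  r <- rank(abs(d))                          # mid-ranks for ties
  w <- sum(r[d > 0])
  total <- n * (n + 1) / 2

  if (n <= exact_max) {
    ranks2 <- as.integer(round(2 * r))
    dist <- signed_rank_null(ranks2)
    w2 <- as.integer(round(2 * w))
    cdf_le <- sum(dist[seq_len(w2 + 1)])
    cdf_ge <- sum(dist[(w2 + 1):length(dist)])
    p <- if (w > total / 2) 2 * cdf_ge else 2 * cdf_le
  } else {
    mu <- total / 2
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (w - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(statistic = w, n = n, p_value = min(1, p))
}
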