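# Shared fixtures: all synthetic, generated in code at test time.

# noise fully disabled
noisefree <- function() {
  noise_spec(broadband_level_db = -Inf, harmonic_level_db = -Inf,
             drift_amplitude = 0)
}

# a canonical noise-free record with a pronounced diastolic wave
canonical_class1_record <- function(seed = 11) {
  generate_record(seed = seed, noise = noisefree(), hr_mean = 75, hr_sd = 1.5,
                  template = beat_template(diastolic_amplitude_ratio = 0.5))
}

# the clean pulsatile branch of a record: inversion + constant-offset removal
clean_ac_signal <- function(rec) {
  x <- -rec$samples
  new_sig <- x - mean(x)
  structure(list(samples = new_sig, fs = rec$fs, stage = "ac",
                 provenance = "clean"), class = "ppg_signal")
}

# record-level ground truth summary from the generator's annotations
truth_summary <- function(rec) {
  tr <- rec$truth
  hr <- 60 / stats::median(diff(tr$systolic_peak_time))
  list(ri = mean(tr$ri_true, na.rm = TRUE),
       etc = mean(tr$delta_t, na.rm = TRUE) * 1000 / sqrt(hr / 60),
       hr = hr,
       n_beats = nrow(tr))
}

# independent Wilcoxon oracle: exhaustive enumeration of all 2^n sign
# assignments, same mid-rank and two-sided doubling convention
wilcoxon_enum_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  total <- n * (n + 1) / 2
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- as.vector(signs %*% r)
  cdf_le <- mean(ws <= w_obs + 1e-9)
  cdf_ge <- mean(ws >= w_obs - 1e-9)
  min(1, if (w_obs > total / 2) 2 * cdf_ge else 2 * cdf_le)
}

# cohort experiment reports are expensive; compute once per seed and share
.report_cache <- new.env(parent = emptyenv())
cached_experiment <- function(seed = 101, config = ppg_experiment_config()) {
  key <- paste0("rep", seed)
  if (!exists(key, envir = .report_cache))
    assign(key, run_ppg_experiments(config, seed = seed),
           envir = .report_cache)
  get(key, envir = .report_cache)
}

summary_cell <- function(report, experiment, metric, family = NULL,
                         order = NULL, f_high = NULL) {
  s <- report$summary
  sel <- s$experiment == experiment & s$metric == metric
  if (!is.null(family)) sel <- sel & s$family == family
  if (!is.null(order)) sel <- sel & s$order == order
  if (!is.null(f_high)) sel <- sel & s$f_high == f_high
  s[sel, ]
}
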