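test_that("beat detection recovers every generated beat on clean records", {
  rec <- canonical_class1_record()
  ac <- clean_ac_signal(rec)
  beats <- detect_beats(ac$samples, rec$fs)
  tr <- rec$truth
  expect_equal(length(beats$peaks), nrow(tr), tolerance = 1)
  # systolic peak times within one sample of the generator truth
  matched <- vapply(beats$peak_times, function(t)
    min(abs(tr$systolic_peak_time - t)), numeric(1))
  expect_lt(stats::median(matched), 1.5 / rec$fs)

  # same count with the default -90 dB noise
  recn <- generate_record(seed = 11, hr_mean = 75, hr_sd = 1.5,
                          template = beat_template(diastolic_amplitude_ratio = 0.5))
  bn <- detect_beats(clean_ac_signal(recn)$samples, recn$fs)
  expect_equal(length(bn$peaks), length(beats$peaks))

  expect_error(detect_beats(rep(1, 3000), 320), "flat|no beats")
  expect_error(detect_beats(rnorm(100), 320), "2 s")
})

test_that("fiducial detection matches dense-grid truth on clean class-1 beats", {
  rec <- canonical_class1_record()
  ac <- clean_ac_signal(rec)
  fs <- rec$fs
  beats <- detect_beats(ac$samples, fs)
  tr <- rec$truth
  errs_notch <- c(); errs_dia <- c()
  for (b in 2:(length(beats$peaks) - 1)) {
    seg <- ac$samples[beats$onsets[b]:beats$onsets[b + 1]]
    fid <- detect_fiducials(seg, fs)
    t0 <- beats$onset_times[b]
    j <- which.min(abs(tr$notch_time - (t0 + fid$notch_time)))
    errs_notch <- c(errs_notch, abs(t0 + fid$notch_time - tr$notch_time[j]))
    errs_dia <- c(errs_dia, abs(t0 + fid$diastolic_peak_time -
                                tr$diastolic_peak_time[j]))
  }
  expect_lt(stats::median(errs_notch), 2.5 / fs)
  expect_lt(stats::median(errs_dia), 2.5 / fs)

  expect_error(detect_fiducials(seq(1, 0, length.out = 50), 320), "systolic")
})

test_that("beats without a diastolic wave are classed ineligible", {
  fs <- 320
  rec0 <- generate_record(seed = 21, noise = noisefree(), hr_mean = 70,
                          hr_sd = 0,
                          template = beat_template(diastolic_amplitude_ratio = 0))
  idx <- compute_indices(clean_ac_signal(rec0), fs)
  expect_identical(idx$n_eligible, 0L)
  expect_true(is.na(idx$ri_pct))
  expect_true(is.na(idx$etc_ms))
  expect_gte(idx$dawber_class, 3L)

  # class gating from a hand-built fiducial row
  row <- data.frame(onset_time = 0, systolic_peak_time = 0.15,
                    systolic_amplitude = 1, notch_time = 0.35,
                    diastolic_peak_time = 0.45, diastolic_amplitude = 0.4,
                    notch_rise = 0.2, delta_t = 0.35)
  expect_identical(classify_dawber(row)$class, 1L)
  row$notch_rise <- 0.05
  expect_identical(classify_dawber(row)$class, 2L)
  row$notch_time <- NA_real_; row$delta_t <- NA_real_
  expect_identical(classify_dawber(row)$class, 3L)
  expect_false(classify_dawber(row)$eligible)
})

test_that("skewness index matches its definition and brute-force oracle", {
  expect_equal(skewness_sqi(c(0, 0, 1)), 0.70711, tolerance = 1e-5)

  # full periods of a sinusoid are symmetric
  t <- (0:6399) / 320
  expect_equal(skewness_sqi(sin(2 * pi * 2 * t)), 0, tolerance = 1e-9)

  # affine invariance
  set.seed(7)
  x <- rnorm(500)^2
  expect_equal(skewness_sqi(3 * x + 5), skewness_sqi(x), tolerance = 1e-12)

  # brute-force third-standardized-moment oracle, written as a literal sum
  brute <- function(v) {
    n <- length(v); mu <- sum(v) / n
    sdev <- sqrt(sum((v - mu)^2) / n)
    acc <- 0
    for (i in seq_len(n)) acc <- acc + ((v[i] - mu) / sdev)^3
    acc / n
  }
  for (k in 1:20) {
    v <- rnorm(sample(5:100, 1))
    expect_equal(skewness_sqi(v), brute(v), tolerance = 1e-12)
  }
  # e1071's population skewness (type 1) agrees
  v <- rexp(200)
  expect_equal(skewness_sqi(v), e1071::skewness(v, type = 1),
               tolerance = 1e-12)
  expect_error(skewness_sqi(rep(2, 10)), "variance")
})

test_that("heart rate, RI and ETc follow their definitions", {
  expect_equal(heart_rate(cumsum(rep(0.690, 10))), 60 / 0.690)
  expect_equal(heart_rate(cumsum(rep(0.690, 10))), 87, tolerance = 0.01)
  expect_equal(heart_rate(c(0, 1, 2, 3)), 60)
  expect_error(heart_rate(1.5), "2 beats")

  fid <- data.frame(systolic_amplitude = c(1, 1), diastolic_amplitude = c(0.5, 0),
                    delta_t = c(0.3, 0.3), eligible = c(TRUE, TRUE))
  expect_equal(reflection_index(fid), 25)          # mean of 50% and 0%
  expect_equal(reflection_index(fid[1, ]), 50)
  expect_equal(ejection_time_compensated(fid, 60), 300)
  expect_equal(ejection_time_compensated(fid, 240), 150)
  fid$eligible <- FALSE
  expect_error(reflection_index(fid), "eligible")
  expect_error(ejection_time_compensated(fid, 60), "eligible")
})

test_that("index computation recovers generator truth on a clean record", {
  rec <- canonical_class1_record()
  idx <- compute_indices(smooth_reference(clean_ac_signal(rec)))
  ts <- truth_summary(rec)
  expect_lt(abs(idx$ri_pct - ts$ri), 2)
  expect_lt(abs(idx$etc_ms - ts$etc), 6)
  expect_lt(abs(idx$hr_bpm - ts$hr), 2)
  expect_gt(idx$n_eligible / idx$n_beats, 0.9)
})
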