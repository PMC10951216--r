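test_that("beat template and noise spec validate their parameters", {
  expect_error(beat_template(systolic_width = 0), "positive")
  expect_error(beat_template(diastolic_amplitude_ratio = 1.2), "\\[0, 1\\]")
  expect_error(beat_template(diastolic_center = 0.1), "exceed")
  expect_error(noise_spec(broadband_level_db = 3), "negative")
})

test_that("single-wave beats carry no notch truth; ratio is scale invariant", {
  fs <- 320
  t1 <- beat_template(diastolic_amplitude_ratio = 0)
  b1 <- generate_beat(t1, fs, 0.9)
  expect_true(is.na(b1$truth$notch_time))
  expect_true(is.na(b1$truth$diastolic_peak_time))
  expect_length(b1$samples, round(fs * 0.9))

  # well-separated Gaussians: truth amplitude ratio tracks the template ratio
  sep <- beat_template(systolic_center = 0.12, systolic_width = 0.035,
                       diastolic_amplitude_ratio = 0.5,
                       diastolic_center = 0.5, diastolic_width = 0.05)
  bt <- generate_beat(sep, fs, 1.0)
  expect_equal(bt$truth$diastolic_amplitude / bt$truth$systolic_amplitude,
               0.5, tolerance = 0.01)

  # doubling both amplitudes leaves the truth RI unchanged
  sep2 <- beat_template(systolic_amplitude = 2,
                        systolic_center = 0.12, systolic_width = 0.035,
                        diastolic_amplitude_ratio = 0.5,
                        diastolic_center = 0.5, diastolic_width = 0.05)
  bt2 <- generate_beat(sep2, fs, 1.0)
  expect_equal(bt2$truth$ri_true, bt$truth$ri_true, tolerance = 1e-9)

  expect_error(generate_beat(t1, -1, 0.8), "fs")
  expect_error(generate_beat(t1, fs, 0.05), "period")
})

test_that("records are reproducible, correctly sized and raw-inverted", {
  r1 <- generate_record(duration = 20, seed = 5)
  r2 <- generate_record(duration = 20, seed = 5)
  expect_identical(r1$samples, r2$samples)
  expect_identical(r1$truth, r2$truth)
  r3 <- generate_record(duration = 20, seed = 6)
  expect_false(identical(r1$samples, r3$samples))

  expect_length(r1$samples, round(320 * 20))
  expect_identical(r1$polarity, "raw-inverted")
  # pulses point downward: the mean sits nearer the top of the range
  expect_gt(mean(r1$samples) - min(r1$samples),
            max(r1$samples) - mean(r1$samples))
  expect_error(generate_record(duration = 0.3, seed = 1), "duration")
  expect_error(generate_record(duration = 20), "seed")
})

test_that("noise-free record equals the clean train plus offset, inverted", {
  rec <- generate_record(duration = 10, seed = 9, noise = noisefree(),
                         dc_offset = 10)
  expect_equal(rec$samples, 10 - rec$clean_ac, tolerance = 1e-12)
})

test_that("an hr_sd = 0 record beats at exactly the nominal rate", {
  rec <- generate_record(duration = 20, hr_mean = 87, hr_sd = 0, seed = 2)
  expect_equal(unique(round(rec$truth$period, 6)), round(60 / 87, 6))
  # peak times are truth-grid quantized (1/10 sample), so allow ~0.1 bpm
  expect_equal(heart_rate(rec$truth$systolic_peak_time), 87, tolerance = 1e-3)
  # fundamental at 1.45 Hz in the spectrum of the clean train
  pg <- ppg_periodogram(rec$clean_ac - mean(rec$clean_ac), rec$fs)
  f_peak <- pg$freq_hz[which.max(pg$power)]
  expect_equal(f_peak, 1.45, tolerance = 0.06)
})

test_that("generated spectra match the stated noise structure", {
  rec <- generate_record(seed = 4)          # defaults: 40 s, -90 dB floor
  pg <- ppg_periodogram(rec$samples - mean(rec$samples), rec$fs)
  clean <- rec$clean_ac - mean(rec$clean_ac)
  p_peak <- max(ppg_periodogram(clean, rec$fs)$power)

  # broadband floor above 20 Hz within +-6 dB of -90 dB re systolic peak
  sel <- pg$freq_hz > 20 & !(abs(pg$freq_hz - 30) < 1 | abs(pg$freq_hz - 50) < 1)
  floor_db <- 10 * log10(mean(pg$power[sel]) / p_peak)
  expect_lt(abs(floor_db - (-90)), 6)

  # discrete interference lines poke out of the floor at 30 and 50 Hz
  # (line bins also carry one realization of floor noise, so the margin
  # fluctuates around its 10 dB mean)
  for (fh in c(30, 50)) {
    line <- max(pg$power[abs(pg$freq_hz - fh) < 0.1])
    expect_gt(10 * log10(line / mean(pg$power[sel])), 3)
  }

  # spectral realism: >99% of clean-signal power below 10 Hz
  pgc <- ppg_periodogram(clean, rec$fs)
  expect_gt(sum(pgc$power[pgc$freq_hz <= 10]) / sum(pgc$power), 0.99)
})

test_that("cohorts split into the two morphology classes deterministically", {
  co <- generate_cohort(n_records = 6, class1_fraction = 0.5, seed = 31,
                        duration = 12)
  expect_length(co, 6)
  cls <- vapply(co, function(r) r$morphology_class, integer(1))
  expect_equal(sum(cls == 1L), 3)
  co2 <- generate_cohort(n_records = 6, class1_fraction = 0.5, seed = 31,
                         duration = 12)
  expect_identical(lapply(co, `[[`, "samples"), lapply(co2, `[[`, "samples"))

  # class-2-only cohort: no diastolic truth anywhere
  co0 <- generate_cohort(n_records = 3, class1_fraction = 0, seed = 8,
                         duration = 12, noise = noisefree())
  for (r in co0) expect_true(all(is.na(r$truth$diastolic_peak_time)) ||
                             all(r$truth$notch_rise < 0.05 *
                                 r$truth$systolic_amplitude, na.rm = TRUE))
  expect_error(generate_cohort(0, 0.5, seed = 1), "positive")
  expect_error(generate_cohort(4, 2, seed = 1), "class1_fraction")
})

test_that("records round-trip through the CSV + JSON writer", {
  dir <- withr::local_tempdir()
  rec <- generate_record(duration = 6, seed = 13)
  rec$id <- "rec99"
  paths <- write_ppg_record(rec, file.path(dir, "rec99"))
  expect_true(all(file.exists(paths)))
  back <- read_ppg_record(file.path(dir, "rec99"))
  expect_equal(back$samples, rec$samples, tolerance = 1e-12)
  expect_equal(back$fs, rec$fs)
  expect_identical(back$polarity, rec$polarity)
  expect_equal(back$truth$notch_time, rec$truth$notch_time, tolerance = 1e-9)
})
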