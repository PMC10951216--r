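# ppgdistort

Quantifies how causal IIR band-pass filtering distorts the
photoplethysmography (PPG) pulse waveform.

PPG pre-processing must remove the DC level, drift and electronic noise
without deforming the pulse shape, because downstream cardiovascular
parameters are morphological: the reflection index, ejection time, skewness
of the sample distribution. A causal IIR band-pass filter, however, delays
each harmonic by its own group delay

τ_g(ω) = −dφ/dω,  with  φ(ω) = π/2 − arctan(2Qω/ω₀ + √(4Q²−1)) − arctan(2Qω/ω₀ − √(4Q²−1))

for the idealized second-order band-pass H(s) = (ω₀/Q)s / (s² + (ω₀/Q)s + ω₀²).
The delay grows as the centre frequency ω₀ falls, so narrowing the pass band
shifts and smears the pulse. This package measures the damage filter by
filter:

* **Theory** — closed-form transfer function, phase and group delay, with a
  numerical-differentiation cross-check (`band_spec()`, `bp_phase_response()`,
  `group_delay_analytic()`, `group_delay_numeric()`).
* **Filter bank** — Butterworth, Bessel, Elliptic, Chebyshev I/II band-pass
  designs at orders 2/4/6 in cascaded-biquad form, applied strictly causally;
  digital group delay measured from the realized filters (`design_filter()`,
  `apply_causal()`, `digital_group_delay()`).
* **Pipeline** — inversion, moving-average DC removal (1 s window),
  reference smoothing (10 samples), normalization to systolic amplitude
  (`invert_and_remove_dc()`, `smooth_reference()`, `normalize_to_systolic()`).
* **Morphology** — beat and fiducial detection, Dawber-class gating, and the
  indices S_SQI (third standardized moment, divisor-N), RI = 100·A_d/A_s (%)
  and ETc = ΔT/√(HR/60) (ms) (`detect_beats()`, `detect_fiducials()`,
  `compute_indices()`).
* **Distortion statistics** — ΔS_SQI, ΔRI, ΔETc and the systolic-peak shift
  ΔT_peak against an unfiltered smoothed reference, summarized over a cohort
  with medians, quartiles and exact Wilcoxon signed-rank paired tests
  (`index_deviation()`, `systolic_peak_shift()`, `wilcoxon_signed_rank()`,
  `run_experiment_grid()`).
* **Synthetic cohort** — a seeded two-Gaussian pulse generator with exact
  ground-truth fiducials, emulating 40 s fingertip records at 320 Hz with a
  −90 dB noise floor and 30/50 Hz interference lines (`generate_record()`,
  `generate_cohort()`).

## Worked example

Filter a synthetic record with a narrow 0.1–2 Hz Butterworth band and watch
the morphology degrade:

```r
library(ppgdistort)

rec <- generate_record(duration = 40, hr_mean = 75, seed = 42)
ac  <- invert_and_remove_dc(rec)          # upward pulses, DC removed
ref <- smooth_reference(ac)               # the comparison baseline
compute_indices(ref)
#> index_set: S_SQI 0.3783 | RI 43.8% | ETc 461 ms | HR 74.7 bpm | 46 beats (29 eligible, class 2)

flt <- design_filter(filter_spec("butterworth", 2, band_spec(0.1, 2), fs = 320))
filtered <- apply_causal(flt, ac$samples)
compute_indices(filtered, fs = 320)
#> index_set: S_SQI 0.1850 | RI NA | ETc NA | HR 74.7 bpm | 46 beats (0 eligible, class 3)

systolic_peak_shift(filtered, ref, fs = 320)
#> [1] 63.6   # ms
```

The reference signal has a healthy class-1/2 waveform: skewness 0.38,
reflection index 43.8%, compensated ejection time 461 ms. After 0.1–2 Hz
filtering the dicrotic notch is gone — no beat remains eligible, so RI and
ETc are undefined — the skewness has collapsed toward a sinusoid's, and the
systolic peak arrives 64 ms late, consistent with the analytic group delay
of a Q ≈ 0.5 band centred near 1 Hz. The full two-experiment study grid
(three bandwidths; five families × three orders) runs with:

```r
report <- run_ppg_experiments(ppg_experiment_config(), seed = 1, out_dir = "out")
head(report$summary)
```

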