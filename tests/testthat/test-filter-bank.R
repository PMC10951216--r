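study_grid <- function() {
  g <- expand.grid(
    family = c("butterworth", "bessel", "elliptic", "chebyshev1", "chebyshev2"),
    order = c(2L, 4L, 6L),
    f_high = c(10, 5, 2),
    stringsAsFactors = FALSE)
  g$f_low <- 0.1
  g
}

test_that("every filter of the study grid is realizable and stable", {
  g <- study_grid()
  for (i in seq_len(nrow(g))) {
    flt <- design_filter(filter_spec(g$family[i], g$order[i],
                                     band_spec(g$f_low[i], g$f_high[i]), 320))
    expect_lt(max(Mod(flt$zpg$pole)), 1)
    expect_equal(nrow(flt$sos), g$order[i] / 2)
    # DC rejection: exact null for all-pole prototypes; finite-zero families
    # (elliptic, Chebyshev II at even prototype order) bottom out at the
    # stopband attenuation (-40 dB)
    expect_lt(Mod(filter_response(flt, 0)), 0.011)
  }
})

test_that("impulse response decays at the rate set by the slowest pole", {
  for (fam in c("butterworth", "chebyshev2")) {
    flt <- design_filter(filter_spec(fam, 4, band_spec(0.1, 10), 320))
    n <- 20000
    imp <- apply_causal(flt, c(1, rep(0, n - 1)))
    rho <- max(Mod(flt$zpg$pole))
    # tail bounded by a constant times rho^n (generous constant)
    expect_lt(max(abs(imp[(n - 500):n])), 1e3 * rho^(n - 500))
  }
  # a Butterworth order-2 impulse response over 10k samples dies out
  flt <- design_filter(filter_spec("butterworth", 2, band_spec(0.1, 10), 320))
  imp <- apply_causal(flt, c(1, rep(0, 9999)))
  expect_lt(abs(imp[10000]) / max(abs(imp)), 1e-6)
})

test_that("band-pass magnitude passes mid-band and rejects out-of-band", {
  flt <- design_filter(filter_spec("butterworth", 2, band_spec(0.1, 10), 320))
  expect_gt(Mod(filter_response(flt, 5)), 0.9)
  expect_lt(Mod(filter_response(flt, 100)), 0.1)
  expect_error(filter_spec("butterworth", 2, band_spec(0.1, 200), 320),
               "Nyquist")
  expect_error(filter_spec("butterworth", 3, band_spec(0.1, 10), 320),
               "even")
})

test_that("causal application: zero in, zero out; prefix property; length kept", {
  flt <- design_filter(filter_spec("elliptic", 4, band_spec(0.1, 10), 320))
  expect_equal(apply_causal(flt, rep(0, 100)), rep(0, 100))
  expect_error(apply_causal(flt, numeric(0)), "empty")

  set.seed(3)
  x <- rnorm(2000)
  y <- apply_causal(flt, x)
  expect_length(y, 2000)
  # causality: output on a prefix equals the prefix of the full output
  y_prefix <- apply_causal(flt, x[1:700])
  expect_equal(y_prefix, y[1:700], tolerance = 1e-12)
})

test_that("impulse-response spectrum matches the designed frequency response", {
  for (fam in c("butterworth", "bessel", "chebyshev1")) {
    flt <- design_filter(filter_spec(fam, 4, band_spec(0.1, 10), 320))
    n <- 60000                      # long enough for the 0.1 Hz edge to settle
    imp <- apply_causal(flt, c(1, rep(0, n - 1)))
    f_test <- seq(0.5, 30, length.out = 100)
    # DTFT of the impulse response at the test frequencies
    dtft <- vapply(f_test, function(f)
      sum(imp * exp(-1i * 2 * pi * f / 320 * (0:(n - 1)))), complex(1))
    expect_lt(max(Mod(dtft - filter_response(flt, f_test))), 1e-6)
  }
})

test_that("steady-state sinusoid gain equals the designed magnitude response", {
  flt <- design_filter(filter_spec("butterworth", 2, band_spec(0.1, 10), 320))
  fs <- 320
  t <- (0:(40 * fs - 1)) / fs
  for (f in c(1, 5.05, 10)) {
    y <- apply_causal(flt, sin(2 * pi * f * t))
    tail_amp <- (max(y[(20 * fs):(40 * fs)]) - min(y[(20 * fs):(40 * fs)])) / 2
    expect_equal(tail_amp, Mod(filter_response(flt, f)), tolerance = 0.01)
  }
  # mid-band gain is high (band centre passes within ~10%)
  expect_gt(Mod(filter_response(flt, 5.05)), 0.85)
})

test_that("digital group delay: pure delay, analytic cross-check, ranking", {
  # a pure 2-sample delay realized as one biquad
  delay2 <- structure(
    list(sos = matrix(c(0, 0, 1, 1, 0, 0), nrow = 1),
         zpg = signal::Zpg(zero = c(0i, 0i), pole = complex(0), gain = 1),
         spec = list(fs = 320)),
    class = "digital_filter")
  gd <- digital_group_delay(delay2, seq(1, 100, by = 1))
  expect_equal(gd$tau_g_s, rep(2 / 320, 100), tolerance = 1e-10)

  # agreement with signal::grpdelay on a recomposed transfer function
  flt <- design_filter(filter_spec("butterworth", 2, band_spec(0.1, 10), 320))
  b <- flt$sos[1, 1:3]                # order 2: a single biquad section
  a <- flt$sos[1, 4:6]
  # grpdelay warns about its own singularity at the DC zero; harmless here
  gref <- suppressWarnings(signal::grpdelay(b, a, n = 32768, Fs = 320))
  f_grid <- seq(2, 8, by = 0.02)            # flat region, interpolation-safe
  mine <- digital_group_delay(flt, f_grid)$tau_g_s
  theirs <- stats::approx(gref$w, gref$gd / 320, xout = f_grid)$y
  expect_lt(max(abs(mine - theirs)), 1e-4)

  expect_error(digital_group_delay(flt, c(100, 200)), "Nyquist|inside")
})

test_that("order-4 delay flatness: Bessel least variable, Chebyshev II most", {
  f <- seq(1, 8, by = 0.02)
  fams <- c("butterworth", "bessel", "elliptic", "chebyshev1", "chebyshev2")
  gd <- lapply(fams, function(fm)
    digital_group_delay(design_filter(
      filter_spec(fm, 4, band_spec(0.1, 10), 320)), f)$tau_g_s)
  names(gd) <- fams
  sds <- vapply(gd, sd, numeric(1))
  rngs <- vapply(gd, function(g) diff(range(g)), numeric(1))
  expect_identical(names(which.min(sds)), "bessel")
  expect_identical(names(which.max(rngs)), "chebyshev2")
  expect_lt(sds["bessel"], sds["butterworth"])
})

test_that("the Bessel magnitude-normalization option moves the -3 dB edge", {
  fd <- design_filter(filter_spec("bessel", 4, band_spec(0.1, 10), 320))
  fm <- design_filter(filter_spec("bessel", 4, band_spec(0.1, 10), 320,
                                  bessel_norm = "mag"))
  expect_equal(Mod(filter_response(fm, 10)), 1 / sqrt(2), tolerance = 0.01)
  expect_gt(Mod(filter_response(fd, 10)), Mod(filter_response(fm, 10)))
})
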