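test_that("Butterworth filter matches analytic magnitude responses", {
  # DC gain 1: a constant series passes unchanged in both modes
  const <- belt_ts(rep(3.7, 2000), rate = 1000)
  expect_equal(butterworth_filter(const, "lowpass", 10)$values,
               rep(3.7, 2000), tolerance = 1e-9)
  expect_equal(butterworth_filter(const, "lowpass", 10, zero_lag = TRUE)$values,
               rep(3.7, 2000), tolerance = 1e-9)

  # causal 2nd-order gain at the cutoff is 1/sqrt(2)
  s <- sine_ts(5, rate = 1000, duration = 4)
  y <- butterworth_filter(s, "lowpass", 5)
  expect_equal(tail_amplitude(y), 1 / sqrt(2), tolerance = 0.01)

  # zero-lag mode squares the magnitude: gain 0.5 at the cutoff
  # (measured over the middle of the signal, away from both edge transients)
  yz <- butterworth_filter(s, "lowpass", 5, zero_lag = TRUE)
  expect_equal(sqrt(2) * stats::sd(yz$values[1001:3000]), 0.5,
               tolerance = 0.01)

  # 100 Hz tone through the 10 Hz low-pass: |H| = 1/sqrt(1 + (f/fc)^4);
  # sampled at 10 kHz so the bilinear frequency warp is negligible
  tone <- sine_ts(100, rate = 10000, duration = 1)
  att <- tail_amplitude(butterworth_filter(tone, "lowpass", 10))
  expect_equal(att, 1 / sqrt(1 + 10^4), tolerance = 0.01)
  expect_equal(att, 0.0100, tolerance = 0.01)

  expect_error(butterworth_filter(s, "lowpass", 600), "Nyquist")
  expect_error(butterworth_filter(belt_ts(1:5, 1000), "lowpass", 10), "short")
})

test_that("zero-lag filtering preserves the peak position of a symmetric pulse", {
  n <- 2000
  pulse <- belt_ts(exp(-0.5 * ((1:n - 1000) / 40)^2), rate = 1000)
  yz <- butterworth_filter(pulse, "lowpass", 10, zero_lag = TRUE)
  expect_equal(which.max(yz$values), 1000)
  # the causal pass, by contrast, delays the peak
  yc <- butterworth_filter(pulse, "lowpass", 10)
  expect_gt(which.max(yc$values), 1000)
})

test_that("full-wave rectification is elementwise absolute value and idempotent", {
  x <- belt_ts(c(-1, 2, -3), rate = 10)
  expect_equal(full_wave_rectify(x)$values, c(1, 2, 3))
  nonneg <- belt_ts(c(0, 1, 2.5), rate = 10)
  expect_equal(full_wave_rectify(nonneg)$values, nonneg$values)
  expect_equal(full_wave_rectify(full_wave_rectify(x))$values,
               full_wave_rectify(x)$values)
  # mean of a rectified zero-mean sinusoid is 2/pi times the amplitude
  s <- sine_ts(10, rate = 1000, duration = 1)  # 10 full periods
  expect_equal(mean(full_wave_rectify(s)$values), 2 / pi, tolerance = 0.01)
})

test_that("EMG envelope chain blocks DC, tracks activation, and scales linearly", {
  zero <- belt_ts(rep(0, 3000), rate = 1000)
  expect_equal(emg_envelope(zero)$values, rep(0, 3000))

  # constant offset is removed by the 20 Hz high-pass
  off <- belt_ts(rep(2, 3000), rate = 1000)
  env <- emg_envelope(off)$values
  core <- env[300:2700]
  expect_lt(max(core), 0.02 * 2)

  # envelope of simulated EMG correlates with the known activation
  cfg <- session_config("walk", n_cycles = 12, circumference_noise_sd = 0,
                        seed = 11)
  act <- simulate_activations(cfg)$VL
  raw <- simulate_emg(act, cfg, seed = 42)
  e <- emg_envelope(raw)
  expect_gt(stats::cor(e$values, act$values), 0.8)

  # linearity: doubling the raw EMG doubles the envelope (before clipping)
  e1 <- emg_envelope(raw, clip_negative = FALSE)
  raw2 <- belt_ts(2 * raw$values, rate = raw$rate)
  e2 <- emg_envelope(raw2, clip_negative = FALSE)
  expect_equal(e2$values, 2 * e1$values, tolerance = 1e-10)

  # envelope non-negativity after clipping
  expect_true(all(e$values >= 0))
})

test_that("MVC computation and normalization follow the max-across-trials rule", {
  c1 <- belt_ts(rep(1, 100), rate = 100)
  expect_equal(unname(compute_mvc(list(VL = c1))), 1)
  two <- list(VL = list(belt_ts(c(0.1, 0.4, 0.2), 10),
                        belt_ts(c(0.3, 0.7, 0.1), 10)))
  expect_equal(unname(compute_mvc(two)), 0.7)
  expect_error(compute_mvc(list()), "at least one")
  expect_error(compute_mvc(list(VL = list())), "empty")

  # MVC from synthetic standing + sitting maximal co-contraction trials
  # equals the peak envelope of those trials
  envs <- lapply(c("cocontraction_standing", "cocontraction_sitting"),
                 function(cond) {
    ses <- generate_session(cond, seed = 3)
    emg_envelope(ses$channels$emg_RF_V)
  })
  mvc <- compute_mvc(list(RF = envs))
  expect_equal(unname(mvc), max(sapply(envs, function(e) max(e$values))))

  env <- belt_ts(c(0, 0.35, 0.7), 10)
  nm <- normalize_mvc(env, 0.7)
  expect_equal(nm$values, c(0, 0.5, 1))
  expect_equal(normalize_mvc(belt_ts(rep(0, 5), 10), 0.3)$values, rep(0, 5))
  expect_error(normalize_mvc(env, 0), "positive")
})

test_that("circumference processing converts, filters and differentiates", {
  cal <- default_calibration()
  # constant capacitance: constant length, zero velocity
  cc <- belt_ts(rep(500, 2000), rate = 1000, unit = "nF")
  out <- process_circumference(cc, cal)
  expect_equal(out$length$values, rep(111.4672, 2000), tolerance = 1e-9)
  expect_equal(out$velocity$values, rep(0, 2000), tolerance = 1e-9)

  # linear length ramp: velocity recovers the slope away from the edges
  rate <- 1000
  t <- (0:3999) / rate
  L <- 100 + 5 * t                       # 5 mm/s
  cap <- belt_ts(length_to_capacitance(cal, L), rate = rate, unit = "nF")
  v <- suppressWarnings(process_circumference(cap, cal))$velocity$values
  core <- v[500:3500]
  expect_equal(mean(core), 5, tolerance = 0.01)
  expect_lt(max(abs(core - 5)), 0.05 * 5)

  # band-limited L(t) survives the 10 Hz low-pass round trip
  L2 <- 140 + 3 * sin(2 * pi * 1 * t)    # 1 Hz, far below cutoff
  cap2 <- belt_ts(length_to_capacitance(cal, L2), rate = rate, unit = "nF")
  out2 <- process_circumference(cap2, cal, zero_lag = TRUE)
  expect_equal(out2$length$values[500:3500], L2[500:3500], tolerance = 0.02)
  # and skipping the filter is an exact inverse
  out3 <- process_circumference(cap2, cal, lowpass_hz = NA)
  expect_equal(out3$length$values, L2, tolerance = 1e-9)
})
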