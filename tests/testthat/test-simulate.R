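test_that("activation simulation honours templates, offsets and presets", {
  # empty template list: all-zero activation
  empty <- setNames(replicate(5, data.frame(center = numeric(0),
                                            width = numeric(0),
                                            peak = numeric(0)),
                              simplify = FALSE), muscle_names())
  cfg0 <- session_config("walk", n_cycles = 3, templates = empty,
                         amplitude_jitter = 0, seed = 1)
  a0 <- simulate_activations(cfg0)
  expect_true(all(sapply(a0, function(a) all(a$values == 0))))

  # single bump peaks at its center with its stated height
  one <- empty
  one$VL <- data.frame(center = 50, width = 5, peak = 0.5)
  cfg1 <- session_config("walk", n_cycles = 1, templates = one,
                         amplitude_jitter = 0, lead_in = 0, seed = 1)
  a1 <- simulate_activations(cfg1)$VL$values
  expect_equal(max(a1), 0.5, tolerance = 1e-6)
  expect_equal(which.max(a1), round(length(a1) / 2), tolerance = 2)

  # co-contraction gait style: tonic offset raises the in-cycle minimum
  cfgc <- session_config("walk", n_cycles = 2, style = "cocontraction",
                         cocontraction_offset = 0.3, lead_in = 0, seed = 1)
  ac <- simulate_activations(cfgc)
  expect_true(all(sapply(ac, function(a) min(a$values) >= 0.3 - 1e-12)))

  # relaxation style reduces swing-phase activity relative to neutral
  cfgn <- session_config("walk", n_cycles = 4, seed = 6)
  cfgr <- session_config("walk", n_cycles = 4, style = "relaxation", seed = 6)
  an <- simulate_activations(cfgn)$BFL$values
  ar <- simulate_activations(cfgr)$BFL$values
  expect_lt(max(ar), max(an))

  # passive preset: silence; co-contraction preset: maximal plateau
  ap <- simulate_activations(session_config("passive", seed = 1))
  expect_true(all(sapply(ap, function(a) all(a$values == 0))))
  am <- simulate_activations(session_config("cocontraction_standing", seed = 1))
  expect_equal(max(am$VL$values), 1)

  expect_error(session_config("walk", templates = within(empty, VL <- data.frame(
    center = 10, width = -1, peak = 0.2))), "width")
})

test_that("simulated EMG is a seeded band-limited carrier scaled by activation", {
  cfg <- session_config("walk", n_cycles = 8, seed = 31)
  act <- simulate_activations(cfg)$VM
  zero <- belt_ts(rep(0, length(act$values)), rate = cfg$rate)
  expect_true(all(simulate_emg(zero, cfg, seed = 1)$values == 0))
  e1 <- simulate_emg(act, cfg, seed = 5)
  e2 <- simulate_emg(act, cfg, seed = 5)
  expect_identical(e1$values, e2$values)
  expect_false(identical(e1$values, simulate_emg(act, cfg, seed = 6)$values))
  # envelope of a 30 s simulated signal tracks the activation
  cfg30 <- session_config("walk", n_cycles = 28, seed = 32)
  act30 <- simulate_activations(cfg30)$VL
  env <- emg_envelope(simulate_emg(act30, cfg30, seed = 7))
  expect_gt(stats::cor(env$values, act30$values), 0.8)
  bad <- session_config("walk", n_cycles = 2, seed = 1)
  bad$emg_band <- c(20, 600)
  expect_error(simulate_emg(act, bad, seed = 1), "Nyquist")
})

test_that("simulated GRF has exact swing zeros and detector-consistent contacts", {
  cfg <- session_config("walk", n_cycles = 5, seed = 17)
  grf <- simulate_grf(cfg)
  lay <- beltgait:::session_layout(cfg)
  swing <- !is.na(lay$phase) & lay$phase >= cfg$stance_fraction
  expect_true(all(grf$values[swing] == 0))
  # peak near the configured body-weight multiple
  expect_equal(max(grf$values), 1.1 * cfg$grf_body_weight, tolerance = 0.01)
  run <- simulate_grf(session_config("run", n_cycles = 5, seed = 17))
  expect_equal(max(run$values), 2.3 * 700, tolerance = 0.01)

  # detector recovers exactly n_cycles events at truth samples, all presets
  # and styles, several seeds
  for (cond in c("walk", "run")) for (sty in c("neutral", "relaxation"))
    for (s in c(1, 22, 333)) {
      ses <- generate_session(cond, style = sty, n_cycles = 5, seed = s)
      ev <- detect_heel_contacts(ses$channels$vgrf_N)
      expect_length(ev$contact_indices, 5)
      expect_true(all(abs(ev$contact_indices - ses$truth$contact_indices) <= 1))
    }
})

test_that("simulated circumference follows the truth model, passive term and noise law", {
  cfg <- session_config("walk", n_cycles = 6, circumference_noise_sd = 0,
                        seed = 41)
  acts <- simulate_activations(cfg)
  out <- simulate_circumference(acts, cfg)
  expect_equal(out$noiseless$values,
               predict(cfg$truth_model, beltgait:::as_activity_matrix(acts)))
  expect_identical(out$measured$values, out$noiseless$values)

  # zero activations with passive amplitude 2: minimum is b - 2
  pas <- session_config("passive", circumference_noise_sd = 0, seed = 1)
  apz <- simulate_activations(pas)
  opz <- simulate_circumference(apz, pas)
  expect_equal(min(opz$noiseless$values), pas$truth_model$b - 2,
               tolerance = 1e-6)
  expect_false(all(opz$noiseless$values == opz$noiseless$values[1]))

  # sample SD of the injected noise matches its nominal value at large T
  big <- session_config("squat", n_cycles = 15, cycle_duration = 4, seed = 3)
  ab <- simulate_activations(big)
  ob <- simulate_circumference(ab, big)
  expect_equal(sd(ob$measured$values - ob$noiseless$values), 1.8,
               tolerance = 0.05 * 1.8)
})

test_that("capacitance synthesis inverts the calibration and flags bad lengths", {
  cal <- default_calibration()
  const <- belt_ts(rep(111.4672, 100), rate = 1000, unit = "mm")
  expect_equal(simulate_capacitance(const, cal)$values, rep(500, 100),
               tolerance = 1e-9)
  ramp <- belt_ts(seq(97, 189, length.out = 500), rate = 1000, unit = "mm")
  cap <- simulate_capacitance(ramp, cal)
  expect_true(all(diff(cap$values) > 0))
  # exact round trip when the low-pass is skipped
  back <- process_circumference(cap, cal, lowpass_hz = NA)
  expect_equal(back$length$values, ramp$values, tolerance = 1e-9)
  low <- belt_ts(c(100, 50), rate = 10, unit = "mm")
  expect_error(simulate_capacitance(low, cal), "element 2")
})

test_that("session generation is deterministic, aligned, and labelled", {
  s1 <- generate_session("walk", n_cycles = 4, seed = 99)
  s2 <- generate_session("walk", n_cycles = 4, seed = 99)
  expect_identical(s1, s2)
  expect_false(identical(s1$channels$capacitance_nF$values,
                         generate_session("walk", n_cycles = 4,
                                          seed = 100)$channels$capacitance_nF$values))

  # all channels and the truth share rate and length
  lens <- sapply(s1$channels, function(ch) length(ch$values))
  expect_equal(unname(lens), rep(lens[[1]], length(lens)))
  expect_length(s1$truth$circumference$values, lens[[1]])
  expect_equal(nrow(s1$truth$activations), lens[[1]])
  expect_equal(names(s1$channels),
               c("capacitance_nF", paste0("emg_", muscle_names(), "_V"),
                 "vgrf_N"))

  # passive preset: zero truth activity, non-constant circumference
  pp <- generate_session("passive", seed = 2)
  expect_true(all(pp$truth$activations == 0))
  expect_gt(diff(range(pp$truth$circumference$values)), 1)

  # walk preset carries one truth contact per cycle
  w20 <- generate_session("walk", n_cycles = 20, seed = 8)
  expect_length(w20$truth$contact_indices, 20)

  expect_error(generate_session("moonwalk", seed = 1))
})
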