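test_that("R-peak detection recovers clean and noisy synthetic trains", {
  beats <- simulate_beat_train(60, 30)
  ecg <- render_ecg_waveform(beats, rate = 300, duration = 30)
  r <- detect_r_peaks(ecg)
  expect_length(r, length(beats))
  expect_lte(max(abs(r - beats)), 1 / 300 + 1e-9)

  # Gaussian noise at 10 dB SNR relative to the clean signal power
  snr_sd <- sqrt(mean(ecg$samples^2) / 10)
  noisy <- render_ecg_waveform(beats, rate = 300, duration = 30,
                               noise_sd = snr_sd, seed = 4)
  rn <- detect_r_peaks(noisy)
  matched <- vapply(beats, function(b) any(abs(rn - b) <= 0.02), TRUE)
  expect_gte(mean(matched), 0.99)
  # precision: no spurious detections far from any true beat
  spurious <- vapply(rn, function(p) all(abs(beats - p) > 0.02), TRUE)
  expect_lte(mean(spurious), 0.01)

  expect_error(detect_r_peaks(channel_recording(rep(1, 900), 300, "ecg")),
               "no signal")
  expect_error(detect_r_peaks(channel_recording(sin(1:100), 300, "ecg")),
               "2 s")
})

test_that("beat windows tile the inter-peak region", {
  w <- beat_windows(c(0, 1, 2))
  expect_equal(w$start, c(0, 1))
  expect_equal(w$end, c(1, 2))
  expect_equal(nrow(beat_windows(5)), 0)
  wi <- beat_windows(c(0, 0.8, 1.9))
  expect_equal(wi$end - wi$start, c(0.8, 1.1))
  expect_error(beat_windows(c(1, 1)), "strictly increasing")
})

test_that("per-beat pulse pressure is the window max minus min", {
  # explicit triangular beat: 80 -> 120 -> 80 over one second
  up <- seq(80, 120, length.out = 150); down <- seq(120, 80, length.out = 151)[-1]
  ch <- channel_recording(c(up, down, rep(80, 300)), 300, "abp", "mmHg")
  bp <- beat_pulse_pressure(ch, 0, 1)
  expect_equal(bp$systolic, 120)
  expect_equal(bp$diastolic, 80)
  expect_equal(bp$pp, 40)
  expect_true(bp$valid)

  const <- channel_recording(rep(90, 300), 300, "abp", "mmHg")
  expect_equal(beat_pulse_pressure(const, 0, 0.9)$pp, 0)

  expect_false(beat_pulse_pressure(ch, 0, 1 / 300)$valid)

  # offset invariance
  shifted <- ch; shifted$samples <- ch$samples + 13.7
  expect_equal(beat_pulse_pressure(shifted, 0, 1)$pp, 40)
})

test_that("PPG amplitude scales with gain and vanishes on flat windows", {
  beats <- simulate_beat_train(60, 10)
  ch <- render_ppg_waveform(beats, dpop_target = 0, resp_rate = 6, rate = 400,
                            baseline_wander_amp = 0)
  a <- beat_pop_amplitude(ch, 1, 2)$amplitude
  expect_equal(a, 1, tolerance = 1e-3)
  gained <- ch; gained$samples <- 5 * ch$samples
  expect_equal(beat_pop_amplitude(gained, 1, 2)$amplitude, 5 * a,
               tolerance = 1e-9)
  flat <- channel_recording(rep(2, 400), 400, "ppg")
  expect_equal(beat_pop_amplitude(flat, 0, 0.9)$amplitude, 0)
})

test_that("beat VTI matches closed-form and quadrature oracles", {
  # half-sine pulse, peak 100 cm/s, duration 0.3 s
  rate <- 300
  t <- seq(0, 1 - 1 / rate, by = 1 / rate)
  v <- ifelse(t < 0.3, 100 * sin(pi * t / 0.3), 0)
  ch <- channel_recording(v, rate, "doppler", "cm/s")
  full <- beat_vti(ch, 0, 1, ejection_threshold_frac = 0)
  expect_equal(full$vti, (2 / pi) * 100 * 0.3, tolerance = 0.02)

  zero <- channel_recording(rep(0, 300), 300, "doppler", "cm/s")
  expect_equal(beat_vti(zero, 0, 0.9)$vti, 0)

  # threshold 0.1: integral over the region where sin >= 0.1, against an
  # independent quadrature oracle
  th <- asin(0.1)
  oracle <- stats::integrate(function(x) 100 * sin(pi * x / 0.3),
                             0.3 * th / pi, 0.3 * (pi - th) / pi)$value
  part <- beat_vti(ch, 0, 1, ejection_threshold_frac = 0.1)
  expect_equal(part$vti, oracle, tolerance = 0.05)
})

test_that("stroke volume and cardiac output follow the Doppler formulas", {
  expect_equal(stroke_volume(20, doppler_geometry(20, 20)),
               20 / cos(20 * pi / 180) * pi, tolerance = 1e-9)
  expect_equal(stroke_volume(20, doppler_geometry(20, 20)), 66.87,
               tolerance = 0.005)
  expect_equal(stroke_volume(20, doppler_geometry(0, 20)), 20 * pi)
  expect_equal(stroke_volume(0), 0)
  expect_error(doppler_geometry(95), "angle")
  expect_error(stroke_volume(-1), "non-negative")

  expect_equal(cardiac_output(70, 70), 4.9)
  expect_equal(cardiac_output(0, 80), 0)
  expect_equal(cardiac_output(50, 120), 6)
})
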