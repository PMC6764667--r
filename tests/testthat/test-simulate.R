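test_that("beat trains have the requested rate, span and determinism", {
  b <- simulate_beat_train(60, 10)
  expect_equal(b, 0:9)
  b75 <- simulate_beat_train(75, 60)
  expect_length(b75, 75)
  expect_equal(unique(round(diff(b75), 10)), 0.8)

  bj <- simulate_beat_train(70, 600, jitter_sd = 0.02, seed = 1)
  expect_lt(abs(mean(diff(bj)) - 60 / 70) / (60 / 70), 0.01)
  expect_true(all(diff(bj) > 0))
  expect_true(all(bj >= 0 & bj <= 600))
  expect_identical(bj, simulate_beat_train(70, 600, jitter_sd = 0.02, seed = 1))

  expect_error(simulate_beat_train(-60, 10), "positive")
  expect_error(simulate_beat_train(60, 0), "positive")
})

test_that("arterial renderer carries the dPP target into per-beat pulse pressures", {
  beats <- simulate_beat_train(60, 40)
  # zero modulation: every beat identical
  ch0 <- render_arterial_waveform(beats, map_level = 90, mean_pp = 40,
                                  dpp_target = 0, resp_rate = 6, rate = 300)
  win <- beat_windows(beats)
  pp0 <- vapply(seq_len(nrow(win)), function(i)
    beat_pulse_pressure(ch0, win$start[i], win$end[i])$pp, 0)
  expect_equal(pp0, rep(40, length(pp0)), tolerance = 1e-6)
  expect_equal(mean(ch0$samples), 90, tolerance = 0.2)

  # dPP 20 with 20 beats per respiratory cycle (HR 60, 3 breaths/min):
  # discrete beat sampling can only undershoot, bounded by the extreme-
  # sampling shortfall of a sinusoid
  beats3 <- simulate_beat_train(60, 80)
  ch <- render_arterial_waveform(beats3, 90, 40, dpp_target = 20,
                                 resp_rate = 3, rate = 300)
  win3 <- beat_windows(beats3)
  pp <- vapply(seq_len(nrow(win3)), function(i)
    beat_pulse_pressure(ch, win3$start[i], win3$end[i])$pp, 0)
  est <- dpp(pp)$value
  expect_gte(est, 19.0)
  expect_lte(est, 20.0 + 1e-6)

  # doubling mean_pp leaves the (relative) estimate unchanged
  ch2 <- render_arterial_waveform(beats3, 90, 80, dpp_target = 20,
                                  resp_rate = 3, rate = 300)
  pp2 <- vapply(seq_len(nrow(win3)), function(i)
    beat_pulse_pressure(ch2, win3$start[i], win3$end[i])$pp, 0)
  expect_equal(dpp(pp2)$value, est, tolerance = 1e-9)

  expect_error(render_arterial_waveform(numeric(0)), "non-empty")
  expect_error(render_arterial_waveform(beats, dpp_target = 250), "200")
})

test_that("PPG renderer carries dPOP and is gain-invariant under extraction", {
  beats <- simulate_beat_train(60, 80)
  win <- beat_windows(beats)
  amp_of <- function(ch) vapply(seq_len(nrow(win)), function(i)
    beat_pop_amplitude(ch, win$start[i], win$end[i])$amplitude, 0)

  flat <- render_ppg_waveform(beats, dpop_target = 0, resp_rate = 3,
                              rate = 400, baseline_wander_amp = 0)
  expect_equal(diff(range(amp_of(flat))), 0, tolerance = 1e-6)

  ch <- render_ppg_waveform(beats, dpop_target = 15, resp_rate = 3,
                            rate = 400, baseline_wander_amp = 0)
  est <- dpop(amp_of(ch))$value
  expect_gte(est, 14.2)
  expect_lte(est, 15.0 + 1e-6)

  gained <- ch; gained$samples <- 10 * ch$samples
  expect_equal(dpop(amp_of(gained))$value, est, tolerance = 1e-9)
})

test_that("CVP renderer modes shape peaks and troughs as specified", {
  flat <- render_cvp_waveform(mean_cvp = 6, dcvp_target = 0, cardiac_amp = 0,
                              rate = 400, duration = 30)
  expect_equal(flat$samples, rep(6, length(flat$samples)), tolerance = 1e-12)

  # 4 mmHg swing recovered through the 40 Hz downsampling path
  cv <- render_cvp_waveform(mean_cvp = 6, dcvp_target = 4, resp_rate = 14,
                            cardiac_amp = 0, rate = 400, duration = 30)
  d <- dcvp(resample_channel(cv, 40), 5, 5 + 60 / 14)
  expect_equal(d$value, 4, tolerance = 0.05)

  # PEP-like raises only the maxima
  neu <- render_cvp_waveform(6, 4, resp_rate = 12, cardiac_amp = 0,
                             rate = 400, duration = 30)
  pep <- render_cvp_waveform(6, 4, resp_rate = 12, cardiac_amp = 0,
                             rate = 400, duration = 30, mode = "PEP",
                             peak_offset = 2)
  cyc <- data.frame(s = c(5, 10), e = c(10, 15))
  for (i in 1:2) {
    vn <- neu$samples[channel_times(neu) >= cyc$s[i] & channel_times(neu) < cyc$e[i]]
    vp <- pep$samples[channel_times(pep) >= cyc$s[i] & channel_times(pep) < cyc$e[i]]
    expect_equal(max(vp) - max(vn), 2, tolerance = 0.01)
    expect_equal(min(vp), min(vn), tolerance = 0.01)
  }
  # CPAP-like shifts peaks and troughs together
  cpap <- render_cvp_waveform(6, 4, resp_rate = 12, cardiac_amp = 0,
                              rate = 400, duration = 30, mode = "CPAP",
                              baseline_offset = 3)
  expect_equal(max(cpap$samples) - max(neu$samples), 3, tolerance = 1e-9)
  expect_equal(min(cpap$samples) - min(neu$samples), 3, tolerance = 1e-9)

  expect_error(render_cvp_waveform(6, -1), "non-negative")
})

test_that("Doppler renderer inverts the stroke-volume formula", {
  beats <- simulate_beat_train(60, 10)
  ch <- render_doppler_velocity(beats, rep(70, 10), angle = 20, diameter = 20,
                                rate = 300)
  v <- beat_vti(ch, beats[1], beats[2], ejection_threshold_frac = 0)
  expect_equal(v$vti, 70 * cos(20 * pi / 180) / pi, tolerance = 0.05)
  expect_equal(v$vti, 20.94, tolerance = 0.06)

  ch0 <- render_doppler_velocity(beats, rep(70, 10), angle = 0, diameter = 20,
                                 rate = 300)
  v0 <- beat_vti(ch0, beats[1], beats[2], ejection_threshold_frac = 0)
  expect_equal(v0$vti, 70 / pi, tolerance = 0.05)

  # constant sv vector: all beat VTIs equal
  win <- beat_windows(beats)
  vt <- vapply(seq_len(nrow(win)), function(i)
    beat_vti(ch, win$start[i], win$end[i])$vti, 0)
  expect_lt(diff(range(vt)), 1e-9)

  expect_error(render_doppler_velocity(beats, rep(70, 3)), "one entry per beat")
})

test_that("simulated truth reproduces the study's dropout pattern", {
  cfg <- simulation_config(n_subjects = 20, dropout = c(20, 19, 13, 5),
                           interventions = "PEP", rng_seed = 3)
  tr <- simulate_truth(cfg)
  per_step <- tapply(tr$subject, tr$step, function(s) length(unique(s)))
  expect_equal(as.vector(per_step), c(20, 20, 19, 13, 5))
  expect_true(all(tr$true_dpp > 0 & tr$true_dpop > 0 & tr$true_dcvp > 0))
  # one row per subject x completed step x resistance
  expect_equal(nrow(tr), (20 + 20 + 19 + 13 + 5) * 3)
})

test_that("noiseless generative model is exactly identifiable from its truth", {
  cfg <- simulation_config(n_subjects = 4, subject_sd = 0, residual_sd = 0,
                           interventions = "PEP", rng_seed = 5)
  tr <- simulate_truth(cfg)
  tr$dpp <- tr$true_dpp
  m <- suppressWarnings(pvar_model(tr, outcome = "dpp", intervention = "PEP"))
  s <- m$slopes
  expect_equal(s$slope[s$resistance == "0"], cfg$slope_log_dpp, tolerance = 1e-8)
  expect_equal(s$slope[s$resistance == "10"],
               cfg$slope_log_dpp + cfg$resistance_effects[["10"]],
               tolerance = 1e-8)
})

test_that("identical seeds give byte-identical simulated datasets", {
  cfg <- noiseless_config(n_subjects = 1, lbnp_levels = c(0, 20),
                          interventions = "PEP", resistance_levels = c(0, 5),
                          breaths_per_sequence = 3,
                          resp_rate = c(mean = 14, sd = 1), rng_seed = 9)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  m1 <- run_simulate(cfg, d1, quiet = TRUE)
  m2 <- run_simulate(cfg, d2, quiet = TRUE)
  expect_identical(m1$files, m2$files)
  expect_identical(m1$config_hash, m2$config_hash)
  f <- "S01_abp.txt"
  expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})
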