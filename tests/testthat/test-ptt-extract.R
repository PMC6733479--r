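test_that("linear upsampling is exact on linear signals and bounded on smooth ones", {
  wf_const <- waveform(rep(2.5, 100), 125)
  up <- upsample_waveform(wf_const, 500)
  expect_true(all(up$value == 2.5))
  expect_equal(wf_fs(up), 500)

  ramp <- waveform(seq(0, 1, length.out = 126), 125)
  up_r <- upsample_waveform(ramp, 500)
  expect_equal(up_r$value, up_r$t, tolerance = 1e-12)

  # interpolation error bound for a 1 Hz sine: (dt)^2 * max|f''| / 8
  t125 <- (0:249) / 125
  wf_sin <- waveform(sin(2 * pi * t125), 125)
  up_s <- upsample_waveform(wf_sin, 500)
  bound <- (1 / 125)^2 * (2 * pi)^2 / 8
  expect_lt(max(abs(up_s$value - sin(2 * pi * up_s$t))), bound * 1.01)

  expect_error(upsample_waveform(wf_const, 50), "target_fs")
})

test_that("R-peak detection recovers simulated beats to sample precision", {
  cfg <- quick_cfg(duration = 120, mean_hr = 60, noise_sd_ecg = 0, seed = 8)
  beats <- generate_beat_times(cfg)
  ecg <- synthesize_ecg(beats, cfg)
  r <- detect_r_peaks(ecg)
  truth <- beats[beats >= 0.5 & beats <= 120 - 0.5]
  expect_equal(length(r), length(truth))
  expect_lt(max(abs(r - truth)), 1 / cfg$fs_ecg + 1e-9)
})

test_that("flat ECG yields zero detections with a warning", {
  flat <- waveform(rep(0.3, 10 * 500), 500)
  expect_warning(r <- detect_r_peaks(flat), "flat")
  expect_length(r, 0)
  expect_error(detect_r_peaks(waveform(rnorm(100), 500)), "5 s")
})

test_that("R-peak detection at SNR 10 keeps sensitivity and PPV above 99%", {
  cfg <- quick_cfg(duration = 300, noise_sd_ecg = 0.1, seed = 21)
  beats <- generate_beat_times(cfg)
  ecg <- synthesize_ecg(beats, cfg)
  r <- detect_r_peaks(ecg)
  truth <- beats[beats >= 0.5 & beats <= 300 - 0.5]
  tol <- 0.05
  hits <- vapply(truth, function(b) any(abs(r - b) <= tol), logical(1))
  matched <- vapply(r, function(p) any(abs(truth - p) <= tol), logical(1))
  expect_gte(mean(hits), 0.99) # sensitivity
  expect_gte(mean(matched), 0.99) # positive predictivity
})

test_that("pulse arrival lands on the steepest ascent of the pulse", {
  cfg <- quick_cfg(duration = 4, noise_sd_ppg = 0)
  ppg <- upsample_waveform(synthesize_ppg(1, 0.25, cfg), 500)

  # bare argmax localizes within one native PPG sample of the truth
  a0 <- detect_pulse_arrival(ppg, 1, refine = "none")
  expect_lt(abs(a0 - 1.25), 1 / cfg$fs_ppg)

  # parabolic refinement sharpens it well below a native sample
  a1 <- detect_pulse_arrival(ppg, 1)
  expect_lt(abs(a1 - 1.25), 0.003)

  # no ascent in the window: missing
  dec <- waveform(seq(1, 0, length.out = 2000), 500)
  expect_true(is.na(detect_pulse_arrival(dec, 1)))

  # window past the record end: missing
  expect_true(is.na(detect_pulse_arrival(ppg, 3.5)))

  # two candidate upstrokes: the steeper (second) one wins
  t <- (0:999) / 500
  v <- numeric(1000)
  v[t >= 0.2 & t < 0.3] <- (t[t >= 0.2 & t < 0.3] - 0.2) * 2 # slope 2
  v[t >= 0.3] <- 0.2
  v[t >= 0.5 & t < 0.55] <- 0.2 + (t[t >= 0.5 & t < 0.55] - 0.5) * 8 # slope 8
  v[t >= 0.55] <- 0.6
  two <- waveform(v, 500)
  a2 <- detect_pulse_arrival(two, 0, w_min = 0.1, w_max = 0.7, refine = "none")
  expect_gt(a2, 0.5)
  expect_lt(a2, 0.55)
})

test_that("PTT pairing subtracts, drops missing and enforces a minimum count", {
  out <- compute_ptt(c(0, 1, 2), c(0.25, 1.25, 2.25), min_beats = 1)
  expect_equal(out$ptt, rep(0.25, 3))

  out2 <- compute_ptt(c(0, 1, 2), c(0.25, NA, 2.25), min_beats = 1)
  expect_equal(out2$r_time, c(0, 2))

  expect_error(compute_ptt(c(0, 1, 2), c(0.25, 1.25, 2.25)), "valid beats")
  expect_error(compute_ptt(1:3, 1:2), "paired")
})

test_that("4 Hz spline resampling interpolates the knots exactly", {
  beats <- tibble::tibble(r_time = as.numeric(0:19), ptt = rep(0.25, 20))
  u <- resample_ptt(beats)
  expect_equal(diff(u$t), rep(0.25, nrow(u) - 1))
  expect_true(all(abs(u$ptt - 0.25) < 1e-12))

  # knots reproduced where grid points coincide with beat times
  set.seed(1)
  beats2 <- tibble::tibble(r_time = as.numeric(0:19), ptt = 0.25 + rnorm(20, 0, 0.01))
  u2 <- resample_ptt(beats2)
  at_knots <- u2$ptt[u2$t %in% beats2$r_time]
  expect_equal(at_knots, beats2$ptt, tolerance = 1e-12)

  # 0.05 Hz sine at HR 60: grid error below 1 ms against the closed form
  bt <- as.numeric(0:199)
  beats3 <- tibble::tibble(r_time = bt, ptt = 0.25 + 0.01 * sin(2 * pi * 0.05 * bt))
  u3 <- resample_ptt(beats3)
  expect_lt(max(abs(u3$ptt - (0.25 + 0.01 * sin(2 * pi * 0.05 * u3$t)))), 0.001)

  expect_error(resample_ptt(tibble::tibble(r_time = c(0, 1, 1, 2), ptt = rep(0.2, 4))), "duplicate")
  expect_error(resample_ptt(tibble::tibble(r_time = 0:2, ptt = rep(0.2, 3))), "4 beats")
})

test_that("end-to-end extraction recovers the true PTT at zero drift and noise", {
  cfg <- sim_config(duration = 300, noise_sd_ecg = 0, noise_sd_ppg = 0, seed = 3)
  rec <- simulate_recording(cfg, clock_preset("clean"))
  ps <- extract_ptt(rec)
  truth_fun <- stats::spline(rec$truth$beat_time, rec$truth$true_ptt,
    xout = ps$uniform$t, method = "natural"
  )$y
  # localization floor: half a native PPG sample plus refinement/spline error
  expect_lt(max(abs(ps$uniform$ptt - truth_fun)), 0.0045)
  expect_lt(abs(mean(ps$beats$ptt) - mean(rec$truth$true_ptt)), 0.001)
})

test_that("clock drift transfers into the extracted PTT as the predicted sawtooth", {
  cfg <- sim_config(duration = 1600, ptt_modulations = list(), rr_jitter_sd = 0.005, seed = 11)
  rec <- simulate_recording(cfg, clock_preset("skwhsmh"))
  ps <- extract_ptt(rec)

  # extracted = true - offset: residual vs ground truth matches the offset
  off <- stats::approx(rec$offset$t, rec$offset$offset_s, xout = ps$beats$r_time)$y
  tru <- stats::approx(rec$truth$beat_time, rec$truth$true_ptt, xout = ps$beats$r_time)$y
  expect_lt(sqrt(mean((ps$beats$ptt - tru + off)^2, na.rm = TRUE)), 0.004)

  # jump train: period 100 +/- 2 s
  jumps <- detect_artifact_jumps(ps)
  expect_gte(length(jumps), 14)
  expect_lt(abs(stats::median(diff(jumps)) - 100), 2)

  # folded artifact template: a linear ramp of peak-to-peak 8 +/- 2 ms
  # (sd-based estimate: an ideal ramp has p2p = sqrt(12) * sd)
  tpl <- estimate_sawtooth_template(ps, period = 100)
  expect_lt(abs(sqrt(12) * stats::sd(tpl$template) - 0.008), 0.002)

  # mean recovery within one PPG sample
  expect_lt(abs(mean(ps$beats$ptt) - mean(rec$truth$true_ptt)), 0.008)
})

test_that("pairing is monotone and strictly positive", {
  cfg <- quick_cfg(duration = 120, seed = 14)
  rec <- simulate_recording(cfg, clock_preset("skwhsmh"))
  ps <- extract_ptt(rec)
  expect_true(all(ps$beats$ptt > 0))
  expect_true(all(diff(ps$beats$r_time) > 0))
  expect_true(!anyDuplicated(ps$beats$arrival_time))
  expect_true(all(ps$beats$arrival_time > ps$beats$r_time))
})

test_that("zero drift leaves no artifact-band excess over the noise floor", {
  rec <- simulate_recording(sim_config(duration = 1600, seed = 9), clock_preset("clean"))
  ps <- extract_ptt(rec)
  sp <- power_spectrum(ps)
  m_band <- stats::median(sp$power[sp$freq >= 0.005 & sp$freq <= 0.02])
  m_flank <- stats::median(sp$power[sp$freq > 0.02 & sp$freq <= 0.05])
  expect_lt(m_band, 3 * m_flank)
})
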