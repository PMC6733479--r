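params_quiet <- function(...) suppressWarnings(deshape_params(...))

test_that("STFT frames put a pure tone's ridge at its frequency", {
  y <- physio_series(f = 0.1, amplitude = 0.005, noise_sd = 0, duration = 1600)
  fr <- stft_frames(y, params = params_quiet())
  ridge <- apply(fr$mag, 1, function(m) fr$freqs[which.max(m[fr$freqs > 0.002])] + 0)
  # restrict argmax away from DC leakage
  sel <- fr$freqs > 0.002
  ridge <- apply(fr$mag[, sel], 1, function(m) fr$freqs[sel][which.max(m)])
  expect_true(all(abs(ridge - 0.1) < 2 * diff(fr$freqs[1:2])))

  # independent brute-force DFT oracle for one frame at the tone frequency
  nw <- fr$nw
  seg <- y$ptt[1:nw]
  seg <- stats::.lm.fit(cbind(1, seq_len(nw)), seg)$residuals
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(nw - 1)) / (nw - 1))
  k <- which.min(abs(fr$freqs - 0.1)) - 1L
  brute <- abs(sum(seg * w * exp(-2i * pi * k * (0:(nw - 1)) / fr$nfft)))
  expect_equal(fr$mag[1, k + 1L], brute, tolerance = 1e-9)

  # zero signal: all-zero magnitudes
  z <- tibble::tibble(t = y$t, ptt = rep(0, nrow(y)))
  expect_true(all(stft_frames(z, params = params_quiet())$mag == 0))

  expect_error(
    stft_frames(physio_series(duration = 200), params = params_quiet()),
    "window longer"
  )
})

test_that("plain STFT of a sawtooth keeps its harmonics", {
  x <- saw_series(noise_sd = 0)
  stf <- stft_tfr(x, params_quiet())
  prof <- colMeans(stf$values)
  at <- function(f) prof[which.min(abs(stf$freqs - f))]
  # harmonic magnitudes roughly 1/k of the fundamental
  expect_gt(at(0.02) / at(0.01), 0.3)
  expect_gt(at(0.03) / at(0.01), 0.15)
})

test_that("short-time cepstrum peaks at the period and its multiples", {
  t <- seq(0, 1599.75, 0.25)
  # three-harmonic signal with period 50 s
  x <- tibble::tibble(
    t = t,
    ptt = 0.25 + 0.003 * sin(2 * pi * 0.02 * t) +
      0.002 * sin(2 * pi * 0.04 * t) + 0.001 * sin(2 * pi * 0.06 * t)
  )
  fr <- stft_frames(x, params = params_quiet())
  cep <- short_time_cepstrum(fr)
  expect_true(all(cep$values >= 0))
  sel <- which(cep$quefrency >= 6 & cep$quefrency <= 250)
  v <- cep$values[40, sel]
  q <- cep$quefrency[sel]
  # global max at the period, and a local peak at twice the period
  expect_lt(abs(q[which.max(v)] - 50), 1)
  # a clear local peak survives at twice the period
  near_2T <- abs(q - 100) <= 2
  expect_gt(max(v[near_2T]), 5 * stats::median(v))

  expect_error(short_time_cepstrum(fr, gamma = 0), "gamma")

  # quefrency peak location is invariant to the magnitude exponent
  cep2 <- short_time_cepstrum(fr, gamma = 0.45)
  v2 <- cep2$values[40, sel]
  expect_lt(abs(q[which.max(v2)] - q[which.max(v)]), 1)
})

test_that("white-noise frames carry no coherent cepstral peak", {
  x <- saw_series(noise_sd = 0)
  fr_s <- stft_frames(x, params = params_quiet())
  ref <- short_time_cepstrum(fr_s)
  sel <- which(ref$quefrency >= 6 & ref$quefrency <= 250)
  peak_ref <- max(ref$values[30, sel])
  # matched-variance noise: sawtooth p2p 8 ms has SD ~2.3 ms
  ok <- vapply(1:20, function(s) {
    y <- physio_series(amplitude = 0, noise_sd = 0.0023, seed = s)
    cep <- short_time_cepstrum(stft_frames(y, params = params_quiet()))
    max(cep$values[30, sel]) < 0.25 * peak_ref
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("deshape keeps the fundamental and suppresses harmonics", {
  x <- saw_series(noise_sd = 0)
  tf <- dsstft(x, params_quiet())
  stf <- stft_tfr(x, params_quiet())
  expect_true(all(tf$values >= 0) && all(is.finite(tf$values)))

  bw <- freq_bin_width(tf)
  argmax <- apply(tf$values, 1, function(v) tf$freqs[which.max(v)])
  expect_true(all(abs(argmax - 0.01) <= bw + 1e-12))

  at <- function(m, f) {
    prof <- colMeans(m$values)
    prof[which.min(abs(m$freqs - f))]
  }
  r_ds <- at(tf, 0.02) / at(tf, 0.01)
  r_st <- at(stf, 0.02) / at(stf, 0.01)
  expect_lt(r_ds, 0.25)
  expect_gt(r_st, 0.3) # the plain STFT keeps the ~1/2 magnitude harmonic
  expect_lt(r_ds, 0.5 * r_st)
})

test_that("a pure tone's deshape ridge matches the STFT ridge", {
  y <- physio_series(f = 0.1, amplitude = 0.005, noise_sd = 0)
  tf <- dsstft(y, params_quiet())
  stf <- stft_tfr(y, params_quiet())
  r1 <- extract_ridge(tf)
  r2 <- extract_ridge(stf)
  expect_true(all(abs(r1$freq - r2$freq) <= freq_bin_width(tf) + 1e-12))
})

test_that("two independent tones both survive de-shaping", {
  t <- seq(0, 1599.75, 0.25)
  x <- tibble::tibble(
    t = t,
    ptt = 0.25 + 0.003 * sin(2 * pi * 0.01 * t) + 0.003 * sin(2 * pi * 0.095 * t)
  )
  tf <- dsstft(x, params_quiet())
  prof <- colMeans(tf$values)
  lo <- tf$freqs >= 0.005 & tf$freqs <= 0.02
  hi <- tf$freqs >= 0.08 & tf$freqs <= 0.11
  expect_lt(abs(tf$freqs[lo][which.max(prof[lo])] - 0.01), 0.001)
  expect_lt(abs(tf$freqs[hi][which.max(prof[hi])] - 0.095), 0.001)
  # both lines prominent relative to the band between them
  mid <- tf$freqs > 0.03 & tf$freqs < 0.07
  expect_gt(max(prof[lo]), 3 * max(prof[mid]))
  expect_gt(max(prof[hi]), 3 * max(prof[mid]))
})

test_that("ridge extraction tracks constant and drifting fundamentals", {
  r <- extract_ridge(dsstft(saw_series(noise_sd = 5e-4), params_quiet()))
  expect_true(all(abs(r$freq - 0.01) < 0.001, na.rm = TRUE))

  # chirp fundamental 0.008 -> 0.012 Hz: monotone increasing ridge
  t <- seq(0, 1599.75, 0.25)
  ph <- 2 * pi * (0.008 * t + (0.012 - 0.008) * t^2 / (2 * max(t)))
  xc <- tibble::tibble(t = t, ptt = 0.25 + 0.008 * ((ph / (2 * pi)) %% 1 - 0.5))
  rc <- extract_ridge(dsstft(xc, params_quiet()), band = c(0.005, 0.02))
  expect_gt(stats::cor(rc$time, rc$freq, method = "spearman"), 0.9)
  expect_gt(rc$freq[nrow(rc)], rc$freq[1])

  # zero signal: ridge undefined
  z <- tibble::tibble(t = t, ptt = rep(0, length(t)))
  rz <- extract_ridge(dsstft(z, params_quiet()))
  expect_true(all(is.na(rz$freq)))
})

test_that("time-shifting the input shifts ridges in time, not frequency", {
  y <- physio_series(f = 0.095, amplitude = 0.004, noise_sd = 0, duration = 2000)
  p <- params_quiet()
  tf_full <- dsstft(y, p)
  shifted <- y[y$t >= 200, ]
  tf_shift <- dsstft(shifted, p)
  expect_equal(tf_shift$times[1] - tf_full$times[1], 200, tolerance = 0.25)
  r_full <- extract_ridge(tf_full)
  r_shift <- extract_ridge(tf_shift)
  common <- intersect(round(r_full$time, 6), round(r_shift$time, 6))
  expect_gt(length(common), 50)
  f1 <- r_full$freq[match(common, round(r_full$time, 6))]
  f2 <- r_shift$freq[match(common, round(r_shift$time, 6))]
  expect_true(all(abs(f1 - f2) <= freq_bin_width(tf_full) + 1e-12, na.rm = TRUE))
})

test_that("parameter validation rejects degenerate grids", {
  expect_error(deshape_params(gamma = 1.2), "gamma")
  expect_error(deshape_params(cepstral_threshold = 1), "threshold")
  expect_error(deshape_params(freq_range = c(0, 0.15)), "0 Hz")
  expect_warning(deshape_params(window_length = 100, freq_range = c(0.004, 0.15)), "cycles")
})
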