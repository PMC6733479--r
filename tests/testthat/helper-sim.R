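# small, fast configs and direct PTT-series constructors shared across tests

quick_cfg <- function(duration = 60, seed = 1L, ...) {
  sim_config(duration = duration, seed = seed, ...)
}

# 4 Hz PTT series with a known sawtooth artifact injected directly
saw_series <- function(duration = 1600, period = 100, amplitude = 0.008,
                       noise_sd = 0.001, baseline = 0.25, seed = 1L,
                       extra = function(t) 0) {
  t <- seq(0, duration - 0.25, by = 0.25)
  withr::with_seed(seed, {
    tibble::tibble(
      t = t,
      ptt = baseline + ideal_sawtooth(t, period, amplitude) + extra(t) +
        stats::rnorm(length(t), 0, noise_sd)
    )
  })
}

# 4 Hz series with physiology only (no artifact)
physio_series <- function(duration = 1600, f = 0.095, amplitude = 0.003,
                          noise_sd = 0.001, baseline = 0.25, seed = 1L) {
  t <- seq(0, duration - 0.25, by = 0.25)
  withr::with_seed(seed, {
    tibble::tibble(
      t = t,
      ptt = baseline + amplitude * sin(2 * pi * f * t) +
        stats::rnorm(length(t), 0, noise_sd)
    )
  })
}

freq_bin_width <- function(tf) diff(tf$freqs[1:2])

# fraction of ridge frames within one display bin of f0
ridge_frac_at <- function(tf, f0) {
  r <- extract_ridge(tf)
  mean(abs(r$freq - f0) <= freq_bin_width(tf) + 1e-12, na.rm = TRUE)
}

# hand-built flat spectrum for tie-break tests
flat_spectrum <- function(delta_f = 0.0025, fs = 4, value = 1) {
  sp <- tibble::tibble(freq = seq(0, fs / 2, by = delta_f), power = value)
  attr(sp, "fs") <- fs
  attr(sp, "n") <- round(fs / delta_f)
  attr(sp, "delta_f") <- delta_f
  attr(sp, "ms_input") <- value
  class(sp) <- c("ptt_spectrum", class(sp))
  sp
}
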