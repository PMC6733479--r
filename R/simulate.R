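#' Simulation configuration for paired ECG/PPG recordings
#'
#' Describes a synthetic subject: heart rate and its variability, the true
#' pulse transit time (PTT) and its physiological modulations, channel noise
#' and sampling rates. Defaults emulate an adult under monitoring: heart rate
#' 75 bpm with respiratory (0.25 Hz) and low-frequency (0.1 Hz) RR
#' modulation, PTT baseline 250 ms modulated by respiration (0.25 Hz, 2 ms)
#' and a Mayer-wave component (0.1 Hz, 1.5 ms), ECG at 500 Hz and PPG at
#' 125 Hz as delivered by the patient monitors the artifact was observed on.
#'
#' @param duration Recording length in seconds (> 0). Default 1600 s, the
#'   shortest record length used for cohort displays.
#' @param mean_hr Mean heart rate in beats/min, in (20, 250).
#' @param hrv_amplitudes List of `c(frequency_hz, amplitude_s)` pairs
#'   modulating the RR interval sinusoidally.
#' @param rr_jitter_sd SD of white beat-to-beat RR jitter, seconds.
#' @param ptt_baseline Baseline PTT in seconds (> 0).
#' @param ptt_modulations List of `c(frequency_hz, amplitude_s)` pairs
#'   modulating the true PTT sinusoidally.
#' @param ptt_trend Optional piecewise-linear additive trend: a two-column
#'   matrix or list of `c(time_s, value_s)` breakpoints.
#' @param ptt_episodes Optional list of `c(frequency_hz, amplitude_s,
#'   start_s, end_s)` transient modulations active only inside the stated
#'   interval (models episodic physiology such as intermittent Mayer waves).
#' @param noise_sd_ecg,noise_sd_ppg SD of additive Gaussian sensor noise
#'   (a.u.); the R wave and pulse amplitudes are 1.
#' @param fs_ecg,fs_ppg Sampling rates in Hz; defaults 500 and 125.
#' @param seed Integer seed; all channels draw reproducible sub-streams.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(duration = 1600,
                       mean_hr = 75,
                       hrv_amplitudes = list(c(0.25, 0.02), c(0.1, 0.03)),
                       rr_jitter_sd = 0.01,
                       ptt_baseline = 0.25,
                       ptt_modulations = list(c(0.25, 0.002), c(0.1, 0.0015)),
                       ptt_trend = NULL,
                       ptt_episodes = NULL,
                       noise_sd_ecg = 0.05,
                       noise_sd_ppg = 0.002,
                       fs_ecg = 500,
                       fs_ppg = 125,
                       seed = 1L) {
  stopifnot(length(duration) == 1L, length(mean_hr) == 1L)
  if (duration <= 0) stop("`duration` must be > 0", call. = FALSE)
  if (mean_hr <= 20 || mean_hr >= 250) stop("`mean_hr` must lie in (20, 250)", call. = FALSE)
  if (ptt_baseline <= 0) stop("`ptt_baseline` must be > 0", call. = FALSE)
  if (rr_jitter_sd < 0 || noise_sd_ecg < 0 || noise_sd_ppg < 0) {
    stop("noise standard deviations must be >= 0", call. = FALSE)
  }
  # templates: QRS bump has ~60 Hz content, PPG upstroke ~15 Hz
  if (fs_ecg < 120) stop("`fs_ecg` must exceed twice the QRS template bandwidth (>= 120 Hz)", call. = FALSE)
  if (fs_ppg < 30) stop("`fs_ppg` must exceed twice the pulse template bandwidth (>= 30 Hz)", call. = FALSE)
  check_pairs <- function(x, nm, len = 2L) {
    if (is.null(x)) return(list())
    x <- lapply(x, as.numeric)
    ok <- vapply(x, function(p) length(p) == len && all(is.finite(p)), logical(1))
    if (!all(ok)) stop(sprintf("`%s` entries must be numeric of length %d", nm, len), call. = FALSE)
    if (any(vapply(x, function(p) p[2] < 0, logical(1)))) {
      stop(sprintf("`%s` amplitudes must be >= 0", nm), call. = FALSE)
    }
    x
  }
  cfg <- list(
    duration = duration, mean_hr = mean_hr,
    hrv_amplitudes = check_pairs(hrv_amplitudes, "hrv_amplitudes"),
    rr_jitter_sd = rr_jitter_sd,
    ptt_baseline = ptt_baseline,
    ptt_modulations = check_pairs(ptt_modulations, "ptt_modulations"),
    ptt_trend = if (is.null(ptt_trend)) NULL else do.call(rbind, lapply(ptt_trend, as.numeric)),
    ptt_episodes = check_pairs(ptt_episodes, "ptt_episodes", len = 4L),
    noise_sd_ecg = noise_sd_ecg, noise_sd_ppg = noise_sd_ppg,
    fs_ecg = fs_ecg, fs_ppg = fs_ppg,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' Dual-clock model of the acquisition chain
#'
#' Hypothesised mechanism for the sawtooth artifact: the PPG timebase runs at
#' a rate `1 + drift_ppm * 1e-6` relative to the ECG timebase, and whenever
#' the accumulated inter-channel offset reaches `correction_trigger` the
#' chain corrects it by an instantaneous jump of `correction_quantum`
#' (one sample dropped or held). The resulting alignment offset is a
#' sawtooth of amplitude `correction_quantum` and period
#' `correction_quantum / (drift_ppm * 1e-6)` seconds. The patient monitor's
#' internals are not public; this model is one mechanism sufficient to
#' reproduce the observed phenomenology, not a verified description.
#'
#' @param drift_ppm Relative rate offset of the PPG clock, parts per million
#'   (>= 0; 0 disables the artifact).
#' @param correction_quantum Timing jump per correction event, seconds;
#'   default one nominal PPG sample period (8 ms at 125 Hz).
#' @param correction_trigger Accumulated-offset threshold that fires a
#'   correction, seconds; defaults to `correction_quantum`.
#' @param initial_offset Alignment offset at t = 0, seconds.
#' @return A list of class `clock_model`.
#' @seealso [clock_preset()] for the named presets used throughout.
#' @export
clock_model <- function(drift_ppm,
                        correction_quantum = 1 / 125,
                        correction_trigger = correction_quantum,
                        initial_offset = 0) {
  if (drift_ppm < 0) stop("`drift_ppm` must be >= 0", call. = FALSE)
  if (correction_quantum <= 0) stop("`correction_quantum` must be > 0", call. = FALSE)
  if (correction_trigger <= 0) stop("`correction_trigger` must be > 0", call. = FALSE)
  m <- list(
    drift_ppm = drift_ppm,
    correction_quantum = correction_quantum,
    correction_trigger = correction_trigger,
    initial_offset = initial_offset
  )
  class(m) <- "clock_model"
  m
}

#' Named clock-model presets
#'
#' Presets reproduce the artifact periods observed clinically with an 8 ms
#' (one PPG sample) correction quantum: period = quantum / (drift * 1e-6).
#'
#' * `"skwhsmh"`: 80 ppm -> 100 s period
#' * `"cgmh150"`: 53.333 ppm -> 150 s period
#' * `"cgmh75"`: 106.667 ppm -> 75 s period
#' * `"cgmh10"`: 800 ppm -> 10 s period
#' * `"clean"`: zero drift, no artifact
#'
#' @param name Preset name.
#' @return A [clock_model()].
#' @export
clock_preset <- function(name = c("skwhsmh", "cgmh75", "cgmh150", "cgmh10", "clean")) {
  name <- match.arg(name)
  drift <- switch(name,
    skwhsmh = 80,
    cgmh75 = 0.008 / 75 * 1e6,
    cgmh150 = 0.008 / 150 * 1e6,
    cgmh10 = 0.008 / 10 * 1e6,
    clean = 0
  )
  clock_model(drift_ppm = drift, correction_quantum = 0.008)
}

#' Generate beat (R-peak) times
#'
#' Instantaneous RR = 60 / mean_hr plus the summed sinusoidal HRV
#' modulations (random phase per component) plus white jitter. Beats are
#' emitted on `[0, duration)` starting at t = 0.
#'
#' @param config A [sim_config()].
#' @return Numeric vector of strictly increasing beat times, seconds.
#' @export
generate_beat_times <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::local_seed(sub_seed(config$seed, 1L))
  mods <- config$hrv_amplitudes
  phases <- stats::runif(length(mods), 0, 2 * pi)
  rr_mean <- 60 / config$mean_hr
  # generous upper bound on beat count for preallocation
  n_max <- ceiling(config$duration / rr_mean * 2) + 16L
  beats <- numeric(n_max)
  jitter <- if (config$rr_jitter_sd > 0) stats::rnorm(n_max, 0, config$rr_jitter_sd) else numeric(n_max)
  t <- 0
  n <- 0L
  while (t < config$duration) {
    n <- n + 1L
    beats[n] <- t
    rr <- rr_mean + jitter[n]
    for (i in seq_along(mods)) {
      rr <- rr + mods[[i]][2] * sin(2 * pi * mods[[i]][1] * t + phases[i])
    }
    if (rr <= 0) stop("realized RR interval <= 0; reduce modulation amplitudes or jitter", call. = FALSE)
    t <- t + rr
  }
  beats[seq_len(n)]
}

piecewise_trend <- function(t, breakpoints) {
  if (is.null(breakpoints) || nrow(breakpoints) == 0L) return(rep(0, length(t)))
  if (nrow(breakpoints) == 1L) return(rep(breakpoints[1, 2], length(t)))
  stats::approx(breakpoints[, 1], breakpoints[, 2], xout = t, rule = 2)$y
}

#' Synthesize the true PTT for each beat
#'
#' `ptt(t_b) = baseline + sum(amplitude * sin(2 pi f t_b + phase)) +
#' trend(t_b) + episodic terms`. Phases are drawn once per component from
#' the config's seeded sub-stream.
#'
#' @param beat_times Beat times from [generate_beat_times()].
#' @param config A [sim_config()].
#' @return Numeric vector of per-beat PTT values, seconds (all > 0).
#' @export
synthesize_true_ptt <- function(beat_times, config) {
  stopifnot(inherits(config, "sim_config"))
  if (length(beat_times) == 0L) stop("`beat_times` must be nonempty", call. = FALSE)
  withr::local_seed(sub_seed(config$seed, 2L))
  mods <- config$ptt_modulations
  phases <- stats::runif(length(mods), 0, 2 * pi)
  eps <- config$ptt_episodes
  eps_phases <- stats::runif(length(eps), 0, 2 * pi)
  ptt <- rep(config$ptt_baseline, length(beat_times))
  for (i in seq_along(mods)) {
    ptt <- ptt + mods[[i]][2] * sin(2 * pi * mods[[i]][1] * beat_times + phases[i])
  }
  ptt <- ptt + piecewise_trend(beat_times, config$ptt_trend)
  for (i in seq_along(eps)) {
    e <- eps[[i]]
    on <- beat_times >= e[3] & beat_times <= e[4]
    ptt[on] <- ptt[on] + e[2] * sin(2 * pi * e[1] * beat_times[on] + eps_phases[i])
  }
  if (any(ptt <= 0)) stop("synthesized PTT <= 0; check baseline/modulations/trend", call. = FALSE)
  ptt
}

# QRS stand-in: Gaussian bump, global max exactly at the beat time
qrs_template_sd <- 0.008

#' Synthesize an ECG-like waveform
#'
#' Sum of a narrow Gaussian QRS-like template (SD 8 ms, amplitude 1)
#' centered at each beat time, plus white Gaussian noise. Morphological
#' realism (P/T waves) is out of scope; only R-peak timing matters here.
#'
#' @param beat_times Beat times, seconds, within `[0, duration]`.
#' @param config A [sim_config()].
#' @return A [waveform()] at `config$fs_ecg`, label `"ECG"`.
#' @export
synthesize_ecg <- function(beat_times, config) {
  stopifnot(inherits(config, "sim_config"))
  fs <- config$fs_ecg
  n <- round(config$duration * fs)
  x <- numeric(n)
  half <- ceiling(5 * qrs_template_sd * fs)
  for (b in beat_times) {
    c_idx <- round(b * fs) # 0-based
    idx <- max(0L, c_idx - half):min(n - 1L, c_idx + half)
    if (length(idx) == 0L) next
    x[idx + 1L] <- x[idx + 1L] + exp(-((idx / fs - b)^2) / (2 * qrs_template_sd^2))
  }
  if (config$noise_sd_ecg > 0) {
    withr::local_seed(sub_seed(config$seed, 3L))
    x <- x + stats::rnorm(n, 0, config$noise_sd_ecg)
  }
  waveform(x, fs, label = "ECG")
}

#' PPG pulse template (closed form)
#'
#' Raised-cosine upstroke of width `width` followed by exponential decay
#' with time constant `tau`:
#' `p(s) = (1 - cos(pi s / width)) / 2` for `0 <= s <= width`,
#' `p(s) = exp(-(s - width) / tau)` for `s > width`, else 0.
#' Its steepest ascent is analytically at `s = width / 2`.
#'
#' @param s Time since pulse onset, seconds (vectorized).
#' @param width Upstroke width, seconds (default 120 ms).
#' @param tau Decay time constant, seconds (default 300 ms).
#' @return Template values in `[0, 1]`.
#' @export
ppg_pulse_template <- function(s, width = 0.12, tau = 0.3) {
  out <- numeric(length(s))
  up <- s >= 0 & s <= width
  dn <- s > width
  out[up] <- 0.5 * (1 - cos(pi * s[up] / width))
  out[dn] <- exp(-(s[dn] - width) / tau)
  out
}

#' Synthesize a PPG-like waveform
#'
#' Each beat contributes one [ppg_pulse_template()] pulse placed so that its
#' continuous-time steepest-ascent instant equals
#' `beat_time + true_ptt` exactly (pulse onset at
#' `beat_time + true_ptt - width/2`), plus white Gaussian noise.
#'
#' @param beat_times Beat times, seconds.
#' @param true_ptt Per-beat PTT values, seconds; same length.
#' @param config A [sim_config()].
#' @param width,tau Pulse template parameters, seconds.
#' @return A [waveform()] at `config$fs_ppg`, label `"PPG"`.
#' @export
synthesize_ppg <- function(beat_times, true_ptt, config, width = 0.12, tau = 0.3) {
  stopifnot(inherits(config, "sim_config"))
  if (length(beat_times) != length(true_ptt)) {
    stop("`beat_times` and `true_ptt` must have equal length", call. = FALSE)
  }
  if (length(beat_times) >= 2L) {
    rr_min <- min(diff(beat_times))
    if (width + tau > 0.9 * rr_min) {
      stop("pulses would overlap beyond 90% of the RR interval; lower HR or shorten the template", call. = FALSE)
    }
  }
  fs <- config$fs_ppg
  n <- round(config$duration * fs)
  x <- numeric(n)
  ext <- width + 5 * tau
  for (k in seq_along(beat_times)) {
    onset <- beat_times[k] + true_ptt[k] - width / 2
    i0 <- max(0L, ceiling(onset * fs))
    i1 <- min(n - 1L, floor((onset + ext) * fs))
    if (i1 < i0) next
    idx <- i0:i1
    x[idx + 1L] <- x[idx + 1L] + ppg_pulse_template(idx / fs - onset, width, tau)
  }
  if (config$noise_sd_ppg > 0) {
    withr::local_seed(sub_seed(config$seed, 4L))
    x <- x + stats::rnorm(n, 0, config$noise_sd_ppg)
  }
  waveform(x, fs, label = "PPG")
}

#' Apply dual-clock skew to a waveform
#'
#' Emulates an acquisition chain whose timebase drifts relative to nominal:
#' the recorded sample at nominal time t carries the true signal at
#' `t + offset(t)`, where the accumulated offset grows at
#' `drift_ppm * 1e-6` s/s and is reset by `correction_quantum` whenever it
#' reaches `correction_trigger`. Implemented by linear-interpolation
#' resampling of the true signal at the distorted time grid.
#'
#' @param wf A [waveform()] (normally the PPG channel).
#' @param clock A [clock_model()].
#' @return A list with elements `waveform` (the skewed recording),
#'   `correction_times` (seconds of each correction event) and `offset`
#'   (tibble `t`, `offset_s`: the alignment-offset function, a sawtooth).
#' @export
apply_clock_skew <- function(wf, clock) {
  stopifnot(inherits(clock, "clock_model"))
  fs <- wf_fs(wf)
  t <- wf$t
  r <- clock$drift_ppm * 1e-6
  if (r == 0) {
    return(list(
      waveform = wf,
      correction_times = numeric(0),
      offset = tibble::tibble(t = t, offset_s = rep(clock$initial_offset, length(t)))
    ))
  }
  acc <- clock$initial_offset + r * t
  off <- acc - clock$correction_quantum * floor(acc / clock$correction_trigger)
  k_min <- floor(clock$initial_offset / clock$correction_trigger) + 1
  k_max <- floor(max(acc) / clock$correction_trigger)
  corr <- if (k_max >= k_min) {
    (seq(k_min, k_max) * clock$correction_trigger - clock$initial_offset) / r
  } else {
    numeric(0)
  }
  y <- stats::approx(t, wf$value, xout = t + off, rule = 2)$y
  list(
    waveform = waveform(y, fs, label = wf_label(wf), t0 = t[1]),
    correction_times = corr,
    offset = tibble::tibble(t = t, offset_s = off)
  )
}

#' Simulate a complete paired ECG/PPG recording
#'
#' Runs the full generator: beat times, true PTT, ECG and PPG synthesis,
#' then clock skew on the PPG channel only (only inter-channel alignment
#' matters for PTT; one-sided drift is the minimal model). Bit-identical
#' output for identical `config` + seed.
#'
#' @param config A [sim_config()].
#' @param clock A [clock_model()]; default `clock_preset("clean")`.
#' @return A list of class `monitor_recording`: `ecg`, `ppg` (waveforms),
#'   `truth` (tibble `beat_time`, `true_ptt`), `correction_times`, `offset`
#'   (alignment-offset tibble), `config`, `clock`.
#' @export
#' @examples
#' rec <- simulate_recording(sim_config(duration = 30, seed = 7))
#' rec$truth
simulate_recording <- function(config, clock = clock_preset("clean")) {
  beats <- generate_beat_times(config)
  ptt <- synthesize_true_ptt(beats, config)
  ecg <- synthesize_ecg(beats, config)
  ppg0 <- synthesize_ppg(beats, ptt, config)
  sk <- apply_clock_skew(ppg0, clock)
  out <- list(
    ecg = ecg,
    ppg = sk$waveform,
    truth = tibble::tibble(beat_time = beats, true_ptt = ptt),
    correction_times = sk$correction_times,
    offset = sk$offset,
    config = config,
    clock = clock
  )
  class(out) <- "monitor_recording"
  out
}

#' @export
print.monitor_recording <- function(x, ...) {
  cat(sprintf(
    "<monitor_recording> %.0f s, %d beats, drift %.4g ppm (%s artifact)\n",
    x$config$duration, nrow(x$truth), x$clock$drift_ppm,
    if (x$clock$drift_ppm > 0) "sawtooth" else "no"
  ))
  invisible(x)
}

#' Ideal zero-mean sawtooth wave
#'
#' Linear ramp rising by `amplitude` over each `period`, resetting abruptly;
#' mean removed. Used as a closed-form reference in tests and to construct
#' PTT series carrying a known artifact.
#'
#' @param t Times, seconds.
#' @param period Sawtooth period, seconds.
#' @param amplitude Peak-to-peak amplitude.
#' @param phase Phase offset, seconds.
#' @return Numeric vector.
#' @export
ideal_sawtooth <- function(t, period, amplitude, phase = 0) {
  amplitude * (((t - phase) %% period) / period - 0.5)
}
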