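#' Upsample a waveform by linear interpolation
#'
#' The PPG channel is upsampled to the ECG rate (500 Hz) by linear
#' interpolation before pulse-arrival detection. Values at grid points that
#' coincide with original samples are unchanged.
#'
#' @param wf A [waveform()].
#' @param target_fs Target sampling rate, Hz; must be >= `wf_fs(wf)`.
#' @return A [waveform()] at `target_fs` spanning the original record.
#' @export
upsample_waveform <- function(wf, target_fs = 500) {
  fs <- wf_fs(wf)
  if (target_fs < fs) stop("`target_fs` must be >= the waveform's sampling rate", call. = FALSE)
  if (!all(is.finite(wf$value))) stop("non-finite samples", call. = FALSE)
  t_new <- seq(wf$t[1], wf$t[nrow(wf)], by = 1 / target_fs)
  y <- stats::approx(wf$t, wf$value, xout = t_new)$y
  waveform(y, target_fs, label = wf_label(wf), t0 = wf$t[1])
}

#' Detect R peaks in an ECG waveform
#'
#' Pan-Tompkins-style detector: 5-25 Hz band-pass (zero-phase Butterworth),
#' squared derivative, 120 ms moving-window integration, adaptive
#' signal/noise threshold with a 250 ms refractory period, then refinement
#' to the local maximum of the raw ECG within +/- 50 ms.
#'
#' Detections within `edge_guard` of the record ends are dropped: the
#' band-pass filter transient there mislocalizes truncated QRS complexes.
#'
#' @param ecg A [waveform()] of at least 5 s.
#' @param refractory Minimum R-R separation, seconds.
#' @param edge_guard Guard band at both record ends, seconds.
#' @return Numeric vector of R-peak times, seconds (possibly empty, with a
#'   warning, for flat input).
#' @export
detect_r_peaks <- function(ecg, refractory = 0.25, edge_guard = 0.5) {
  fs <- wf_fs(ecg)
  x <- ecg$value
  n <- length(x)
  if (n < 5 * fs) stop("need at least 5 s of ECG", call. = FALSE)
  if (diff(range(x)) == 0) {
    warning("flat ECG signal: no R peaks detected")
    return(numeric(0))
  }
  bf <- signal::butter(2, c(5, 25) / (fs / 2), type = "pass")
  xf <- signal::filtfilt(bf, x)
  d2 <- (c(0, diff(xf)) * fs)^2
  k <- max(3L, round(0.12 * fs))
  env <- as.numeric(stats::filter(d2, rep(1 / k, k), sides = 2))
  env[is.na(env)] <- 0
  if (max(env) <= 0) {
    warning("no QRS energy found: no R peaks detected")
    return(numeric(0))
  }
  i <- 2:(n - 1L)
  cand <- i[env[i] > env[i - 1L] & env[i] >= env[i + 1L]]
  if (length(cand) == 0L) {
    warning("no QRS energy found: no R peaks detected")
    return(numeric(0))
  }
  spki <- max(env[seq_len(min(n, round(3 * fs)))])
  npki <- stats::median(env)
  thr <- npki + 0.25 * (spki - npki)
  acc <- integer(0)
  for (p in cand) {
    if (length(acc) > 0L && (p - acc[length(acc)]) / fs < refractory) {
      if (env[p] > env[acc[length(acc)]]) acc[length(acc)] <- p
      next
    }
    if (env[p] > thr) {
      acc <- c(acc, p)
      spki <- 0.125 * env[p] + 0.875 * spki
    } else {
      npki <- 0.125 * env[p] + 0.875 * npki
    }
    thr <- npki + 0.25 * (spki - npki)
  }
  if (length(acc) == 0L) {
    warning("no peaks above threshold: no R peaks detected")
    return(numeric(0))
  }
  half <- round(0.05 * fs)
  half <- as.integer(half)
  refined <- vapply(as.integer(acc), function(p) {
    lo <- max(1L, p - half)
    hi <- min(n, p + half)
    lo + which.max(x[lo:hi]) - 1L
  }, integer(1))
  refined <- sort(unique(refined))
  # enforce refractory after refinement, keeping the taller raw peak
  keep <- refined[1]
  for (p in refined[-1]) {
    last <- keep[length(keep)]
    if ((p - last) / fs < refractory) {
      if (x[p] > x[last]) keep[length(keep)] <- p
    } else {
      keep <- c(keep, p)
    }
  }
  out <- ecg$t[keep]
  out[out >= ecg$t[1] + edge_guard & out <= ecg$t[n] - edge_guard]
}

#' Detect pulse-arrival times on a PPG waveform
#'
#' The pulse arrival for each R peak is the instant of the fastest PPG
#' ascent: the maximum of the first difference, restricted to rising
#' segments, within the physiological search window
#' `(r + w_min, r + w_max]`. On ties (the first difference of a linearly
#' upsampled signal is piecewise constant) the center of the maximal run is
#' taken. Beats whose window has no rising segment, or extends past the
#' record end, are returned as `NA`.
#'
#' After linear upsampling the derivative is constant across each native
#' PPG sample interval, so the raw argmax only localizes the steepest
#' native segment. With `refine = "parabolic"` (default) the instant is
#' refined to sub-sample precision by fitting a parabola through the slopes
#' of the three neighboring native segments (standard peak interpolation);
#' `refine = "none"` keeps the center of the steepest segment.
#'
#' @param ppg A [waveform()], already upsampled to the ECG rate (500 Hz).
#' @param r_times R-peak times from [detect_r_peaks()].
#' @param w_min,w_max Search window after each R peak, seconds.
#' @param smooth If `TRUE`, smooth the derivative with a 20 ms moving
#'   average before taking the maximum.
#' @param refine Sub-sample refinement of the derivative maximum.
#' @param native_dt Native (pre-upsampling) PPG sample period, seconds;
#'   spacing of the slope samples used for parabolic refinement.
#' @return Numeric vector, one arrival time (or `NA`) per R peak.
#' @export
detect_pulse_arrival <- function(ppg, r_times, w_min = 0.1, w_max = 0.7, smooth = FALSE,
                                 refine = c("parabolic", "none"), native_dt = 0.008) {
  refine <- match.arg(refine)
  fs <- wf_fs(ppg)
  v <- ppg$value
  t <- ppg$t
  n <- length(v)
  d <- diff(v)
  if (smooth) {
    k <- max(3L, round(0.02 * fs))
    d <- as.numeric(stats::filter(d, rep(1 / k, k), sides = 2))
    d[is.na(d)] <- 0
  }
  td <- (t[-1] + t[-n]) / 2
  t_end <- t[n]
  td1 <- td[1]
  nd <- n - 1L
  vapply(r_times, function(r) {
    if (r + w_max > t_end) return(NA_real_)
    # td is uniform: window indices by arithmetic, not a full scan
    i_lo <- max(1L, as.integer(floor((r + w_min - td1) * fs + 1)) + 1L)
    i_hi <- min(nd, as.integer(floor((r + w_max - td1) * fs + 1)))
    if (i_hi < i_lo) return(NA_real_)
    win <- i_lo:i_hi
    dw <- d[win]
    pos <- dw > 0
    if (!any(pos)) return(NA_real_)
    m <- max(dw[pos])
    tol <- 1e-9 * max(abs(m), 1e-12)
    best <- win[pos][which.max(dw[pos])]
    # walk the contiguous rising run of tied maxima around `best`
    lo <- best
    while (lo - 1L >= i_lo && d[lo - 1L] >= m - tol) lo <- lo - 1L
    hi <- best
    while (hi + 1L <= i_hi && d[hi + 1L] >= m - tol) hi <- hi + 1L
    a <- (td[lo] + td[hi]) / 2
    if (refine == "parabolic") {
      c0 <- as.integer(round((lo + hi) / 2))
      step <- max(1L, as.integer(round(native_dt * fs)))
      idx <- c0 + (-2:2) * step
      if (idx[1] >= 1L && idx[5] <= nd) {
        xo <- (-2:2) * native_dt
        fit <- stats::.lm.fit(cbind(1, xo, xo^2), d[idx])
        a2 <- fit$coefficients[3]
        if (a2 < 0) {
          delta <- -fit$coefficients[2] / (2 * a2)
          a <- a + max(-1.5 * native_dt, min(1.5 * native_dt, delta))
        }
      }
    }
    a
  }, numeric(1))
}

#' Beat-indexed pulse transit time
#'
#' `ptt = arrival - r` for each R peak with a non-missing paired arrival;
#' pairs with PTT outside `(min_ptt, max_ptt)` are dropped.
#'
#' @param r_times,arrival_times Paired vectors from the two detectors.
#' @param min_ptt,max_ptt Plausibility bounds on PTT, seconds.
#' @param min_beats Minimum number of valid beats required (default 10).
#' @return Tibble with columns `r_time`, `arrival_time`, `ptt` (valid beats
#'   only; beats with missing arrivals are absent).
#' @export
compute_ptt <- function(r_times, arrival_times, min_ptt = 0.1, max_ptt = 0.7,
                        min_beats = 10L) {
  if (length(r_times) != length(arrival_times)) {
    stop("`r_times` and `arrival_times` must be paired", call. = FALSE)
  }
  ptt <- arrival_times - r_times
  ok <- is.finite(ptt) & ptt > min_ptt & ptt < max_ptt
  if (sum(ok) < min_beats) {
    stop(sprintf("only %d valid beats (< %d)", sum(ok), min_beats), call. = FALSE)
  }
  tibble::tibble(
    r_time = r_times[ok],
    arrival_time = arrival_times[ok],
    ptt = ptt[ok]
  )
}

#' Resample a beat-indexed PTT series onto a uniform grid
#'
#' Natural cubic spline through the `(r_time, ptt)` knots, evaluated on a
#' uniform grid (default 4 Hz, spacing exactly 0.25 s) anchored at the first
#' beat time and confined to the beat-time span (no extrapolation).
#'
#' @param beats Tibble with columns `r_time` and `ptt` (from
#'   [compute_ptt()]).
#' @param rate Grid rate, Hz.
#' @return Tibble with columns `t`, `ptt`.
#' @export
resample_ptt <- function(beats, rate = 4) {
  bt <- beats$r_time
  y <- beats$ptt
  if (length(bt) < 4L) stop("need at least 4 beats for spline resampling", call. = FALSE)
  if (anyDuplicated(bt)) stop("duplicate beat times", call. = FALSE)
  grid <- seq(bt[1], bt[length(bt)], by = 1 / rate)
  s <- stats::spline(bt, y, xout = grid, method = "natural")
  tibble::tibble(t = grid, ptt = s$y)
}

#' Extract the beat-to-beat PTT signal from a paired recording
#'
#' Full extraction pipeline: linear upsampling of the PPG to the ECG rate,
#' R-peak detection, steepest-ascent pulse-arrival detection, beat pairing,
#' and 4 Hz natural-cubic-spline resampling.
#'
#' @param ecg,ppg [waveform()]s, or a `monitor_recording` passed as `ecg`.
#' @param target_fs Upsampling rate for the PPG, Hz.
#' @param rate Uniform resampling rate, Hz.
#' @param w_min,w_max Pulse-arrival search window, seconds.
#' @param min_beats Minimum valid beats (see [compute_ptt()]).
#' @return An object of class `ptt_series`: list with `beats` (tibble
#'   `r_time`, `arrival_time`, `ptt`), `uniform` (tibble `t`, `ptt`) and
#'   `rate`. Use [tidy()][generics::tidy] for the uniform series and
#'   [glance()][generics::glance] for summary statistics.
#' @export
#' @examples
#' rec <- simulate_recording(sim_config(duration = 60, seed = 2))
#' ps <- extract_ptt(rec)
#' glance(ps)
extract_ptt <- function(ecg, ppg = NULL, target_fs = 500, rate = 4,
                        w_min = 0.1, w_max = 0.7, min_beats = 10L) {
  if (inherits(ecg, "monitor_recording")) {
    ppg <- ecg$ppg
    ecg <- ecg$ecg
  }
  ppg_hi <- upsample_waveform(ppg, target_fs)
  r <- detect_r_peaks(ecg)
  a <- detect_pulse_arrival(ppg_hi, r, w_min = w_min, w_max = w_max)
  beats <- compute_ptt(r, a, min_ptt = w_min, max_ptt = w_max, min_beats = min_beats)
  uniform <- resample_ptt(beats, rate = rate)
  out <- list(beats = beats, uniform = uniform, rate = rate)
  class(out) <- "ptt_series"
  out
}

#' @export
print.ptt_series <- function(x, ...) {
  cat(sprintf(
    "<ptt_series> %d beats over %.1f s; %d uniform samples at %g Hz; mean PTT %.1f ms\n",
    nrow(x$beats), diff(range(x$beats$r_time)), nrow(x$uniform), x$rate,
    1000 * mean(x$beats$ptt)
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname extract_ptt
#' @param x A `ptt_series`.
#' @param ... Unused.
#' @method tidy ptt_series
#' @export
tidy.ptt_series <- function(x, ...) x$uniform

#' @rdname extract_ptt
#' @method glance ptt_series
#' @export
glance.ptt_series <- function(x, ...) {
  tibble::tibble(
    n_beats = nrow(x$beats),
    duration_s = diff(range(x$beats$r_time)),
    mean_ptt_s = mean(x$beats$ptt),
    sd_ptt_s = stats::sd(x$beats$ptt),
    rate_hz = x$rate
  )
}

#' @rdname extract_ptt
#' @param object A `ptt_series`.
#' @method autoplot ptt_series
#' @export
autoplot.ptt_series <- function(object, ...) {
  ggplot2::ggplot(object$uniform, ggplot2::aes(x = .data$t, y = 1000 * .data$ptt)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "PTT (ms)") +
    ggplot2::theme_minimal()
}
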