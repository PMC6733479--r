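#' Parameters for the de-shape short-time Fourier transform
#'
#' Defaults are sized for a 4 Hz PTT series holding a ~0.01 Hz artifact:
#' a 400 s Hann window (4 cycles at 0.01 Hz), 10 s hop, cepstral exponent
#' `gamma = 0.3`, per-frame soft threshold at the 0.9 cepstral quantile, and
#' a 512-bin display grid over 0.004-0.15 Hz. A warning is raised when the
#' window holds fewer than two cycles of the lowest display frequency.
#'
#' @param window_length Window length, seconds.
#' @param hop Frame hop, seconds.
#' @param gamma Cepstral magnitude exponent, in (0, 1); small values flatten
#'   the spectral envelope before the cepstrum is taken.
#' @param cepstral_threshold Per-frame soft-threshold quantile, in `[0, 1)`.
#' @param freq_range Display band `c(f_lo, f_hi)` in Hz; must exclude 0 Hz
#'   (the quefrency inversion 1/f is undefined there).
#' @param freq_bins Number of display frequency bins.
#' @param zero_pad FFT zero-padding factor (power-of-two target =
#'   `zero_pad * window samples`).
#' @return A list of class `deshape_params`.
#' @export
deshape_params <- function(window_length = 400, hop = 10, gamma = 0.3,
                           cepstral_threshold = 0.9,
                           freq_range = c(0.004, 0.15), freq_bins = 512L,
                           zero_pad = 8) {
  if (gamma <= 0 || gamma >= 1) stop("`gamma` must lie in (0, 1)", call. = FALSE)
  if (cepstral_threshold < 0 || cepstral_threshold >= 1) {
    stop("`cepstral_threshold` must lie in [0, 1)", call. = FALSE)
  }
  if (freq_range[1] <= 0) stop("`freq_range` must exclude 0 Hz", call. = FALSE)
  if (freq_range[2] <= freq_range[1]) stop("`freq_range` must be increasing", call. = FALSE)
  if (window_length * freq_range[1] < 2) {
    warning("window holds fewer than 2 cycles of the lowest display frequency")
  }
  p <- list(
    window_length = window_length, hop = hop, gamma = gamma,
    cepstral_threshold = cepstral_threshold,
    freq_range = as.numeric(freq_range), freq_bins = as.integer(freq_bins),
    zero_pad = zero_pad
  )
  class(p) <- "deshape_params"
  p
}

#' Short-time Fourier transform magnitude frames
#'
#' Hann-windowed, per-frame linearly detrended, zero-padded frames. For a
#' pure tone the magnitude at the tone's frequency is the frame maximum.
#'
#' @param x Numeric signal, or tibble with columns `t` and `ptt`.
#' @param fs Sampling rate, Hz (ignored when `x` is a tibble).
#' @param params A [deshape_params()].
#' @param detrend_frames Remove a per-frame linear trend before windowing.
#' @return An object of class `stft_frames`: list with `times` (frame
#'   centers, s), `freqs` (full one-sided FFT grid, Hz), `mag` (frames x
#'   freqs magnitude matrix), `fs`, `nfft`, `nw`, `t0`, `params`.
#' @export
stft_frames <- function(x, fs = NULL, params = deshape_params(), detrend_frames = TRUE) {
  t0 <- 0
  if (is.data.frame(x)) {
    t0 <- x$t[1]
    fs <- 1 / diff(x$t[1:2])
    x <- x$ptt
  }
  if (is.null(fs)) stop("`fs` required for a bare numeric signal", call. = FALSE)
  n <- length(x)
  nw <- round(params$window_length * fs)
  if (nw > n) stop("window longer than signal", call. = FALSE)
  nh <- max(1L, round(params$hop * fs))
  nfft <- 2^ceiling(log2(nw * params$zero_pad))
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(nw - 1)) / (nw - 1))
  starts <- seq(1L, n - nw + 1L, by = nh)
  nf <- nfft / 2 + 1L
  mag <- matrix(0, nrow = length(starts), ncol = nf)
  basis <- cbind(1, seq_len(nw))
  for (j in seq_along(starts)) {
    seg <- x[starts[j]:(starts[j] + nw - 1L)]
    if (detrend_frames) seg <- stats::.lm.fit(basis, seg)$residuals
    X <- stats::fft(c(seg * w, numeric(nfft - nw)))
    mag[j, ] <- Mod(X[seq_len(nf)])
  }
  out <- list(
    times = t0 + (starts - 1 + (nw - 1) / 2) / fs,
    freqs = (0:(nfft / 2)) * fs / nfft,
    mag = mag, fs = fs, nfft = nfft, nw = nw, t0 = t0, params = params
  )
  class(out) <- "stft_frames"
  out
}

#' Short-time cepstrum of STFT frames
#'
#' Per frame, the inverse Fourier transform over frequency of the
#' gamma-powered magnitude spectrum. A harmonic frame with period T yields
#' cepstral energy at quefrencies T, 2T, ... Each frame is soft-thresholded
#' at the stated quantile of its positive-quefrency cepstrum and clipped at
#' zero; the quefrency-0 term is removed.
#'
#' @param frames An `stft_frames` object.
#' @param gamma Cepstral exponent (> 0); defaults to the frames' params.
#' @param threshold Soft-threshold quantile; defaults to the frames' params.
#' @return An object of class `cepstrum_frames`: `times`, `quefrency`
#'   (seconds), `values` (frames x quefrencies, nonnegative).
#' @export
short_time_cepstrum <- function(frames, gamma = NULL, threshold = NULL) {
  stopifnot(inherits(frames, "stft_frames"))
  gamma <- gamma %||% frames$params$gamma
  threshold <- threshold %||% frames$params$cepstral_threshold
  if (gamma <= 0) stop("`gamma` must be > 0", call. = FALSE)
  nfft <- frames$nfft
  nq <- nfft / 2 + 1L
  vals <- matrix(0, nrow = nrow(frames$mag), ncol = nq)
  for (j in seq_len(nrow(frames$mag))) {
    mg <- frames$mag[j, ]^gamma
    full <- c(mg, rev(mg[2:(nfft / 2)])) # hermitian-symmetric magnitude
    cep <- Re(stats::fft(full, inverse = TRUE)) / nfft
    cep <- cep[seq_len(nq)]
    thr <- stats::quantile(cep[-1], threshold, names = FALSE)
    cep <- pmax(cep - thr, 0)
    cep[1] <- 0
    vals[j, ] <- cep
  }
  out <- list(
    times = frames$times,
    quefrency = (0:(nq - 1L)) / frames$fs,
    values = vals,
    params = frames$params
  )
  class(out) <- "cepstrum_frames"
  out
}

new_tfr <- function(times, freqs, values, params, meta = list()) {
  out <- c(list(times = times, freqs = freqs, values = values, params = params), meta)
  class(out) <- "tfr"
  out
}

#' De-shape combination of STFT and cepstral frames
#'
#' Builds `U(t, f)` by evaluating each cepstral frame at quefrency `1/f`
#' (linear interpolation; quefrencies above the window length excluded) and
#' returns `W(t, f) = |STFT(t, f)| * U(t, f)`, clipped at zero, on the
#' display grid. For a harmonic signal with fundamental f0 the per-frame
#' maximum of W sits at f0 and the harmonics are suppressed relative to the
#' plain STFT, because the cepstrum has no peak at quefrency `1/(2 f0)`.
#'
#' @param frames An `stft_frames` object.
#' @param cepstral An optional `cepstrum_frames`; computed from `frames`
#'   when omitted.
#' @param params A [deshape_params()]; defaults to the frames' params.
#' @return A time-frequency representation of class `tfr`: `times` (s),
#'   `freqs` (Hz), `values` (nonnegative frames x freqs matrix), `params`.
#' @export
deshape <- function(frames, cepstral = NULL, params = NULL) {
  stopifnot(inherits(frames, "stft_frames"))
  params <- params %||% frames$params
  cepstral <- cepstral %||% short_time_cepstrum(frames)
  if (length(cepstral$times) != length(frames$times)) {
    stop("STFT and cepstral frames do not match", call. = FALSE)
  }
  fgrid <- seq(params$freq_range[1], params$freq_range[2], length.out = params$freq_bins)
  if (any(fgrid == 0)) stop("display grid must exclude 0 Hz", call. = FALSE)
  q_target <- 1 / fgrid
  q_ok <- q_target <= params$window_length & q_target <= max(cepstral$quefrency)
  nt <- length(frames$times)
  W <- matrix(0, nrow = nt, ncol = length(fgrid))
  for (j in seq_len(nt)) {
    m <- stats::approx(frames$freqs, frames$mag[j, ], xout = fgrid, rule = 2)$y
    u <- numeric(length(fgrid))
    if (any(q_ok)) {
      u[q_ok] <- stats::approx(cepstral$quefrency, cepstral$values[j, ],
        xout = q_target[q_ok], rule = 2
      )$y
    }
    W[j, ] <- pmax(m * u, 0)
  }
  new_tfr(frames$times, fgrid, W, params,
    meta = list(window_length = params$window_length, hop = params$hop)
  )
}

#' De-shape short-time Fourier transform of a PTT series
#'
#' Convenience wrapper: global linear detrend, [stft_frames()],
#' [short_time_cepstrum()], [deshape()].
#'
#' @param ptt Tibble `t`, `ptt` (uniform grid) or a `ptt_series`.
#' @param params A [deshape_params()].
#' @return A `tfr` object; see [deshape()].
#' @export
#' @examples
#' t <- seq(0, 800, by = 0.25)
#' x <- tibble::tibble(t = t, ptt = 0.25 + ideal_sawtooth(t, 100, 0.008))
#' tf <- dsstft(x, deshape_params(window_length = 300))
#' extract_ridge(tf)
dsstft <- function(ptt, params = deshape_params()) {
  if (inherits(ptt, "ptt_series")) ptt <- ptt$uniform
  x <- ptt$ptt
  x <- stats::.lm.fit(cbind(1, seq_along(x)), x)$residuals
  frames <- stft_frames(tibble::tibble(t = ptt$t, ptt = x), params = params)
  deshape(frames, short_time_cepstrum(frames), params)
}

#' Plain STFT magnitude on the display grid
#'
#' The un-deshaped counterpart of [dsstft()], for harmonic-suppression
#' comparisons.
#'
#' @inheritParams dsstft
#' @return A `tfr` object holding `|STFT|` on the display grid.
#' @export
stft_tfr <- function(ptt, params = deshape_params()) {
  if (inherits(ptt, "ptt_series")) ptt <- ptt$uniform
  x <- ptt$ptt
  x <- stats::.lm.fit(cbind(1, seq_along(x)), x)$residuals
  frames <- stft_frames(tibble::tibble(t = ptt$t, ptt = x), params = params)
  fgrid <- seq(params$freq_range[1], params$freq_range[2], length.out = params$freq_bins)
  W <- t(apply(frames$mag, 1, function(m) stats::approx(frames$freqs, m, xout = fgrid, rule = 2)$y))
  new_tfr(frames$times, fgrid, W, params,
    meta = list(window_length = params$window_length, hop = params$hop)
  )
}

#' Extract the dominant ridge of a TF representation
#'
#' Per-frame argmax frequency within `band`, median-smoothed over 5 frames.
#' Frames with no positive energy are returned as `NA`.
#'
#' @param tf A `tfr` object.
#' @param band Optional `c(f_lo, f_hi)` restriction, Hz.
#' @param k Median smoothing width, frames (odd).
#' @return Tibble `time`, `freq`.
#' @export
extract_ridge <- function(tf, band = NULL, k = 5L) {
  stopifnot(inherits(tf, "tfr"))
  sel <- if (is.null(band)) {
    seq_along(tf$freqs)
  } else {
    which(tf$freqs >= band[1] & tf$freqs <= band[2])
  }
  if (length(sel) == 0L) stop("band outside the frequency grid", call. = FALSE)
  f <- apply(tf$values[, sel, drop = FALSE], 1, function(v) {
    if (all(v <= 0) || any(!is.finite(v))) NA_real_ else tf$freqs[sel][which.max(v)]
  })
  if (length(f) >= k && any(!is.na(f))) {
    filled <- f
    filled[is.na(filled)] <- stats::median(f, na.rm = TRUE)
    sm <- stats::runmed(filled, k)
    sm[is.na(f)] <- NA_real_
    f <- as.numeric(sm)
  }
  tibble::tibble(time = tf$times, freq = f)
}

#' @export
print.tfr <- function(x, ...) {
  cat(sprintf(
    "<tfr> %d frames x %d frequency bins; t in [%.0f, %.0f] s; f in [%.4g, %.4g] Hz\n",
    length(x$times), length(x$freqs), min(x$times), max(x$times),
    min(x$freqs), max(x$freqs)
  ))
  invisible(x)
}

#' @rdname deshape
#' @param x A `tfr`.
#' @param ... Unused.
#' @method tidy tfr
#' @export
tidy.tfr <- function(x, ...) {
  tibble::tibble(
    time = rep(x$times, times = length(x$freqs)),
    freq = rep(x$freqs, each = length(x$times)),
    value = as.vector(x$values)
  )
}

#' @rdname deshape
#' @method glance tfr
#' @export
glance.tfr <- function(x, ...) {
  ridge <- extract_ridge(x)
  tibble::tibble(
    n_frames = length(x$times),
    n_freqs = length(x$freqs),
    window_s = x$params$window_length,
    hop_s = x$params$hop,
    ridge_median_hz = stats::median(ridge$freq, na.rm = TRUE)
  )
}

#' @rdname deshape
#' @param object A `tfr`.
#' @method autoplot tfr
#' @export
autoplot.tfr <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$time, y = .data$freq, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "intensity") +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)") +
    ggplot2::theme_minimal()
}
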