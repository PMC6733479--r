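#' Power spectrum of a uniform PTT series
#'
#' One-sided periodogram of the linearly detrended, Hann-tapered series.
#' Power is scaled so that `sum(power) * delta_f` equals the mean square of
#' the detrended, tapered input (Parseval). A single full-record taper is
#' used (rather than Welch averaging) because distinguishing nearby artifact
#' lines (0.01 vs 0.012 Hz) needs the full-record frequency resolution;
#' Welch averaging is available via `segments`.
#'
#' @param ptt A tibble with columns `t` and `ptt` (uniform grid), or a
#'   `ptt_series` from [extract_ptt()].
#' @param detrend Remove a linear trend first (default `TRUE`); slow
#'   blood-pressure-reciprocal trends would otherwise mask the
#'   low-frequency artifact peaks.
#' @param segments Number of Welch segments (50% overlap); 1 = plain
#'   periodogram.
#' @return A tibble of class `ptt_spectrum` with columns `freq` (Hz, 0 to
#'   Nyquist) and `power` (a.u.), carrying attributes `fs`, `n`, `delta_f`
#'   and `ms_input` (the tapered mean square, for Parseval checks).
#' @export
power_spectrum <- function(ptt, detrend = TRUE, segments = 1L) {
  if (inherits(ptt, "ptt_series")) ptt <- ptt$uniform
  x <- ptt$ptt
  t <- ptt$t
  if (any(!is.finite(x))) stop("non-finite values in PTT series", call. = FALSE)
  dt <- diff(t)
  if (max(abs(dt - dt[1])) > 1e-8) stop("PTT series must be uniformly sampled", call. = FALSE)
  fs <- 1 / dt[1]
  n <- length(x)
  if (n / fs < 60) stop("need at least 60 s of PTT signal", call. = FALSE)
  one_segment <- function(x) {
    n <- length(x)
    if (detrend) {
      x <- stats::.lm.fit(cbind(1, seq_len(n)), x)$residuals
    } else {
      x <- x - mean(x)
    }
    w <- 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
    xw <- x * w
    X <- stats::fft(xw)
    nf <- floor(n / 2) + 1L
    p <- Mod(X[seq_len(nf)])^2 / (n * fs)
    ck <- rep(2, nf)
    ck[1] <- 1
    if (n %% 2 == 0) ck[nf] <- 1
    list(power = p * ck, ms = mean(xw^2), n = n)
  }
  if (segments <= 1L) {
    seg <- one_segment(x)
    nseg <- seg$n
    power <- seg$power
    ms <- seg$ms
  } else {
    len <- floor(n / ((segments + 1) / 2))
    hop <- floor(len / 2)
    starts <- seq(1, n - len + 1, by = hop)
    pieces <- lapply(starts, function(s) one_segment(x[s:(s + len - 1)]))
    nseg <- len
    power <- Reduce(`+`, lapply(pieces, `[[`, "power")) / length(pieces)
    ms <- mean(vapply(pieces, `[[`, numeric(1), "ms"))
  }
  out <- tibble::tibble(freq = (seq_along(power) - 1) * fs / nseg, power = power)
  attr(out, "fs") <- fs
  attr(out, "n") <- n
  attr(out, "delta_f") <- fs / nseg
  attr(out, "ms_input") <- ms
  class(out) <- c("ptt_spectrum", class(out))
  out
}

artifact_bins <- c(0.0067, 0.01, 0.012, 0.0133, 0.1)
bin_levels <- c("0.0067", "0.01", "0.012", "0.0133", "0.1", "other")

#' Dominant frequency of a PTT power spectrum
#'
#' The argmax of power within `band`, classified into the artifact/Mayer
#' frequency bins observed clinically (0.0067, 0.01, 0.012, 0.0133 and
#' 0.1 Hz; bin tolerance +/- 15% of the bin center, nearest bin by relative
#' distance). Ties break toward the lower frequency. Claims finer than two
#' grid bins are refused: the band floor is raised to `2 * delta_f` with a
#' warning when needed, and a warning is issued when the record holds fewer
#' than three periods of the dominant frequency.
#'
#' @param spec A `ptt_spectrum` from [power_spectrum()].
#' @param band Search band `c(f_lo, f_hi)` in Hz; the default covers all
#'   clinically reported dominants while excluding DC and
#'   cardiac/respiratory lines.
#' @return One-row tibble: `f_dom` (Hz), `bin_label` (factor), and
#'   `peak_prominence` (peak power / median band power).
#' @export
dominant_frequency <- function(spec, band = c(0.004, 0.15)) {
  stopifnot(inherits(spec, "ptt_spectrum"))
  df_ <- attr(spec, "delta_f")
  lo <- band[1]
  if (2 * df_ > lo) {
    lo <- 2 * df_
    warning(sprintf(
      "frequency resolution %.4g Hz too coarse for the requested band floor; using %.4g Hz",
      df_, lo
    ))
  }
  sel <- which(spec$freq >= lo & spec$freq <= band[2])
  if (length(sel) == 0L) stop("empty search band", call. = FALSE)
  i <- sel[which.max(spec$power[sel])]
  f_dom <- spec$freq[i]
  rel <- abs(f_dom - artifact_bins) / artifact_bins
  label <- if (min(rel) <= 0.15) as.character(artifact_bins[which.min(rel)]) else "other"
  n_periods <- attr(spec, "n") / attr(spec, "fs") * f_dom
  if (n_periods < 3) {
    warning(sprintf(
      "record holds only %.1f periods of the dominant frequency; estimate unreliable", n_periods
    ))
  }
  tibble::tibble(
    f_dom = f_dom,
    bin_label = factor(label, levels = bin_levels),
    peak_prominence = spec$power[i] / stats::median(spec$power[sel])
  )
}

#' Cohort bin-count table
#'
#' Tallies per-subject dominant-frequency reports into the artifact
#' frequency bins.
#'
#' @param reports A tibble of stacked [dominant_frequency()] rows (one per
#'   subject), or a list of such rows.
#' @return Tibble `bin_label`, `n` with all bins present (zero counts kept);
#'   counts total the number of subjects.
#' @export
cohort_bin_table <- function(reports) {
  if (is.list(reports) && !is.data.frame(reports)) reports <- dplyr::bind_rows(reports)
  if (nrow(reports) == 0L) stop("no subjects", call. = FALSE)
  reports |>
    dplyr::mutate(bin_label = factor(as.character(.data$bin_label), levels = bin_levels)) |>
    dplyr::count(.data$bin_label, .drop = FALSE)
}

#' Detect artifact jumps in a uniform PTT series
#'
#' Locates the abrupt resets of a sawtooth artifact as local maxima of the
#' lagged difference `x(t + lag) - x(t)` exceeding `min_jump`, separated by
#' at least `min_sep`. The clock-correction reset (one PPG sample, 8 ms) is
#' smeared over roughly one RR interval by beat sampling and spline
#' resampling, hence the ~1 s lag.
#'
#' @param ptt Tibble `t`, `ptt` (uniform), or a `ptt_series`.
#' @param min_jump Minimum jump height, seconds (default 5 ms, between the
#'   8 ms correction quantum and the beat-level measurement noise).
#' @param lag Differencing lag, seconds.
#' @param min_sep Minimum separation between jumps, seconds.
#' @param smooth_s Running-median pre-smoothing width, seconds (suppresses
#'   beat-level measurement noise while keeping the jump edges).
#' @return Numeric vector of jump times, seconds.
#' @export
detect_artifact_jumps <- function(ptt, min_jump = 0.005, lag = 6, min_sep = 10,
                                  smooth_s = 5) {
  if (inherits(ptt, "ptt_series")) ptt <- ptt$uniform
  x <- ptt$ptt
  t <- ptt$t
  fs <- 1 / diff(t[1:2])
  if (smooth_s > 0) {
    k <- round(smooth_s * fs)
    if (k %% 2 == 0) k <- k + 1L
    if (k >= 3 && length(x) > k) x <- as.numeric(stats::runmed(x, k))
  }
  L <- max(1L, round(lag * fs))
  n <- length(x)
  if (n <= L) return(numeric(0))
  d <- abs(x[(L + 1):n] - x[seq_len(n - L)])
  tc <- (t[(L + 1):n] + t[seq_len(n - L)]) / 2
  cand <- which(d > min_jump)
  if (length(cand) == 0L) return(numeric(0))
  cand <- cand[order(d[cand], decreasing = TRUE)]
  keep <- numeric(0)
  for (i in cand) {
    if (all(abs(tc[i] - keep) >= min_sep)) keep <- c(keep, tc[i])
  }
  sort(keep)
}

#' @rdname power_spectrum
#' @param object A `ptt_spectrum`.
#' @param ... Unused.
#' @method autoplot ptt_spectrum
#' @export
autoplot.ptt_spectrum <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object)[-1, ], ggplot2::aes(x = .data$freq, y = .data$power)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "frequency (Hz)", y = "power (a.u.)") +
    ggplot2::theme_minimal()
}
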