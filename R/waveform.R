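#' Construct a uniformly sampled waveform
#'
#' A waveform is a tibble with columns `t` (seconds) and `value` (arbitrary
#' units), carrying its sampling rate and channel label as attributes.
#' Sample `i` (0-based) sits at `t0 + i / fs`.
#'
#' @param samples Numeric vector of amplitudes; must be finite.
#' @param fs Sampling rate in Hz (> 0).
#' @param label Channel label, e.g. `"ECG"` or `"PPG"`.
#' @param t0 Time of the first sample in seconds.
#' @return A tibble of class `waveform` with columns `t`, `value`.
#' @export
#' @examples
#' wf <- waveform(sin(2 * pi * (0:999) / 100), fs = 100, label = "ECG")
#' wf_fs(wf)
waveform <- function(samples, fs, label = "signal", t0 = 0) {
  if (!is.numeric(samples)) stop("`samples` must be numeric", call. = FALSE)
  if (!all(is.finite(samples))) stop("waveform samples must be finite", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a single positive number", call. = FALSE)
  }
  x <- tibble::tibble(
    t = t0 + (seq_along(samples) - 1) / fs,
    value = as.numeric(samples)
  )
  attr(x, "fs") <- as.numeric(fs)
  attr(x, "label") <- label
  class(x) <- c("waveform", class(x))
  x
}

#' Sampling rate of a waveform
#' @param x A [waveform()].
#' @return Sampling rate in Hz.
#' @export
wf_fs <- function(x) {
  fs <- attr(x, "fs")
  if (is.null(fs)) stop("object carries no sampling rate; build it with waveform()", call. = FALSE)
  fs
}

#' Channel label of a waveform
#' @param x A [waveform()].
#' @return Character label.
#' @export
wf_label <- function(x) attr(x, "label") %||% "signal"

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf(
    "<waveform> %s: %d samples at %g Hz (%.1f s)\n",
    wf_label(x), nrow(x), wf_fs(x), nrow(x) / wf_fs(x)
  ))
  NextMethod()
}

# deterministic sub-stream seeds so each stage draws independent,
# reproducible randomness from one user-facing seed
sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(k)) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
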