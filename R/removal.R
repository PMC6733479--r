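#' Estimate a one-period sawtooth template by phase folding
#'
#' Folds the linearly detrended PTT series modulo the artifact period and
#' takes the per-phase median across cycles; the template is centered to
#' zero mean. Content incoherent with the folding period (physiological
#' rhythms, noise) averages out; the constant-period artifact survives.
#' A phase-shuffled null (each complete cycle circularly rotated by a random
#' amount before folding) estimates the template RMS expected from
#' incoherent content alone; removal should be refused when the template RMS
#' is below twice that null.
#'
#' This period-synchronous estimator is this package's own transparent
#' correction stage, limited to constant-period artifacts.
#'
#' @param ptt Tibble `t`, `ptt` (uniform grid) or a `ptt_series`.
#' @param period Artifact period in seconds (take `1 / f_dom` from
#'   [dominant_frequency()]).
#' @param n_null Number of phase-shuffled null replicates.
#' @return An object of class `sawtooth_template`: `phase` (s), `template`
#'   (s, zero-mean), `period`, `rms`, `null_rms`, and `removable`
#'   (`rms >= 2 * null_rms`).
#' @export
estimate_sawtooth_template <- function(ptt, period, n_null = 19L) {
  if (inherits(ptt, "ptt_series")) ptt <- ptt$uniform
  x <- ptt$ptt
  t <- ptt$t
  fs <- 1 / diff(t[1:2])
  n <- length(x)
  if ((n - 1) / fs < 3 * period) stop("need at least 3 artifact cycles", call. = FALSE)
  x <- stats::.lm.fit(cbind(1, seq_len(n)), x)$residuals
  nb <- max(2L, round(period * fs))
  phase_bin <- (floor(((t - t[1]) %% period) * fs + 0.5) %% nb) + 1L
  fold <- function(xx) {
    tpl <- vapply(seq_len(nb), function(b) stats::median(xx[phase_bin == b]), numeric(1))
    tpl[is.na(tpl)] <- 0
    tpl - mean(tpl)
  }
  template <- fold(x)
  # phase-shuffled null: rotate each complete cycle independently
  cyc <- floor((t - t[1]) / period)
  null_rms <- withr::with_seed(1L, {
    reps <- vapply(seq_len(n_null), function(r) {
      xs <- x
      for (c_id in unique(cyc)) {
        idx <- which(cyc == c_id)
        if (length(idx) > 1L) {
          shift <- sample.int(length(idx), 1L) - 1L
          xs[idx] <- xs[idx][((seq_along(idx) - 1L + shift) %% length(idx)) + 1L]
        }
      }
      sqrt(mean(fold(xs)^2))
    }, numeric(1))
    stats::median(reps)
  })
  rms <- sqrt(mean(template^2))
  out <- list(
    phase = (seq_len(nb) - 1L) / fs,
    template = template,
    period = period,
    rms = rms,
    null_rms = null_rms,
    removable = rms >= 2 * null_rms
  )
  class(out) <- "sawtooth_template"
  out
}

#' @export
print.sawtooth_template <- function(x, ...) {
  cat(sprintf(
    "<sawtooth_template> period %.4g s, RMS %.3g ms (null %.3g ms): %s\n",
    x$period, 1000 * x$rms, 1000 * x$null_rms,
    if (x$removable) "removable" else "below null threshold, removal refused"
  ))
  invisible(x)
}

#' Subtract a tiled sawtooth template from a PTT series
#'
#' Tiles the one-period template across the record at the phase maximizing
#' cross-correlation with the (detrended) series, then subtracts it. A
#' zero template returns the input unchanged.
#'
#' @param ptt Tibble `t`, `ptt` (uniform grid) or a `ptt_series`.
#' @param template A [estimate_sawtooth_template()] result (or a bare
#'   numeric one-period template at the series rate).
#' @param period Artifact period, seconds; defaults to the template's.
#' @param phase Phase offset in samples; estimated by cross-correlation when
#'   `NULL`.
#' @return Tibble `t`, `ptt` (corrected series).
#' @export
subtract_artifact <- function(ptt, template, period = NULL, phase = NULL) {
  if (inherits(ptt, "ptt_series")) ptt <- ptt$uniform
  if (inherits(template, "sawtooth_template")) {
    period <- period %||% template$period
    tpl <- template$template
  } else {
    tpl <- as.numeric(template)
  }
  if (is.null(period)) stop("`period` required with a bare template", call. = FALSE)
  if (all(tpl == 0)) return(tibble::tibble(t = ptt$t, ptt = ptt$ptt))
  t <- ptt$t
  fs <- 1 / diff(t[1:2])
  nb <- length(tpl)
  base_bin <- floor(((t - t[1]) %% period) * fs + 0.5) %% nb
  if (is.null(phase)) {
    x <- stats::.lm.fit(cbind(1, seq_along(ptt$ptt)), ptt$ptt)$residuals
    score <- vapply(0:(nb - 1L), function(s) {
      sum(x * tpl[((base_bin + s) %% nb) + 1L])
    }, numeric(1))
    phase <- which.max(score) - 1L
  }
  tiled <- tpl[((base_bin + phase) %% nb) + 1L]
  tibble::tibble(t = t, ptt = ptt$ptt - tiled)
}

#' Remove a constant-period sawtooth artifact from a PTT series
#'
#' Estimates the template with [estimate_sawtooth_template()] and subtracts
#' it with [subtract_artifact()]. When the template does not rise above
#' twice the phase-shuffled null RMS, removal is refused (the input is
#' returned unchanged) unless `force = TRUE`; this guard keeps the
#' correction from ever sculpting genuine physiology on artifact-free data.
#'
#' @inheritParams estimate_sawtooth_template
#' @param force Subtract even when the template fails the null guard.
#' @return A list of class `sawtooth_removal`: `corrected` (tibble `t`,
#'   `ptt`), `template` (the `sawtooth_template`), `applied` (logical).
#' @export
remove_sawtooth <- function(ptt, period, force = FALSE, n_null = 19L) {
  if (inherits(ptt, "ptt_series")) ptt <- ptt$uniform
  tpl <- estimate_sawtooth_template(ptt, period, n_null = n_null)
  applied <- tpl$removable || force
  corrected <- if (applied) {
    subtract_artifact(ptt, tpl)
  } else {
    tibble::tibble(t = ptt$t, ptt = ptt$ptt)
  }
  if (!applied) {
    message("template RMS below phase-shuffled null threshold; removal refused")
  }
  out <- list(corrected = corrected, template = tpl, applied = applied)
  class(out) <- "sawtooth_removal"
  out
}

#' @export
print.sawtooth_removal <- function(x, ...) {
  cat(sprintf(
    "<sawtooth_removal> %s (template RMS %.3g ms, null %.3g ms)\n",
    if (x$applied) "artifact subtracted" else "removal refused",
    1000 * x$template$rms, 1000 * x$template$null_rms
  ))
  invisible(x)
}
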