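#' Write a paired recording to the project CSV format
#'
#' Plain-text format: comment header lines carrying the per-channel sampling
#' rates, then `channel,sample_index,value` rows. Values are serialized at
#' full double precision so write/read round-trips are bit-identical.
#'
#' @param rec A `monitor_recording` (or a named list of [waveform()]s).
#' @param path Output CSV file.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  chans <- if (inherits(rec, "monitor_recording")) {
    list(ECG = rec$ecg, PPG = rec$ppg)
  } else {
    rec
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("# pttsaw-recording v1", con)
  for (nm in names(chans)) {
    writeLines(sprintf("# channel=%s fs=%.10g", nm, wf_fs(chans[[nm]])), con)
  }
  writeLines("channel,sample_index,value", con)
  for (nm in names(chans)) {
    wf <- chans[[nm]]
    writeLines(sprintf("%s,%d,%.17g", nm, seq_len(nrow(wf)) - 1L, wf$value), con)
  }
  invisible(path)
}

#' Read a paired recording written by [write_recording()]
#'
#' @param path CSV file.
#' @param channels Channel labels to keep; extra channels in the file are
#'   ignored with a warning, missing ones are an error.
#' @return A named list of [waveform()]s.
#' @export
read_recording <- function(path, channels = c("ECG", "PPG")) {
  lines <- readLines(path, n = 50L)
  hdr <- grep("^# channel=", lines, value = TRUE)
  if (length(hdr) == 0L) stop("missing fs header: not a pttsaw recording CSV", call. = FALSE)
  m <- regmatches(hdr, regexec("^# channel=(\\S+) fs=([0-9.eE+-]+)", hdr))
  labels <- vapply(m, `[`, character(1), 2)
  fs <- as.numeric(vapply(m, `[`, character(1), 3))
  if (any(!is.finite(fs)) || any(fs <= 0)) stop("invalid sampling rate in header", call. = FALSE)
  names(fs) <- labels
  missing <- setdiff(channels, labels)
  if (length(missing) > 0L) {
    stop(sprintf("missing channel(s): %s", paste(missing, collapse = ", ")), call. = FALSE)
  }
  extra <- setdiff(labels, channels)
  if (length(extra) > 0L) {
    warning(sprintf("ignoring extra channel(s): %s", paste(extra, collapse = ", ")))
  }
  dat <- utils::read.csv(path, comment.char = "#")
  out <- lapply(channels, function(ch) {
    d <- dat[dat$channel == ch, ]
    d <- d[order(d$sample_index), ]
    if (!all(is.finite(d$value))) stop("non-finite samples in channel ", ch, call. = FALSE)
    waveform(d$value, fs[[ch]], label = ch)
  })
  names(out) <- channels
  out
}

#' Write/read ground truth and PTT series tables
#'
#' Small CSV helpers for the simulator's ground truth
#' (`beat_time_s,true_ptt_s`), correction event times (`correction_time_s`),
#' the beat table (`r_time_s,arrival_time_s,ptt_s`) and the uniform series
#' (`t_s,ptt_s`).
#'
#' @param truth Tibble `beat_time`, `true_ptt`.
#' @param path Output file.
#' @return The path (writers, invisibly) or a tibble (readers).
#' @name ptt_io
NULL

#' @rdname ptt_io
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.csv(
    data.frame(beat_time_s = truth$beat_time, true_ptt_s = truth$true_ptt),
    path,
    row.names = FALSE
  )
  invisible(path)
}

#' @rdname ptt_io
#' @param times Numeric vector of correction event times.
#' @export
write_corrections <- function(times, path) {
  utils::write.csv(data.frame(correction_time_s = times), path, row.names = FALSE)
  invisible(path)
}

#' @rdname ptt_io
#' @param ps A `ptt_series` from [extract_ptt()].
#' @param beats_path,uniform_path Output files for the two tables.
#' @export
write_ptt_series <- function(ps, beats_path, uniform_path) {
  utils::write.csv(
    data.frame(
      r_time_s = ps$beats$r_time,
      arrival_time_s = ps$beats$arrival_time,
      ptt_s = ps$beats$ptt
    ),
    beats_path,
    row.names = FALSE
  )
  utils::write.csv(
    data.frame(t_s = ps$uniform$t, ptt_s = ps$uniform$ptt),
    uniform_path,
    row.names = FALSE
  )
  invisible(c(beats_path, uniform_path))
}

#' @rdname ptt_io
#' @export
read_ptt_uniform <- function(path) {
  d <- utils::read.csv(path)
  tibble::tibble(t = d$t_s, ptt = d$ptt_s)
}

#' Write a TF representation to plain-text files
#'
#' The matrix goes to `<prefix>_values.csv` (long: `time_s,freq_hz,value`)
#' and the parameters to `<prefix>_params.json`.
#'
#' @param tf A `tfr` object.
#' @param prefix Output path prefix.
#' @return The prefix, invisibly.
#' @export
write_tf <- function(tf, prefix) {
  long <- tidy(tf)
  utils::write.csv(
    data.frame(time_s = long$time, freq_hz = long$freq, value = long$value),
    paste0(prefix, "_values.csv"),
    row.names = FALSE
  )
  jsonlite::write_json(
    tf$params[c("window_length", "hop", "gamma", "cepstral_threshold", "freq_range", "freq_bins")],
    paste0(prefix, "_params.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(prefix)
}

#' Read a TF representation written by [write_tf()]
#'
#' @param prefix Path prefix used when writing.
#' @return A `tfr` object.
#' @export
read_tf <- function(prefix) {
  d <- utils::read.csv(paste0(prefix, "_values.csv"))
  p <- jsonlite::read_json(paste0(prefix, "_params.json"), simplifyVector = TRUE)
  params <- suppressWarnings(deshape_params(
    window_length = p$window_length, hop = p$hop, gamma = p$gamma,
    cepstral_threshold = p$cepstral_threshold,
    freq_range = p$freq_range, freq_bins = p$freq_bins
  ))
  times <- sort(unique(d$time_s))
  freqs <- sort(unique(d$freq_hz))
  v <- matrix(0, nrow = length(times), ncol = length(freqs))
  v[cbind(match(d$time_s, times), match(d$freq_hz, freqs))] <- d$value
  new_tfr(times, freqs, v, params,
    meta = list(window_length = params$window_length, hop = params$hop)
  )
}

#' Read a pipeline configuration from YAML
#'
#' Schema version 1: top-level `pttsaw_config: 1` plus any arguments of
#' [pipeline_config()].
#'
#' @param path YAML file.
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$pttsaw_config) || y$pttsaw_config != 1) {
    stop("unsupported or missing config schema version (`pttsaw_config: 1`)", call. = FALSE)
  }
  y$pttsaw_config <- NULL
  do.call(pipeline_config, y)
}
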