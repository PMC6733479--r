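#' Truncate TF representations to a common time span
#'
#' Cohort averaging requires a common grid; each subject's TF map is
#' truncated to the span of the shortest record.
#'
#' @param tfs A list of `tfr` objects sharing the frequency grid.
#' @return A list of truncated `tfr` objects.
#' @export
truncate_to_common <- function(tfs) {
  if (length(tfs) < 2L) stop("need at least 2 subjects", call. = FALSE)
  if (any(vapply(tfs, function(x) length(x$times) == 0L, logical(1)))) {
    stop("empty TF representation", call. = FALSE)
  }
  f0 <- tfs[[1]]$freqs
  same <- vapply(tfs, function(x) {
    length(x$freqs) == length(f0) && max(abs(x$freqs - f0)) < 1e-9
  }, logical(1))
  if (!all(same)) stop("mismatched frequency grids", call. = FALSE)
  t_max <- min(vapply(tfs, function(x) max(x$times), numeric(1)))
  lapply(tfs, function(x) {
    keep <- x$times <= t_max + 1e-9
    new_tfr(x$times[keep], x$freqs, x$values[keep, , drop = FALSE], x$params,
      meta = list(window_length = x$window_length, hop = x$hop)
    )
  })
}

#' Average TF representations across a cohort
#'
#' Each subject's map is max-normalized to 1 before the elementwise mean is
#' taken (PTT oscillation amplitudes differ across subjects; without
#' normalization a few large-amplitude subjects would dominate). A rhythm
#' common to the cohort (the artifact line) survives averaging, while
#' idiosyncratic, differently timed physiology is attenuated.
#'
#' @param tfs A list of `tfr` objects on common grids (see
#'   [truncate_to_common()]).
#' @return A `tfr` of subclass `cohort_tf` with `mean_values` in `[0, 1]`
#'   and an `n_subjects` field.
#' @export
average_tf <- function(tfs) {
  tfs <- truncate_to_common(tfs)
  n_min <- min(vapply(tfs, function(x) length(x$times), integer(1)))
  norm <- lapply(tfs, function(x) {
    v <- x$values[seq_len(n_min), , drop = FALSE]
    mx <- max(v)
    if (mx > 0) v / mx else v
  })
  mean_v <- Reduce(`+`, norm) / length(norm)
  out <- new_tfr(tfs[[1]]$times[seq_len(n_min)], tfs[[1]]$freqs, mean_v,
    tfs[[1]]$params,
    meta = list(
      n_subjects = length(tfs),
      window_length = tfs[[1]]$window_length, hop = tfs[[1]]$hop
    )
  )
  class(out) <- c("cohort_tf", class(out))
  out
}

#' @export
print.cohort_tf <- function(x, ...) {
  cat(sprintf("<cohort_tf> average over %d subjects\n", x$n_subjects))
  NextMethod()
}
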