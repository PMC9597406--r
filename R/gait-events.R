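#' Detect foot contacts and strides from vertical ground reaction force
#'
#' Initial foot contacts are located as upward crossings of a relative force
#' threshold: the first sample at or above `threshold_fraction` of the peak
#' force that follows a sample below it. After each detected contact,
#' subsequent crossings are ignored for `refractory` seconds to suppress
#' chatter near the threshold. Because the threshold is relative, detection is
#' invariant to rescaling the force signal.
#'
#' @param grf Numeric vector of vertical force samples (N), or a data frame
#'   with an `fz_n` column as produced by the synthetic generator.
#' @param sampling_rate Sampling rate in Hz.
#' @param threshold_fraction Threshold as a fraction of the peak force
#'   (default 2% of peak signal).
#' @param refractory Dead time after each contact, in seconds.
#' @return A `stride_windows` object: list with `contact_indices` (1-based
#'   sample indices), `stride_durations` (seconds, one per consecutive contact
#'   pair), `sampling_rate` and `threshold_value` (N, recorded for audit).
#' @export
#' @examples
#' fz <- rep(0, 6000)
#' fz[1001:1800] <- sin(pi * seq(0, 1, length.out = 800)) * 700
#' fz[3001:3800] <- fz[1001:1800]
#' detect_strides(fz, sampling_rate = 2000)
detect_strides <- function(grf, sampling_rate = 2000,
                           threshold_fraction = 0.02, refractory = 0.2) {
  if (is.data.frame(grf)) {
    if (!"fz_n" %in% names(grf)) abort_config("`grf` data frame needs `fz_n`")
    grf <- grf$fz_n
  }
  if (!is.numeric(grf) || length(grf) < 2) {
    abort_data("`grf` must be a numeric force series")
  }
  if (any(!is.finite(grf))) abort_data("`grf` contains non-finite samples")
  if (any(grf < 0)) abort_data("`grf` must be non-negative")
  if (!is_scalar_number(threshold_fraction) ||
      threshold_fraction <= 0 || threshold_fraction >= 1) {
    abort_config("`threshold_fraction` must lie in (0, 1)")
  }
  peak <- max(grf)
  if (peak <= 0) abort_strides("insufficient strides: all-zero force signal")
  thr <- threshold_fraction * peak
  above <- grf >= thr
  crossing <- which(above & !c(TRUE, above[-length(above)]))
  # enforce refractory period
  dead <- round(refractory * sampling_rate)
  contacts <- integer(0)
  last <- -Inf
  for (ix in crossing) {
    if (ix > last + dead) {
      contacts <- c(contacts, ix)
      last <- ix
    }
  }
  if (length(contacts) < 2) {
    abort_strides("insufficient strides: fewer than 2 contacts detected")
  }
  structure(
    list(
      contact_indices = contacts,
      stride_durations = diff(contacts) / sampling_rate,
      sampling_rate = sampling_rate,
      threshold_value = thr
    ),
    class = "stride_windows"
  )
}

#' @export
print.stride_windows <- function(x, ...) {
  cat(sprintf(
    "<stride_windows> %d contacts, %d strides (%.3f-%.3f s), threshold %.2f N\n",
    length(x$contact_indices), length(x$stride_durations),
    min(x$stride_durations), max(x$stride_durations), x$threshold_value
  ))
  invisible(x)
}

#' Tidy stride windows into a tibble
#'
#' @param x A `stride_windows` object.
#' @param ... Unused.
#' @return Tibble with one row per complete stride: `stride`,
#'   `contact_index`, `contact_time_s`, `duration_s`.
#' @export
tidy.stride_windows <- function(x, ...) {
  k <- length(x$stride_durations)
  tibble(
    stride = seq_len(k),
    contact_index = x$contact_indices[seq_len(k)],
    contact_time_s = (x$contact_indices[seq_len(k)] - 1) / x$sampling_rate,
    duration_s = x$stride_durations
  )
}
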