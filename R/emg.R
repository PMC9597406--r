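#' Linear envelope of raw surface EMG
#'
#' Standard linear-envelope extraction: subtract the channel mean (DC offset),
#' zero-phase fourth-order Butterworth band-pass (20-350 Hz) to remove
#' movement artefact and high-frequency noise, full-wave rectify, zero-phase
#' fourth-order Butterworth low-pass at 6 Hz, and clip residual filter
#' ringing below zero. Zero-phase (forward-backward) filtering preserves burst
#' timing relative to the force record. Every stage is positively homogeneous,
#' so scaling the raw signal by `k > 0` scales the envelope by `k`.
#'
#' @param emg Numeric vector of raw EMG (volts), or a data frame whose
#'   non-`time_s` columns are channels (each processed independently).
#' @param sampling_rate Sampling rate in Hz; must exceed twice the upper band
#'   edge.
#' @param band Band-pass corner frequencies in Hz.
#' @param lowpass Envelope low-pass cut-off in Hz.
#' @param order Butterworth design order applied at each stated cut-off.
#' @return Envelope of the same shape as the input (vector in, vector out;
#'   data frame in, data frame out with `time_s` preserved). All values are
#'   non-negative.
#' @export
#' @examples
#' fs <- 2000
#' x <- sin(2 * pi * 100 * seq(0, 4, by = 1 / fs))
#' env <- compute_envelope(x, fs)
#' mean(env[3000:5000]) # ~ 2/pi, the mean of a rectified unit sinusoid
compute_envelope <- function(emg, sampling_rate = 2000, band = c(20, 350),
                             lowpass = 6, order = 4) {
  if (sampling_rate <= 2 * band[2]) {
    abort_config(paste0(
      "sampling_rate (", sampling_rate,
      " Hz) must exceed twice the upper band edge (", band[2], " Hz)"
    ))
  }
  if (is.data.frame(emg)) {
    chans <- setdiff(names(emg), "time_s")
    out <- emg
    for (ch in chans) {
      if (any(!is.finite(emg[[ch]]))) {
        abort_data(paste0("non-finite samples in channel ", ch))
      }
      out[[ch]] <- envelope_vec(emg[[ch]], sampling_rate, band, lowpass, order)
    }
    return(as_tibble(out))
  }
  if (any(!is.finite(emg))) abort_data("non-finite samples in EMG input")
  envelope_vec(emg, sampling_rate, band, lowpass, order)
}

envelope_vec <- function(x, fs, band, lowpass, order) {
  if (length(x) < 2 * fs) {
    abort_data("EMG record must be at least 2 s long (filter transients)")
  }
  x <- x - mean(x)
  bp <- signal::butter(order, band / (fs / 2), type = "pass")
  x <- signal::filtfilt(bp, x)
  x <- abs(x)
  lp <- signal::butter(order, lowpass / (fs / 2), type = "low")
  x <- signal::filtfilt(lp, x)
  pmax(x, 0)
}

#' Per-stride activation rates from EMG envelopes
#'
#' For each muscle `i` and stride `j`, the activation rate is the
#' time-averaged linear envelope over the stride,
#' `a_ij = (1/T_j) * integral of the envelope over stride j` (trapezoidal
#' rule on the uniform sample grid), capturing both how much of the muscle is
#' recruited and how often. Normalized activations are
#' `A_ij = a_ij / baseline_mean_i`, where the per-muscle baseline mean is the
#' five-stride average of `a` from the participant's 0%-incline (level
#' upright) trial. When `baseline` is omitted the table IS the 0%-incline
#' trial and is normalized against itself, so each muscle's mean `A` over the
#' five strides equals 1 by construction.
#'
#' Strides are taken as the first `n_strides` artifact-free complete strides
#' of the record, where artifact-free means no channel sample within the
#' stride reaches `saturation`.
#'
#' @param envelopes Data frame of envelope channels (`time_s` optional) as
#'   returned by [compute_envelope()]; columns must cover
#'   [muscle_channels()] except any listed in `excluded_channels`.
#' @param strides A `stride_windows` object from [detect_strides()].
#' @param baseline `NULL` (self-normalize), an `activation_tbl` from the
#'   0%-incline trial, or a named numeric vector of per-muscle baseline means.
#' @param n_strides Number of strides analysed (default 5).
#' @param saturation Artifact bound in envelope units; strides containing any
#'   sample at or above it are skipped.
#' @param excluded_channels Muscles excluded for signal quality; they
#'   propagate as missing rows and any cost computed over the table fails
#'   loudly rather than silently renormalizing.
#' @return An `activation_tbl`: tibble with columns `muscle`, `stride`, `a`,
#'   `A`, plus attributes `baseline_means` (named numeric) and `strides_used`
#'   (contact indices of the analysed strides).
#' @export
compute_activation <- function(envelopes, strides, baseline = NULL,
                               n_strides = 5, saturation = Inf,
                               excluded_channels = character(0)) {
  stopifnot(inherits(strides, "stride_windows"))
  muscles <- setdiff(MUSCLES, excluded_channels)
  present <- intersect(MUSCLES, names(envelopes))
  missing <- setdiff(muscles, present)
  if (length(missing) > 0) {
    abort_data(paste0(
      "envelope channels missing: ", paste(missing, collapse = ", ")
    ))
  }
  fs <- strides$sampling_rate
  ci <- strides$contact_indices
  n_avail <- length(ci) - 1
  env_mat <- as.matrix(envelopes[muscles])
  if (any(env_mat < 0)) abort_data("envelope values must be non-negative")

  picked <- integer(0)
  for (j in seq_len(n_avail)) {
    if (ci[j + 1] > nrow(env_mat)) break
    win <- env_mat[ci[j]:ci[j + 1], , drop = FALSE]
    if (all(win < saturation)) picked <- c(picked, j)
    if (length(picked) == n_strides) break
  }
  if (length(picked) < n_strides) {
    abort_strides(paste0(
      "insufficient strides: ", length(picked), " artifact-free of ",
      n_strides, " required"
    ))
  }

  a <- matrix(NA_real_, nrow = length(muscles), ncol = n_strides,
              dimnames = list(muscles, NULL))
  for (k in seq_len(n_strides)) {
    j <- picked[k]
    idx <- ci[j]:ci[j + 1]
    tt <- (idx - 1) / fs
    tj <- strides$stride_durations[j]
    for (m in muscles) {
      a[m, k] <- pracma::trapz(tt, env_mat[idx, m]) / tj
    }
  }

  base_means <- resolve_baseline(baseline, a, muscles)
  if (any(!is.finite(base_means)) || any(base_means <= 0)) {
    abort_data("degenerate baseline: zero or non-finite per-muscle mean")
  }
  A <- sweep(a, 1, base_means, "/")

  out <- tibble(
    muscle = factor(rep(muscles, times = n_strides), levels = MUSCLES),
    stride = rep(seq_len(n_strides), each = length(muscles))
  )
  out$a <- purrr::map2_dbl(as.character(out$muscle), out$stride, ~ a[.x, .y])
  out$A <- purrr::map2_dbl(as.character(out$muscle), out$stride, ~ A[.x, .y])
  structure(
    out,
    baseline_means = base_means,
    strides_used = ci[picked],
    class = c("activation_tbl", class(out))
  )
}

resolve_baseline <- function(baseline, a, muscles) {
  if (is.null(baseline)) {
    rowMeans(a)
  } else if (inherits(baseline, "activation_tbl")) {
    bm <- attr(baseline, "baseline_means")
    if (!all(muscles %in% names(bm))) {
      abort_data("baseline activation table does not cover all muscles")
    }
    bm[muscles]
  } else if (is.numeric(baseline) && !is.null(names(baseline))) {
    if (!all(muscles %in% names(baseline))) {
      abort_data("named baseline vector does not cover all muscles")
    }
    baseline[muscles]
  } else {
    abort_config("`baseline` must be NULL, an activation_tbl or named numeric")
  }
}

#' Per-muscle baseline means of an activation table
#'
#' @param activation An `activation_tbl`.
#' @return Named numeric vector of per-muscle baseline means.
#' @export
baseline_means <- function(activation) {
  stopifnot(inherits(activation, "activation_tbl"))
  attr(activation, "baseline_means")
}
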