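# Canonical muscle channel order used throughout: gluteus maximus, biceps
# femoris, rectus femoris, vastus medialis, medial gastrocnemius, soleus,
# tibialis anterior.
MUSCLES <- c("Gmax", "BF", "RF", "VM", "MG", "SOL", "TA")

# Muscle volumes as proportions of the seven-muscle total (2-decimal values,
# summing to 1).
VOLUME_WEIGHTS <- c(
  Gmax = 0.33, BF = 0.08, RF = 0.10, VM = 0.17,
  MG = 0.10, SOL = 0.17, TA = 0.05
)

#' Muscle channel labels
#'
#' The seven lower-limb muscles analysed, in canonical order: gluteus maximus
#' (Gmax), biceps femoris (BF), rectus femoris (RF), vastus medialis (VM),
#' medial gastrocnemius (MG), soleus (SOL) and tibialis anterior (TA).
#'
#' @return Character vector of length 7.
#' @export
#' @examples
#' muscle_channels()
muscle_channels <- function() MUSCLES

#' Muscle volume weights
#'
#' Physiological muscle volumes expressed as proportions of the seven-muscle
#' total, used by the effort-like (volume-weighted) activation cost. The
#' proportions sum to one.
#'
#' @return Named numeric vector over [muscle_channels()].
#' @export
#' @examples
#' sum(muscle_volume_weights())
muscle_volume_weights <- function() VOLUME_WEIGHTS

abort_config <- function(msg, ...) {
  abort(msg, class = "gaitccp_error_config", ...)
}

abort_data <- function(msg, ...) {
  abort(msg, class = "gaitccp_error_data", ...)
}

abort_strides <- function(msg, ...) {
  abort(msg, class = "gaitccp_error_strides", ...)
}

# Deterministic 31-polynomial string hash into [1, 2^31 - 2], used to derive
# independent per-trial seeds from a single cohort seed.
hash_seed <- function(...) {
  key <- paste(..., sep = "\r")
  codes <- utf8ToInt(key)
  h <- 0
  for (cc in codes) h <- (h * 31 + cc) %% 2147483647
  as.integer(h + 1)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
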