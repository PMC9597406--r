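#' Generic weighted activation cost
#'
#' Per-stride cost `C_j = sum_i(w_i * A_ij^p) / sum_i(w_i)` over the seven
#' muscles, and its mean across the analysed strides. `p = Inf` denotes the
#' min-max limit, in which only the maximally activated muscle contributes:
#' `C_j = max_i(A_ij)`. Costs are computed per stride first and then averaged
#' (max-then-average, not average-then-max).
#'
#' With equal weights and an exponent above one the cost is "fatigue-like": it
#' penalizes concentrating activation in any single muscle irrespective of its
#' size. With muscle-volume weights and `p = 1` it is "effort-like", tracking
#' active muscle volume, a determinant of metabolic energy use.
#'
#' @param activation An `activation_tbl` from [compute_activation()],
#'   complete for all seven muscles.
#' @param weights Named non-negative per-muscle weights (default: all 1); at
#'   least one must be positive.
#' @param p Exponent, `>= 1` or `Inf` (symbolic min-max limit).
#' @return List with `per_stride` (tibble `stride`, `cost`) and `mean`.
#' @export
#' @examples
#' # identity activations give unit cost for any valid weights and exponent
#' act <- tibble::tibble(
#'   muscle = factor(rep(muscle_channels(), 2), levels = muscle_channels()),
#'   stride = rep(1:2, each = 7), a = 1, A = 1
#' )
#' class(act) <- c("activation_tbl", class(act))
#' generic_cost(act, p = 2)$mean
generic_cost <- function(activation, weights = NULL, p = 2) {
  A <- activation_matrix(activation)
  if (is.null(weights)) weights <- setNames(rep(1, 7), MUSCLES)
  if (is.null(names(weights)) || !all(MUSCLES %in% names(weights))) {
    abort_config("`weights` must be a vector named by muscle_channels()")
  }
  w <- weights[MUSCLES]
  if (any(w < 0) || sum(w) <= 0) {
    abort_config("weights must be non-negative with at least one positive")
  }
  if (!identical(p, Inf) && (!is_scalar_number(p) || p < 1)) {
    abort_config("`p` must be >= 1 or Inf")
  }
  per_stride <- if (identical(p, Inf)) {
    unname(apply(A, 2, max))
  } else {
    as.numeric(crossprod(w, A^p) / sum(w))
  }
  list(
    per_stride = tibble(stride = seq_along(per_stride), cost = per_stride),
    mean = mean(per_stride)
  )
}

activation_matrix <- function(activation) {
  stopifnot(inherits(activation, "activation_tbl") ||
              is.data.frame(activation))
  muscles <- as.character(unique(activation$muscle))
  missing <- setdiff(MUSCLES, muscles)
  if (length(missing) > 0) {
    abort_data(paste0(
      "incomplete activation table: missing ", paste(missing, collapse = ", ")
    ))
  }
  if (any(!is.finite(activation$A))) {
    abort_data("incomplete activation table: non-finite normalized values")
  }
  strides <- sort(unique(activation$stride))
  A <- matrix(NA_real_, nrow = 7, ncol = length(strides),
              dimnames = list(MUSCLES, strides))
  for (r in seq_len(nrow(activation))) {
    A[as.character(activation$muscle[r]),
      as.character(activation$stride[r])] <- activation$A[r]
  }
  if (any(!is.finite(A))) abort_data("incomplete activation table")
  A
}

#' All trial-level costs for one recording
#'
#' Computes the three activation cost functionals as five-stride means —
#' mean squared activation (`c_a2`: equal weights, `p = 2`), min-max
#' (`c_a_max`: `p = Inf`) and volume-weighted (`c_a_vol`: weights
#' [muscle_volume_weights()], `p = 1`) — and carries the mass-specific
#' metabolic power alongside them.
#'
#' @param activation An `activation_tbl`, complete for all seven muscles.
#' @param metabolic Optional `metabolic_result` from [metabolic_power()]
#'   (its `c_met_p` is copied; `NA` when omitted).
#' @param participant_id,condition,grade,crouch_rep Metadata carried through
#'   to the output row.
#' @return One-row tibble: metadata plus `c_met_p`, `c_a2`, `c_a_max`,
#'   `c_a_vol`.
#' @export
trial_costs <- function(activation, metabolic = NULL,
                        participant_id = NA_character_,
                        condition = NA_character_, grade = NA_real_,
                        crouch_rep = NA_character_) {
  tibble(
    participant_id = participant_id,
    condition = condition,
    grade = grade,
    crouch_rep = crouch_rep,
    c_met_p = if (is.null(metabolic)) NA_real_ else metabolic$c_met_p,
    c_a2 = generic_cost(activation, p = 2)$mean,
    c_a_max = generic_cost(activation, p = Inf)$mean,
    c_a_vol = generic_cost(activation, weights = VOLUME_WEIGHTS, p = 1)$mean
  )
}
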