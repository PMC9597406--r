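#' Pre- and post-transition inclines from a choice sequence
#'
#' The pre-transition incline is the steepest grade at which the incline was
#' selected over crouch walking; the post-transition incline is the
#' shallowest grade at which crouch walking was preferred. A sequence is
#' monotone when no incline selection occurs at a grade above any crouch
#' selection (a single transition). Either field is `NA` when the respective
#' selection set is empty.
#'
#' @param choices Tibble with columns `participant_id`, `grade`, `selected`
#'   (`"incline"` or `"crouch"`), covering every protocol grade per
#'   participant.
#' @param grades Ordered protocol grades (percent).
#' @return Tibble with one row per participant: `pre_transition_grade`,
#'   `post_transition_grade`, `monotone`.
#' @export
#' @examples
#' ch <- tibble::tibble(
#'   participant_id = "P01", grade = c(0, 6, 12, 18, 24),
#'   selected = c("incline", "incline", "incline", "incline", "crouch")
#' )
#' identify_transitions(ch)
identify_transitions <- function(choices, grades = c(0, 6, 12, 18, 24)) {
  needed <- c("participant_id", "grade", "selected")
  if (!all(needed %in% names(choices))) {
    abort_config("`choices` needs columns participant_id, grade, selected")
  }
  if (!all(choices$selected %in% c("incline", "crouch"))) {
    abort_data("`selected` must be 'incline' or 'crouch'")
  }
  choices |>
    group_by(.data$participant_id) |>
    dplyr::group_modify(function(df, key) {
      if (!all(grades %in% df$grade)) {
        abort_data(paste0(
          "choices for ", key$participant_id, " do not cover all grades"
        ))
      }
      inc <- df$grade[df$selected == "incline"]
      cro <- df$grade[df$selected == "crouch"]
      pre <- if (length(inc)) max(inc) else NA_real_
      post <- if (length(cro)) min(cro) else NA_real_
      tibble(
        pre_transition_grade = pre,
        post_transition_grade = post,
        monotone = length(inc) == 0 || length(cro) == 0 || max(inc) < min(cro)
      )
    }) |>
    ungroup()
}

cost_metrics <- c("c_met_p", "c_a2", "c_a_max", "c_a_vol")

as_cost_row <- function(x, what) {
  x <- as.list(x)
  if (!all(cost_metrics %in% names(x))) {
    abort_config(paste0(
      "`", what, "` must carry ", paste(cost_metrics, collapse = ", ")
    ))
  }
  lapply(x[cost_metrics], as.numeric)
}

#' Evaluate the competing-cost-pair rule for one participant
#'
#' Expresses the mean-crouch and pre-transition-incline costs as percentages
#' of the participant's 0%-incline (level upright) values, then applies the
#' strict-inequality competing-cost-pair (CCP) rule per cost pairing: a CCP
#' is accepted for an activation cost when metabolic power decreased from the
#' pre-transition incline to crouch walking AND that activation cost
#' increased. Ties never accept.
#'
#' Advantage and penalty percentages use the pre-transition incline value as
#' denominator: `advantage_X = 100 * (crouch_X - incline_X) / incline_X` and
#' `penalty_met = 100 * (incline_met - crouch_met) / incline_met`. Both are
#' invariant to any common positive rescaling of a participant's costs.
#'
#' @param crouch_costs,incline_costs,baseline_costs One-row data frames or
#'   named lists carrying `c_met_p`, `c_a2`, `c_a_max`, `c_a_vol`: the mean
#'   of the two crouch trials, the pre-transition incline trial, and the
#'   0%-incline trial. Activation entries may be `NA` (excluded EMG), in
#'   which case the corresponding CCP flags and advantages are `NA`.
#' @param participant_id,pre_transition_grade Metadata carried to the output.
#' @return One-row tibble with percent-of-baseline costs
#'   (`<metric>_crouch_pct`, `<metric>_incline_pct`), CCP booleans
#'   (`ccp_a2`, `ccp_a_max`, `ccp_a_vol`), advantages and `penalty_met`.
#' @export
evaluate_ccp <- function(crouch_costs, incline_costs, baseline_costs,
                         participant_id = NA_character_,
                         pre_transition_grade = NA_real_) {
  cr <- as_cost_row(crouch_costs, "crouch_costs")
  inc <- as_cost_row(incline_costs, "incline_costs")
  base <- as_cost_row(baseline_costs, "baseline_costs")
  for (m in cost_metrics) {
    if (is.finite(base[[m]]) && base[[m]] <= 0) {
      abort_data("degenerate denominator: non-positive baseline cost")
    }
  }
  pct <- function(x, m) 100 * x[[m]] / base[[m]]
  vals <- list()
  for (m in cost_metrics) {
    key <- sub("^c_", "", m)
    key <- sub("^met_p$", "met", key)
    vals[[paste0(key, "_crouch_pct")]] <- pct(cr, m)
    vals[[paste0(key, "_incline_pct")]] <- pct(inc, m)
  }
  met_down <- cr$c_met_p < inc$c_met_p
  adv <- function(m) {
    if (!is.finite(cr[[m]]) || !is.finite(inc[[m]])) return(NA_real_)
    if (inc[[m]] == 0) abort_data("degenerate denominator: zero incline cost")
    100 * (cr[[m]] - inc[[m]]) / inc[[m]]
  }
  ccp <- function(m) {
    if (!is.finite(cr[[m]]) || !is.finite(inc[[m]])) return(NA)
    met_down && cr[[m]] > inc[[m]]
  }
  if (inc$c_met_p == 0) abort_data("degenerate denominator: zero incline cost")
  tibble(
    participant_id = participant_id,
    pre_transition_grade = pre_transition_grade,
    !!!vals,
    ccp_a2 = ccp("c_a2"),
    ccp_a_max = ccp("c_a_max"),
    ccp_a_vol = ccp("c_a_vol"),
    advantage_a2 = adv("c_a2"),
    advantage_a_max = adv("c_a_max"),
    advantage_a_vol = adv("c_a_vol"),
    penalty_met = 100 * (inc$c_met_p - cr$c_met_p) / inc$c_met_p
  )
}

#' Competing-cost-pair table for a cohort
#'
#' Applies [evaluate_ccp()] to every participant in a per-trial cost table,
#' using the transition grades derived from their choice sequences. Crouch
#' costs are the arithmetic mean of the initial and final crouch trials by
#' default. Participants without a pre-transition incline (crouch preferred
#' everywhere) yield a row of `NA`s with `note = "no CCP evaluable"`.
#'
#' @param costs Tibble of trial costs: `participant_id`, `condition`,
#'   `grade`, `crouch_rep`, `c_met_p`, `c_a2`, `c_a_max`, `c_a_vol`.
#' @param transitions Output of [identify_transitions()].
#' @param crouch_rule `"mean"` (default), `"initial"` or `"final"`: which
#'   crouch data represent crouch walking.
#' @return Tibble with one row per participant mirroring the percent-cost
#'   table layout, plus `monotone` and `note`.
#' @export
ccp_table <- function(costs, transitions,
                      crouch_rule = c("mean", "initial", "final")) {
  crouch_rule <- match.arg(crouch_rule)
  purrr::map_dfr(seq_len(nrow(transitions)), function(i) {
    tr <- transitions[i, ]
    pid <- tr$participant_id
    df <- costs[costs$participant_id == pid, ]
    empty <- evaluate_ccp(
      setNames(as.list(rep(1, 4)), cost_metrics),
      setNames(as.list(rep(1, 4)), cost_metrics),
      setNames(as.list(rep(1, 4)), cost_metrics),
      participant_id = pid
    )
    empty[-1] <- NA
    if (is.na(tr$pre_transition_grade)) {
      return(mutate(empty,
        post_transition_grade = tr$post_transition_grade,
        monotone = tr$monotone, note = "no CCP evaluable"
      ))
    }
    base <- df[df$condition == "incline" & df$grade == 0, ]
    inc <- df[df$condition == "incline" &
                df$grade == tr$pre_transition_grade, ]
    cr <- df[df$condition == "crouch", ]
    if (crouch_rule != "mean") {
      cr <- cr[!is.na(cr$crouch_rep) & cr$crouch_rep == crouch_rule, ]
    }
    if (nrow(base) != 1 || nrow(inc) != 1 || nrow(cr) == 0) {
      abort_data(paste0("incomplete cost set for participant ", pid))
    }
    crouch_mean <- lapply(
      setNames(cost_metrics, cost_metrics),
      function(m) mean(cr[[m]])
    )
    evaluate_ccp(crouch_mean, inc, base,
      participant_id = pid,
      pre_transition_grade = tr$pre_transition_grade
    ) |>
      mutate(
        post_transition_grade = tr$post_transition_grade,
        monotone = tr$monotone, note = NA_character_
      )
  })
}

#' Group summaries of competing-cost-pair percentages
#'
#' Unweighted mean and range (min, max) of the activation advantages and the
#' metabolic penalty across participants: either the subset in which a mean
#' squared activation / metabolic power CCP was accepted, or all participants
#' with complete activation data.
#'
#' @param ccp Tibble from [ccp_table()] or [evaluate_ccp()] rows.
#' @param restrict_to_ccp If `TRUE` (default) summarize only participants
#'   with `ccp_a2 == TRUE`; otherwise all rows with defined advantages.
#' @param include_nonmonotone Include participants whose choice sequence was
#'   not a single transition (default `FALSE`; only applies when the table
#'   carries a `monotone` column).
#' @return Tibble: `metric`, `n`, `mean`, `min`, `max`.
#' @export
ccp_summary <- function(ccp, restrict_to_ccp = TRUE,
                        include_nonmonotone = FALSE) {
  df <- ccp
  if ("monotone" %in% names(df) && !include_nonmonotone) {
    df <- df[is.na(df$monotone) | df$monotone, ]
  }
  df <- if (restrict_to_ccp) {
    df[!is.na(df$ccp_a2) & df$ccp_a2, ]
  } else {
    df[!is.na(df$advantage_a2), ]
  }
  if (nrow(df) == 0) abort_data("empty selection: no participants to summarize")
  vars <- c("advantage_a2", "advantage_a_max", "advantage_a_vol",
            "penalty_met")
  purrr::map_dfr(vars, function(v) {
    x <- df[[v]][!is.na(df[[v]])]
    tibble(metric = v, n = length(x), mean = mean(x),
           min = min(x), max = max(x))
  })
}
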