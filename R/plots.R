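#' Group cost profiles across incline grades
#'
#' Line plot of group mean +/- s.d. of each cost metric against treadmill
#' grade, with the crouch-walking group mean shown as a dashed reference
#' line per panel.
#'
#' @param costs Per-trial cost tibble (as in `gait_experiment$costs`).
#' @return A ggplot object (faceted by metric, free y scales).
#' @export
plot_cost_profiles <- function(costs) {
  long <- costs |>
    tidyr::pivot_longer(dplyr::all_of(cost_metrics),
                        names_to = "metric", values_to = "value") |>
    mutate(metric = factor(.data$metric, levels = cost_metrics))
  inc <- long |>
    filter(.data$condition == "incline") |>
    group_by(.data$metric, .data$grade) |>
    summarise(
      mean = mean(.data$value), sd = sd(.data$value), .groups = "drop"
    )
  cr <- long |>
    filter(.data$condition == "crouch") |>
    group_by(.data$metric) |>
    summarise(mean = mean(.data$value), .groups = "drop")
  ggplot2::ggplot(inc, ggplot2::aes(x = .data$grade, y = .data$mean)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd,
                   ymax = .data$mean + .data$sd),
      width = 0.8, colour = "grey40"
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(
      data = cr, ggplot2::aes(yintercept = .data$mean),
      linetype = "dashed", colour = "firebrick"
    ) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(
      x = "treadmill grade (%)",
      y = "cost (W/kg for c_met_p; unitless otherwise)",
      caption = "dashed line: crouch-walking group mean"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname plot_cost_profiles
#' @param object A `gait_experiment`.
#' @param ... Unused.
#' @export
autoplot.gait_experiment <- function(object, ...) {
  if (is.null(object$costs)) {
    abort_config("no per-trial costs to plot (example mode)")
  }
  plot_cost_profiles(object$costs)
}

#' Quick look at one synthetic trial
#'
#' Stacked panels of the first seconds of vertical GRF and of one EMG
#' channel, plus the full breath-by-breath oxygen uptake trace.
#'
#' @param object A `gait_trial`.
#' @param muscle Which EMG channel to show.
#' @param window_s Seconds of the signal panels to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gait_trial <- function(object, muscle = "VM", window_s = 6, ...) {
  fs <- object$sampling_rate
  idx <- seq_len(min(round(window_s * fs), nrow(object$grf)))
  sig <- bind_rows(
    tibble(time_s = object$grf$time_s[idx],
           value = object$grf$fz_n[idx], panel = "vertical GRF (N)"),
    tibble(time_s = object$emg$time_s[idx],
           value = object$emg[[muscle]][idx],
           panel = paste0("EMG ", muscle, " (V)")),
    tibble(time_s = object$breaths$time_s,
           value = object$breaths$vo2_l_s, panel = "VO2 (L/s)")
  )
  ggplot2::ggplot(sig, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free") +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}
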