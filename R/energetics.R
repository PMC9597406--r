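#' Steady-state mass-specific metabolic power from breath-by-breath gas
#' exchange
#'
#' Oxygen uptake and carbon dioxide production rates are averaged (unweighted)
#' over the breaths falling in the final `window` seconds of the trial, and
#' converted to mass-specific metabolic power with the standard stoichiometric
#' formula
#' `C_met_P = 1000 * (16.89 * VO2 + 4.82 * VCO2) / M` (W kg^-1, gas rates in
#' L s^-1, body mass `M` in kg). Breaths exactly on the window boundary are
#' included. Because belt speed is constant across trials, no conversion to a
#' cost per distance is performed.
#'
#' A warning (not an error) is raised when the window-mean respiratory
#' exchange ratio exceeds 1.05, indicating the trial may not have been
#' aerobically steady.
#'
#' @param breaths Data frame with columns `time_s`, `vo2_l_s`, `vco2_l_s`
#'   (or `vo2_ml_min`/`vco2_ml_min` with `units = "ml_min"`).
#' @param mass Body mass in kg.
#' @param trial_duration Trial end time in seconds; defaults to the last
#'   breath timestamp.
#' @param window Averaging window length in seconds (final minute by
#'   default).
#' @param units `"l_s"` (default) or `"ml_min"`; the latter divides rates by
#'   60000.
#' @return One-row tibble (class `metabolic_result`): `vo2_mean`,
#'   `vco2_mean` (L s^-1), `rer`, `c_met_p` (W kg^-1), `window_start`,
#'   `window_end`, `n_breaths`, `mass`.
#' @export
#' @examples
#' br <- tibble::tibble(
#'   time_s = seq(5, 300, by = 4),
#'   vo2_l_s = 0.02, vco2_l_s = 0.016
#' )
#' metabolic_power(br, mass = 70)
metabolic_power <- function(breaths, mass, trial_duration = NULL,
                            window = 60, units = c("l_s", "ml_min")) {
  units <- match.arg(units)
  if (!is_scalar_number(mass) || mass <= 0) {
    abort_config("`mass` must be a positive number (kg)")
  }
  if (units == "ml_min") {
    breaths <- dplyr::rename(breaths,
      vo2_l_s = "vo2_ml_min", vco2_l_s = "vco2_ml_min"
    )
    breaths$vo2_l_s <- breaths$vo2_l_s / 60000
    breaths$vco2_l_s <- breaths$vco2_l_s / 60000
  }
  needed <- c("time_s", "vo2_l_s", "vco2_l_s")
  if (!all(needed %in% names(breaths))) {
    abort_config("`breaths` needs columns time_s, vo2_l_s, vco2_l_s")
  }
  if (any(breaths$vo2_l_s < 0) || any(breaths$vco2_l_s < 0)) {
    abort_data("negative gas-exchange rates")
  }
  trial_duration <- trial_duration %||% max(breaths$time_s)
  w0 <- trial_duration - window
  sel <- breaths$time_s >= w0 & breaths$time_s <= trial_duration
  if (sum(sel) < 5) {
    abort_data("insufficient steady-state data: fewer than 5 breaths in window")
  }
  vo2 <- mean(breaths$vo2_l_s[sel])
  vco2 <- mean(breaths$vco2_l_s[sel])
  rer <- if (vo2 > 0) vco2 / vo2 else NA_real_
  if (is.finite(rer) && rer > 1.05) {
    warn(sprintf("window-mean RER = %.2f exceeds 1.05; steady state doubtful",
                 rer))
  }
  out <- tibble(
    vo2_mean = vo2,
    vco2_mean = vco2,
    rer = rer,
    c_met_p = 1000 * (16.89 * vo2 + 4.82 * vco2) / mass,
    window_start = w0,
    window_end = trial_duration,
    n_breaths = sum(sel),
    mass = mass
  )
  class(out) <- c("metabolic_result", class(out))
  out
}
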