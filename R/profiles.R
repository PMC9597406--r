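#' Draw a cohort of synthetic participant profiles
#'
#' Each profile parameterizes one simulated walker: anthropometrics, baseline
#' per-muscle electromyography (EMG) envelope gains, how those gains scale with
#' treadmill grade and with crouch walking, gas-exchange targets, and stride
#' timing. Defaults emulate a cohort in which crouch walking inflates the
#' knee-extensor channels (VM, RF) at a moderate metabolic cost while incline
#' walking scales all channels (and metabolic rate) monotonically with grade,
#' so that steep inclines and crouch form competing-cost pairs.
#'
#' Anthropometrics are drawn around 69.6 +/- 11.1 kg and 1.70 +/- 0.07 m.
#' Knee-extensor crouch gains are > 1 by construction. Oxygen-uptake targets
#' are set so level upright walking costs about 4.3 W kg^-1, crouch about
#' 1.7-1.9 x that, and grade adds 7-8% of the level rate per percent incline.
#'
#' @param n Number of participants.
#' @param seed Integer seed; equal seeds give identical cohorts.
#' @param stride_time_cv Coefficient of variation of the lognormal
#'   stride-to-stride time jitter.
#' @return A tibble with one row per participant. Per-muscle parameters
#'   (`baseline_gains`, `incline_slope`, `crouch_gains`) are list-columns of
#'   named numeric vectors over [muscle_channels()].
#' @export
#' @examples
#' profiles <- sample_profiles(3, seed = 1)
#' profiles$crouch_gains[[1]]
sample_profiles <- function(n = 10, seed = 1, stride_time_cv = 0.03) {
  if (!is_scalar_number(n) || n < 1) abort_config("`n` must be >= 1")
  withr::local_seed(seed)
  rows <- purrr::map(seq_len(n), function(i) {
    mass <- min(max(rnorm(1, 69.6, 11.1), 50), 95)
    height <- rnorm(1, 1.70, 0.07)
    rer <- runif(1, 0.80, 0.95)
    baseline <- setNames(0.05 * runif(7, 0.7, 1.3), MUSCLES)
    slope <- setNames(runif(7, 0.045, 0.055), MUSCLES)
    crouch <- setNames(runif(7, 1.2, 1.6), MUSCLES)
    crouch["VM"] <- runif(1, 3.2, 4.2)
    crouch["RF"] <- runif(1, 2.6, 3.4)
    # level upright walking ~ 4.3 W kg^-1 via the gas-exchange stoichiometry
    vo2_base <- 4.3 * mass / (1000 * (16.89 + 4.82 * rer)) * runif(1, 0.9, 1.1)
    tibble(
      participant_id = sprintf("P%02d", i),
      mass = mass,
      height = height,
      baseline_gains = list(baseline),
      incline_slope = list(slope),
      crouch_gains = list(crouch),
      vo2_baseline = vo2_base,
      vo2_per_grade = vo2_base * runif(1, 0.07, 0.08),
      vo2_crouch = vo2_base * runif(1, 1.7, 1.9),
      rer = rer,
      stride_time_mean = runif(1, 1.0, 1.1),
      stride_time_cv = stride_time_cv,
      seed = hash_seed(seed, "profile", i)
    )
  })
  out <- bind_rows(rows)
  validate_profiles(out)
  out
}

validate_profiles <- function(profiles) {
  if (!is.data.frame(profiles) || nrow(profiles) == 0) {
    abort_config("`profiles` must be a non-empty data frame")
  }
  if (anyDuplicated(profiles$participant_id)) {
    abort_config("duplicate participant_id in profiles")
  }
  for (i in seq_len(nrow(profiles))) {
    p <- profiles[i, ]
    gains <- c(p$baseline_gains[[1]], p$incline_slope[[1]], p$crouch_gains[[1]])
    scal <- c(p$mass, p$vo2_baseline, p$vo2_per_grade, p$vo2_crouch,
              p$stride_time_mean)
    if (any(!is.finite(gains)) || any(gains < 0) ||
        any(!is.finite(scal)) || any(scal <= 0)) {
      abort_config(paste0("non-positive parameter for ", p$participant_id))
    }
    if (p$rer < 0.7 || p$rer > 1.1) {
      abort_config(paste0("rer outside [0.7, 1.1] for ", p$participant_id))
    }
    cg <- p$crouch_gains[[1]]
    if (any(cg[c("VM", "RF")] <= 1)) {
      abort_config(paste0(
        "crouch gains for knee extensors (VM, RF) must exceed 1 for ",
        p$participant_id
      ))
    }
  }
  invisible(profiles)
}
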