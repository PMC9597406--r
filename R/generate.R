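#' Generate one synthetic gait trial
#'
#' Simulates the raw, synchronized signals recorded during one treadmill
#' walking trial: seven channels of surface EMG and vertical ground reaction
#' force (GRF) at `sampling_rate`, plus breath-by-breath gas exchange. Every
#' EMG channel is a band-limited carrier (flat 20-350 Hz Gaussian noise, or a
#' deterministic in-band sinusoid) amplitude-modulated by a raised-cosine
#' burst spanning each stance phase, scaled by the condition-dependent gain
#' `baseline_i * (1 + incline_slope_i * grade)` for incline trials or
#' `baseline_i * crouch_gain_i` for crouch trials. The GRF is a per-stance
#' half-sine with peak `1.2 * mass * g` and exactly zero force in swing.
#' Breath rates rise exponentially (time constant `tau`) towards the
#' condition's steady-state target with independent multiplicative noise per
#' breath.
#'
#' The generator stores its ground truth (scheduled contact samples, per-muscle
#' gains, steady-state gas rates) in the `truth` element so downstream stages
#' can be validated against known values. Identical
#' `(profile, condition, grade, duration, seed)` reproduce identical output.
#'
#' @param profile One-row data frame as produced by [sample_profiles()].
#' @param condition `"incline"` or `"crouch"`.
#' @param grade Treadmill grade in percent (incline trials only).
#' @param duration Trial length in seconds; at least 90 s so the record holds
#'   a final-minute steady-state window and more than 20 strides.
#' @param seed Integer seed for this trial.
#' @param sampling_rate EMG/GRF sampling rate in Hz.
#' @param carrier `"noise"` (default) or `"sine"`; the sinusoidal carrier is
#'   deterministic and makes downstream activation ratios exactly equal to the
#'   generator gain ratios.
#' @param breath_noise_cv Multiplicative noise applied per breath to each gas
#'   rate (coefficient of variation).
#' @param stance_fraction Fraction of each stride spent in stance.
#' @param breath_rate Breaths per minute (mean).
#' @param tau Exponential rise time constant of gas exchange, seconds.
#' @param crouch_rep Optional label (`"initial"`/`"final"`) carried through to
#'   downstream tables for crouch trials.
#' @return A `gait_trial` object: a list with tibbles `emg`
#'   (`time_s` + muscle columns, volts), `grf` (`time_s`, `fz_n`), `breaths`
#'   (`time_s`, `vo2_l_s`, `vco2_l_s`), metadata fields, and `truth`.
#' @export
#' @examples
#' prof <- sample_profiles(1, seed = 2)
#' trial <- generate_trial(prof, "incline", grade = 6, duration = 90, seed = 7)
#' trial
generate_trial <- function(profile, condition = c("incline", "crouch"),
                           grade = 0, duration = 300, seed = 1,
                           sampling_rate = 2000,
                           carrier = c("noise", "sine"),
                           breath_noise_cv = 0.05,
                           stance_fraction = 0.6,
                           breath_rate = 15, tau = 30,
                           crouch_rep = NA_character_) {
  condition <- tryCatch(match.arg(condition),
    error = function(e) abort_config("unknown condition label")
  )
  carrier <- match.arg(carrier)
  if (!is_scalar_number(duration) || duration <= 0) {
    abort_config("`duration` must be a positive number of seconds")
  }
  if (duration < 90) {
    abort_config("`duration` must be >= 90 s (steady-state window + strides)")
  }
  if (condition == "incline" && (!is_scalar_number(grade) || grade < 0)) {
    abort_config("`grade` must be a non-negative percent for incline trials")
  }
  profile <- as_tibble(profile)
  validate_profiles(profile)
  p <- profile[1, ]
  fs <- sampling_rate
  n <- round(duration * fs)

  gains <- if (condition == "crouch") {
    p$baseline_gains[[1]] * p$crouch_gains[[1]]
  } else {
    p$baseline_gains[[1]] * (1 + p$incline_slope[[1]] * grade)
  }

  withr::local_seed(seed)

  # stride schedule: lognormal multiplicative jitter, mean preserved
  cv <- p$stride_time_cv
  sdlog <- sqrt(log(1 + cv^2))
  n_max <- ceiling(duration / (p$stride_time_mean * 0.8)) + 2
  t_strides <- p$stride_time_mean *
    exp(rnorm(n_max, -sdlog^2 / 2, sdlog))
  contacts <- 0.5 + cumsum(c(0, t_strides))
  keep <- which(contacts + c(t_strides, Inf) <= duration - 0.25)
  contacts <- contacts[keep]
  t_strides <- t_strides[keep]

  burst <- numeric(n)
  fz <- numeric(n)
  peak <- 1.2 * p$mass * 9.81
  contact_idx <- integer(length(contacts))
  for (j in seq_along(contacts)) {
    st <- round(stance_fraction * t_strides[j] * fs)
    i0 <- floor(contacts[j] * fs) + 1L
    contact_idx[j] <- i0
    s <- seq_len(st) - 1L
    idx <- i0 + s
    burst[idx] <- 0.5 * (1 - cos(2 * pi * s / (st - 1)))
    fz[idx] <- peak * pmax(sin(pi * s / (st - 1)), 0)
  }

  time_s <- (seq_len(n) - 1) / fs
  emg <- purrr::map(MUSCLES, function(m) {
    car <- if (carrier == "sine") {
      sqrt(2) * sin(2 * pi * 100 * time_s)
    } else {
      w <- rnorm(n)
      bp <- signal::butter(4, c(20, 350) / (fs / 2), type = "pass")
      x <- signal::filter(bp, w)
      as.numeric(x) / sd(x)
    }
    gains[[m]] * burst * car
  })
  names(emg) <- MUSCLES
  emg <- as_tibble(c(list(time_s = time_s), emg))

  # breath-by-breath gas exchange
  vo2_target <- switch(condition,
    crouch = p$vo2_crouch,
    incline = p$vo2_baseline + p$vo2_per_grade * grade
  )
  vco2_target <- p$rer * vo2_target
  mean_iv <- 60 / breath_rate
  iv_sdlog <- sqrt(log(1 + 0.15^2))
  n_breaths <- ceiling(duration / mean_iv * 1.5) + 5
  ivs <- mean_iv * exp(rnorm(n_breaths, -iv_sdlog^2 / 2, iv_sdlog))
  bt <- cumsum(ivs)
  bt <- bt[bt <= duration]
  rise <- 1 - exp(-bt / tau)
  vo2 <- pmax(vo2_target * rise * (1 + rnorm(length(bt), 0, breath_noise_cv)), 0)
  vco2 <- pmax(vco2_target * rise * (1 + rnorm(length(bt), 0, breath_noise_cv)), 0)
  breaths <- tibble(time_s = bt, vo2_l_s = vo2, vco2_l_s = vco2)

  structure(
    list(
      participant_id = p$participant_id,
      condition = condition,
      grade = if (condition == "incline") grade else NA_real_,
      crouch_rep = if (condition == "crouch") crouch_rep else NA_character_,
      emg = emg,
      grf = tibble(time_s = time_s, fz_n = fz),
      breaths = breaths,
      duration = duration,
      sampling_rate = fs,
      belt_speed = 1.15,
      mass = p$mass,
      excluded_channels = character(0),
      truth = list(
        contact_indices = contact_idx,
        contact_times = (contact_idx - 1) / fs,
        stride_times = t_strides,
        gains = gains,
        vo2_ss = vo2_target,
        vco2_ss = vco2_target,
        c_met_ss = 1000 * (16.89 * vo2_target + 4.82 * vco2_target) / p$mass
      ),
      seed = seed
    ),
    class = "gait_trial"
  )
}

#' @export
print.gait_trial <- function(x, ...) {
  lab <- if (x$condition == "incline") {
    sprintf("incline %g%%", x$grade)
  } else {
    paste0("crouch", if (!is.na(x$crouch_rep)) paste0(" (", x$crouch_rep, ")"))
  }
  cat(sprintf(
    "<gait_trial> %s, %s: %.0f s @ %g Hz, %d strides scheduled, %d breaths\n",
    x$participant_id, lab, x$duration, x$sampling_rate,
    length(x$truth$contact_indices), nrow(x$breaths)
  ))
  invisible(x)
}

# condition labels of the standard 7-trial recording set
cohort_conditions <- function(grades) {
  tibble(
    label = c("crouch_initial", paste0("incline_", grades), "crouch_final"),
    condition = c("crouch", rep("incline", length(grades)), "crouch"),
    grade = c(NA, grades, NA),
    crouch_rep = c("initial", rep(NA, length(grades)), "final")
  )
}

#' Generate a full synthetic cohort of gait trials
#'
#' For each participant, generates the standard recording set: an initial
#' crouch trial, one incline trial per grade, and a final crouch trial.
#' Per-trial seeds are derived deterministically from the cohort seed, the
#' participant id and the condition label, so any single trial can be
#' regenerated in isolation.
#'
#' @param profiles Participant profiles from [sample_profiles()].
#' @param grades Protocol incline grades (percent), non-empty.
#' @param duration Trial length in seconds.
#' @param seed Cohort seed.
#' @param ... Passed on to [generate_trial()].
#' @return A list of `gait_trial` objects (class `gait_cohort`) with a
#'   `manifest` attribute tibble (participant, label, condition, grade, seed).
#' @export
#' @examples
#' cohort <- generate_cohort(sample_profiles(2), duration = 90, seed = 3)
#' length(cohort) # 2 participants x 7 trials
generate_cohort <- function(profiles, grades = c(0, 6, 12, 18, 24),
                            duration = 300, seed = 1, ...) {
  validate_profiles(profiles)
  if (length(grades) == 0) abort_config("`grades` must be non-empty")
  conds <- cohort_conditions(grades)
  manifest <- tidyr::crossing(
    participant_id = profiles$participant_id,
    label = conds$label
  ) |>
    left_join(conds, by = "label") |>
    mutate(trial_seed = purrr::map2_int(
      .data$participant_id, .data$label,
      ~ hash_seed(seed, .x, .y)
    ))
  trials <- purrr::pmap(manifest, function(participant_id, label, condition,
                                           grade, crouch_rep, trial_seed) {
    prof <- profiles[profiles$participant_id == participant_id, ]
    generate_trial(prof,
      condition = condition,
      grade = if (is.na(grade)) 0 else grade,
      duration = duration, seed = trial_seed,
      crouch_rep = crouch_rep, ...
    )
  })
  names(trials) <- paste(manifest$participant_id, manifest$label, sep = "/")
  structure(trials, class = "gait_cohort", manifest = manifest)
}

#' Simulate gait-condition choices from trial costs
#'
#' Emulates a walker choosing, at each incline grade, between crouch walking
#' and upright incline walking by comparing a weighted composite of metabolic
#' power and an activation cost. Costs are first rescaled to the participant's
#' 0%-incline (level upright) trial; crouch is selected at a grade when
#' `w_met * C_met_crouch + w_act * C_act_crouch` is strictly less than the
#' incline composite; ties select the incline.
#'
#' @param costs Tibble of per-trial costs with columns `participant_id`,
#'   `condition` (`"crouch"`/`"incline"`), `grade`, `c_met_p` and the chosen
#'   activation metric. Crouch trials (any number per participant) are
#'   averaged.
#' @param weights Named numeric `c(w_met = , w_act = )`; non-negative, not
#'   both zero.
#' @param activation_metric Which activation cost drives the choice; the mean
#'   squared activation (`"c_a2"`) by default, the least biased of the
#'   fatigue-like costs.
#' @return Tibble with columns `participant_id`, `grade`, `selected`.
#' @export
simulate_choice <- function(costs, weights = c(w_met = 1, w_act = 0.5),
                            activation_metric = "c_a2") {
  if (!all(c("w_met", "w_act") %in% names(weights))) {
    abort_config("`weights` must be named c(w_met = , w_act = )")
  }
  w <- weights[c("w_met", "w_act")]
  if (any(w < 0) || sum(w) == 0) {
    abort_config("`weights` must be non-negative and not both zero")
  }
  needed <- c("participant_id", "condition", "grade", "c_met_p",
              activation_metric)
  if (!all(needed %in% names(costs))) {
    abort_config(paste0(
      "`costs` must have columns: ", paste(needed, collapse = ", ")
    ))
  }
  costs |>
    group_by(.data$participant_id) |>
    dplyr::group_modify(function(df, key) {
      base <- df[df$condition == "incline" & df$grade == 0, ]
      if (nrow(base) != 1) {
        abort_config(paste0(
          "missing 0%-incline baseline trial for ", key$participant_id
        ))
      }
      cr <- df[df$condition == "crouch", ]
      if (nrow(cr) == 0) {
        abort_config(paste0("missing crouch trials for ", key$participant_id))
      }
      grades <- sort(unique(df$grade[df$condition == "incline"]))
      cr_score <- w[["w_met"]] * mean(cr$c_met_p) / base$c_met_p +
        w[["w_act"]] * mean(cr[[activation_metric]]) /
          base[[activation_metric]]
      purrr::map_dfr(grades, function(g) {
        inc <- df[df$condition == "incline" & df$grade == g, ]
        inc_score <- w[["w_met"]] * inc$c_met_p / base$c_met_p +
          w[["w_act"]] * inc[[activation_metric]] / base[[activation_metric]]
        tibble(
          grade = g,
          selected = if (cr_score < inc_score) "crouch" else "incline"
        )
      })
    }) |>
    ungroup()
}
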