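#' Experiment configuration
#'
#' Collects and validates every tunable setting of the pipeline. Defaults are
#' the study-protocol values: 2000 Hz sampling, 20-350 Hz EMG band-pass, 6 Hz
#' envelope low-pass, 2%-of-peak stride threshold, 5 analysed strides, a
#' final-minute (60 s) metabolic window, five grades 0-24%, 300 s trials, and
#' significance levels 0.05 (omnibus) / 0.017 (Bonferroni pairwise).
#'
#' @param mode `"simulate"` (generate a synthetic cohort and run the full
#'   signal pipeline), `"example"` (analyse the packaged percent-of-baseline
#'   worked example, skipping the signal stages) or `"directory"` (read
#'   trials written by [write_cohort()]).
#' @param n_participants Cohort size in simulate mode.
#' @param grades Protocol incline grades (percent).
#' @param duration Trial length, seconds.
#' @param seed Single seed behind all randomness.
#' @param sampling_rate,band,lowpass EMG processing settings (Hz).
#' @param threshold_fraction,refractory Stride detection settings.
#' @param n_strides Strides analysed per trial.
#' @param analysis_window Seconds of EMG/GRF (from trial start) used for
#'   stride and activation analysis.
#' @param metabolic_window Final-window length for gas-exchange averaging,
#'   seconds.
#' @param weights Choice-model weights `c(w_met = , w_act = )`.
#' @param crouch_rule Which crouch trials represent crouch walking
#'   (`"mean"`, `"initial"`, `"final"`).
#' @param alpha,posthoc_alpha Significance levels.
#' @param input_dir Trial directory for `"directory"` mode.
#' @return A validated `experiment_config` list.
#' @export
experiment_config <- function(mode = c("simulate", "example", "directory"),
                              n_participants = 10,
                              grades = c(0, 6, 12, 18, 24),
                              duration = 300, seed = 1,
                              sampling_rate = 2000, band = c(20, 350),
                              lowpass = 6, threshold_fraction = 0.02,
                              refractory = 0.2, n_strides = 5,
                              analysis_window = 30, metabolic_window = 60,
                              weights = c(w_met = 1, w_act = 0.5),
                              crouch_rule = c("mean", "initial", "final"),
                              alpha = 0.05, posthoc_alpha = 0.017,
                              input_dir = NULL) {
  mode <- match.arg(mode)
  crouch_rule <- match.arg(crouch_rule)
  if (sampling_rate <= 2 * band[2]) {
    abort_config(paste0(
      "sampling_rate (", sampling_rate, " Hz) must exceed twice the upper ",
      "band edge (", band[2], " Hz)"
    ))
  }
  if (!0 %in% grades) {
    abort_config("protocol grades must include the 0% baseline trial")
  }
  if (mode == "directory" && is.null(input_dir)) {
    abort_config("`input_dir` is required in directory mode")
  }
  structure(
    list(
      mode = mode, n_participants = n_participants, grades = sort(grades),
      duration = duration, seed = seed, sampling_rate = sampling_rate,
      band = band, lowpass = lowpass,
      threshold_fraction = threshold_fraction, refractory = refractory,
      n_strides = n_strides, analysis_window = analysis_window,
      metabolic_window = metabolic_window, weights = weights,
      crouch_rule = crouch_rule, alpha = alpha,
      posthoc_alpha = posthoc_alpha, input_dir = input_dir
    ),
    class = "experiment_config"
  )
}

# signal analysis of one trial: strides, activation rates, metabolic power
analyze_trial <- function(trial, config, baseline = NULL) {
  fs <- trial$sampling_rate
  n_win <- min(round(config$analysis_window * fs), nrow(trial$grf))
  strides <- detect_strides(
    trial$grf$fz_n[seq_len(n_win)], fs,
    threshold_fraction = config$threshold_fraction,
    refractory = config$refractory
  )
  env <- compute_envelope(
    trial$emg[seq_len(n_win), , drop = FALSE], fs,
    band = config$band, lowpass = config$lowpass
  )
  act <- compute_activation(env, strides,
    baseline = baseline, n_strides = config$n_strides,
    excluded_channels = trial$excluded_channels
  )
  met <- metabolic_power(trial$breaths, trial$mass,
    trial_duration = trial$duration, window = config$metabolic_window
  )
  costs <- trial_costs(act, met,
    participant_id = trial$participant_id,
    condition = trial$condition, grade = trial$grade,
    crouch_rep = trial$crouch_rep
  )
  list(strides = strides, activation = act, metabolic = met, costs = costs)
}

# recovery diagnostics against generator ground truth, if present
trial_diagnostics <- function(trial, res, label) {
  if (is.null(trial$truth)) return(NULL)
  fs <- trial$sampling_rate
  det <- res$strides$contact_indices
  tru <- trial$truth$contact_indices
  tru <- tru[tru <= max(det) + fs]
  k <- min(length(det), length(tru))
  contact_err_ms <- max(abs(det[seq_len(k)] - tru[seq_len(k)])) / fs * 1000
  met_err_pct <- 100 * (res$metabolic$c_met_p - trial$truth$c_met_ss) /
    trial$truth$c_met_ss
  mean_A <- res$activation |>
    group_by(.data$muscle) |>
    summarise(mean_A = mean(.data$A), .groups = "drop")
  list(
    summary = tibble(
      participant_id = trial$participant_id, label = label,
      contact_err_ms = contact_err_ms, met_err_pct = met_err_pct
    ),
    activation = mutate(mean_A,
      participant_id = trial$participant_id, label = label,
      gain = trial$truth$gains[as.character(.data$muscle)]
    )
  )
}

#' Run the full experiment pipeline
#'
#' Orchestrates the analysis end to end. In `simulate` mode: draws a cohort
#' of participant profiles, generates the standard recording set per
#' participant (initial crouch, one trial per incline grade, final crouch),
#' detects strides from the vertical GRF, extracts EMG linear envelopes and
#' per-stride activation rates normalized to the 0%-incline trial, computes
#' final-minute metabolic power and the three activation cost functionals,
#' simulates the crouch-versus-incline choice at every grade, derives
#' transition grades, evaluates the competing-cost-pair rule, and produces
#' group summaries and condition-comparison statistics. Deterministic given
#' the configuration (one seed governs all randomness).
#'
#' In `example` mode the packaged percent-of-baseline worked example is
#' analysed directly, skipping the signal stages.
#'
#' @param config An [experiment_config()].
#' @return A `gait_experiment` list: `costs`, `choices`, `transitions`,
#'   `ccp`, `summary_ccp`, `summary_all`, `comparisons` (one
#'   [compare_conditions()] result per cost metric, where evaluable),
#'   `diagnostics` (generator-truth recovery, simulate mode only) and
#'   `config`.
#' @export
#' @examples
#' \donttest{
#' cfg <- experiment_config(mode = "simulate", n_participants = 2,
#'                          duration = 120, seed = 1)
#' exp <- run_experiment(cfg)
#' exp$ccp
#' }
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  if (config$mode == "example") {
    res <- ccp_example_analysis()
    return(structure(
      list(
        costs = NULL, choices = NULL, transitions = NULL, ccp = res$ccp,
        summary_ccp = res$summary_ccp, summary_all = res$summary_all,
        comparisons = NULL, diagnostics = NULL, config = config
      ),
      class = "gait_experiment"
    ))
  }

  if (config$mode == "simulate") {
    profiles <- sample_profiles(config$n_participants, seed = config$seed)
    conds <- cohort_conditions(config$grades)
    get_trial <- function(pid, i) {
      prof <- profiles[profiles$participant_id == pid, ]
      generate_trial(prof,
        condition = conds$condition[i],
        grade = if (is.na(conds$grade[i])) 0 else conds$grade[i],
        duration = config$duration,
        seed = hash_seed(config$seed, pid, conds$label[i]),
        sampling_rate = config$sampling_rate,
        crouch_rep = conds$crouch_rep[i]
      )
    }
    pids <- profiles$participant_id
  } else {
    manifest <- jsonlite::read_json(
      file.path(config$input_dir, "cohort.json"),
      simplifyVector = TRUE
    )$trials
    conds <- manifest[, c("label", "condition", "grade", "crouch_rep")]
    get_trial <- function(pid, i) {
      read_trial(file.path(
        config$input_dir,
        manifest$path[manifest$participant_id == pid &
                        manifest$label == conds$label[i]]
      ))
    }
    pids <- unique(manifest$participant_id)
    conds <- unique(conds)
    profiles <- NULL
  }

  # analyse the 0%-incline trial first so its activation means provide the
  # per-participant normalization baseline
  order_idx <- order(conds$label != "incline_0")
  costs <- list()
  diag_summary <- list()
  diag_act <- list()
  for (pid in pids) {
    baseline <- NULL
    for (i in order_idx) {
      trial <- get_trial(pid, i)
      res <- analyze_trial(trial, config, baseline = baseline)
      if (conds$label[i] == "incline_0") baseline <- res$activation
      costs[[paste(pid, conds$label[i])]] <- res$costs
      dg <- trial_diagnostics(trial, res, conds$label[i])
      if (!is.null(dg)) {
        diag_summary[[paste(pid, conds$label[i])]] <- dg$summary
        diag_act[[paste(pid, conds$label[i])]] <- dg$activation
      }
      rm(trial, res)
    }
  }
  costs <- bind_rows(costs)

  choices <- simulate_choice(costs, weights = config$weights)
  transitions <- identify_transitions(choices, grades = config$grades)
  ccp <- ccp_table(costs, transitions, crouch_rule = config$crouch_rule)
  summary_ccp <- tryCatch(ccp_summary(ccp, restrict_to_ccp = TRUE),
                          error = function(e) NULL)
  summary_all <- tryCatch(ccp_summary(ccp, restrict_to_ccp = FALSE),
                          error = function(e) NULL)
  comparisons <- condition_comparisons(costs, transitions, config)

  diagnostics <- NULL
  if (length(diag_summary) > 0) {
    act <- bind_rows(diag_act)
    base_gain <- act |>
      filter(.data$label == "incline_0") |>
      select("participant_id", "muscle", gain0 = "gain")
    act <- act |>
      left_join(base_gain, by = c("participant_id", "muscle")) |>
      mutate(
        true_ratio = .data$gain / .data$gain0,
        recovered_ratio = .data$mean_A,
        ratio_err_pct = 100 * (.data$recovered_ratio / .data$true_ratio - 1)
      )
    diagnostics <- list(trials = bind_rows(diag_summary), activation = act)
  }

  structure(
    list(
      profiles = profiles, costs = costs, choices = choices,
      transitions = transitions, ccp = ccp, summary_ccp = summary_ccp,
      summary_all = summary_all, comparisons = comparisons,
      diagnostics = diagnostics, config = config
    ),
    class = "gait_experiment"
  )
}

# crouch / pre-transition / post-transition matched comparisons per metric
condition_comparisons <- function(costs, transitions, config) {
  tr <- transitions |>
    filter(!is.na(.data$pre_transition_grade),
           !is.na(.data$post_transition_grade), .data$monotone)
  if (nrow(tr) < 3) return(NULL)
  long <- purrr::map_dfr(seq_len(nrow(tr)), function(i) {
    pid <- tr$participant_id[i]
    df <- costs[costs$participant_id == pid, ]
    cr <- df[df$condition == "crouch", ]
    pre <- df[df$condition == "incline" &
                df$grade == tr$pre_transition_grade[i], ]
    post <- df[df$condition == "incline" &
                 df$grade == tr$post_transition_grade[i], ]
    if (nrow(pre) != 1 || nrow(post) != 1 || nrow(cr) == 0) return(NULL)
    purrr::map_dfr(cost_metrics, function(m) {
      tibble(
        participant_id = pid, metric = m,
        condition = c("crouch", "pre_transition", "post_transition"),
        value = c(mean(cr[[m]]), pre[[m]], post[[m]])
      )
    })
  })
  purrr::map(setNames(cost_metrics, cost_metrics), function(m) {
    d <- long[long$metric == m & is.finite(long$value), ]
    tryCatch(
      compare_conditions(d, "value",
        alpha = config$alpha, posthoc_alpha = config$posthoc_alpha
      ),
      error = function(e) NULL
    )
  })
}

#' @export
print.gait_experiment <- function(x, ...) {
  cat("<gait_experiment>", x$config$mode, "mode\n")
  if (!is.null(x$ccp)) {
    cat(sprintf(
      "  CCP (mean squared activation / metabolic): %d accepted, %d rejected, %d not evaluable\n",
      sum(x$ccp$ccp_a2, na.rm = TRUE),
      sum(!x$ccp$ccp_a2, na.rm = TRUE),
      sum(is.na(x$ccp$ccp_a2))
    ))
  }
  if (!is.null(x$summary_ccp)) {
    s <- x$summary_ccp
    cat(sprintf(
      "  CCP subset (n = %d): advantages a2 %.0f%%, amax %.0f%%, avol %.0f%%; metabolic penalty %.0f%%\n",
      s$n[1], s$mean[s$metric == "advantage_a2"],
      s$mean[s$metric == "advantage_a_max"],
      s$mean[s$metric == "advantage_a_vol"],
      s$mean[s$metric == "penalty_met"]
    ))
  }
  invisible(x)
}

#' Write the experiment artifact bundle
#'
#' Persists `costs.csv`, `choices.csv`, `ccp_results.csv`,
#' `group_summary.json` (both group summaries plus one-line statistics per
#' metric) and `run_manifest.json` (the full configuration) to a directory.
#'
#' @param x A `gait_experiment`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(x, dir) {
  stopifnot(inherits(x, "gait_experiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(x$costs)) {
    readr::write_csv(x$costs, file.path(dir, "costs.csv"))
  }
  if (!is.null(x$choices)) {
    readr::write_csv(x$choices, file.path(dir, "choices.csv"))
  }
  readr::write_csv(x$ccp, file.path(dir, "ccp_results.csv"))
  summaries <- list(
    ccp_subset = x$summary_ccp,
    all_complete = x$summary_all,
    comparisons = if (!is.null(x$comparisons)) {
      purrr::map(x$comparisons, ~ if (!is.null(.x)) glance(.x))
    }
  )
  jsonlite::write_json(summaries, file.path(dir, "group_summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  cfg <- x$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
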