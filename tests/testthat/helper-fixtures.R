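# shared fixture builders; everything is generated in code at test time

# one-row profile tibble with exactly controlled parameters
make_profile <- function(id = "T01", mass = 70,
                         baseline = rep(0.05, 7),
                         slope = rep(0.05, 7),
                         crouch = c(1.3, 1.3, 2.8, 3.5, 1.3, 1.3, 1.3),
                         vo2_baseline = 0.014, vo2_per_grade = 0.00105,
                         vo2_crouch = 0.024, rer = 0.85,
                         stride_time_mean = 1.05, stride_time_cv = 0.03) {
  m <- muscle_channels()
  tibble::tibble(
    participant_id = id, mass = mass, height = 1.7,
    baseline_gains = list(stats::setNames(baseline, m)),
    incline_slope = list(stats::setNames(slope, m)),
    crouch_gains = list(stats::setNames(crouch, m)),
    vo2_baseline = vo2_baseline, vo2_per_grade = vo2_per_grade,
    vo2_crouch = vo2_crouch, rer = rer,
    stride_time_mean = stride_time_mean, stride_time_cv = stride_time_cv,
    seed = 1L
  )
}

# half-sine stance train with known onsets (seconds); returns force vector
make_halfsine_grf <- function(onsets_s, stance_s = 0.7, fs = 2000,
                              peak = 700, total_s = NULL) {
  total_s <- total_s %||% (max(onsets_s) + stance_s + 0.5)
  fz <- numeric(round(total_s * fs))
  st <- round(stance_s * fs)
  for (t0 in onsets_s) {
    i0 <- round(t0 * fs) + 1
    s <- seq_len(st) - 1
    fz[i0 + s] <- peak * pmax(sin(pi * s / (st - 1)), 0)
  }
  fz
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# activation table built directly from a 7 x k matrix of normalized values
make_activation_tbl <- function(A, a = A, baseline = rep(1, 7)) {
  m <- muscle_channels()
  rownames(A) <- m
  k <- ncol(A)
  out <- tibble::tibble(
    muscle = factor(rep(m, times = k), levels = m),
    stride = rep(seq_len(k), each = 7),
    a = as.vector(a),
    A = as.vector(A)
  )
  structure(out,
    baseline_means = stats::setNames(baseline, m),
    class = c("activation_tbl", class(out))
  )
}

# named cost list for evaluate_ccp
cost_list <- function(met, a2, amax, avol) {
  list(c_met_p = met, c_a2 = a2, c_a_max = amax, c_a_vol = avol)
}

# per-trial cost table for a hand-built participant: crouch costs constant,
# incline costs growing with grade
make_choice_costs <- function(id = "P1",
                              grades = c(0, 6, 12, 18, 24),
                              met_crouch = 1.75, a2_crouch = 3.2,
                              met_slope = 0.075, a2_gain_slope = 0.05) {
  inc <- tibble::tibble(
    participant_id = id, condition = "incline", grade = grades,
    crouch_rep = NA_character_,
    c_met_p = 1 + met_slope * grades,
    c_a2 = (1 + a2_gain_slope * grades)^2,
    c_a_max = (1 + a2_gain_slope * grades),
    c_a_vol = (1 + a2_gain_slope * grades)
  )
  cr <- tibble::tibble(
    participant_id = id, condition = "crouch", grade = NA_real_,
    crouch_rep = c("initial", "final"),
    c_met_p = met_crouch, c_a2 = a2_crouch,
    c_a_max = sqrt(a2_crouch), c_a_vol = sqrt(a2_crouch)
  )
  dplyr::bind_rows(inc, cr)
}
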