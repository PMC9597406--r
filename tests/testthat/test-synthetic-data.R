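test_that("equal seeds reproduce bit-identical trials; different seeds differ", {
  prof <- make_profile()
  a <- generate_trial(prof, "incline", grade = 6, duration = 90, seed = 12)
  b <- generate_trial(prof, "incline", grade = 6, duration = 90, seed = 12)
  expect_identical(a$emg, b$emg)
  expect_identical(a$grf, b$grf)
  expect_identical(a$breaths, b$breaths)
  c <- generate_trial(prof, "incline", grade = 6, duration = 90, seed = 13)
  expect_false(identical(a$emg, c$emg))
})

test_that("zero baseline gains produce identically zero EMG", {
  prof <- make_profile(baseline = rep(0, 7))
  tr <- generate_trial(prof, "incline", grade = 12, duration = 90, seed = 2)
  for (m in muscle_channels()) expect_true(all(tr$emg[[m]] == 0))
})

test_that("trial invariants hold across conditions and seeds", {
  prof <- make_profile()
  for (spec in list(list("crouch", 0), list("incline", 0), list("incline", 24))) {
    tr <- generate_trial(prof, spec[[1]], grade = spec[[2]], duration = 90,
                         seed = 31)
    expect_equal(nrow(tr$emg), nrow(tr$grf))
    expect_true(all(tr$grf$fz_n >= 0))
    expect_true(all(diff(tr$breaths$time_s) > 0))
    expect_true(all(tr$breaths$time_s >= 0 & tr$breaths$time_s <= tr$duration))
    expect_gte(length(tr$truth$contact_indices), 6)
    # swing-phase force is exactly zero outside scheduled stances
    expect_gt(mean(tr$grf$fz_n == 0), 0.3)
  }
})

test_that("ground-truth gains follow the condition model", {
  prof <- make_profile(baseline = rep(0.04, 7), slope = rep(0.05, 7))
  t24 <- generate_trial(prof, "incline", grade = 24, duration = 90, seed = 1)
  expect_equal(unname(t24$truth$gains), rep(0.04 * 2.2, 7))
  tcr <- generate_trial(prof, "crouch", duration = 90, seed = 1)
  expect_equal(unname(tcr$truth$gains["VM"] / 0.04),
               unname(prof$crouch_gains[[1]]["VM"]))
})

test_that("invalid generation requests are configuration errors", {
  prof <- make_profile()
  expect_error(generate_trial(prof, "incline", duration = -5),
               class = "gaitccp_error_config")
  expect_error(generate_trial(prof, "incline", duration = 30),
               class = "gaitccp_error_config")
  expect_error(generate_trial(prof, "hopping", duration = 300),
               class = "gaitccp_error_config")
  expect_error(generate_trial(prof, "incline", grade = -3, duration = 300),
               class = "gaitccp_error_config")
})

test_that("cohorts have two crouch trials plus one trial per grade, deterministically", {
  profs <- sample_profiles(2, seed = 5)
  co <- generate_cohort(profs, grades = c(0, 12), duration = 90, seed = 5)
  expect_length(co, 2 * 4)
  man <- attr(co, "manifest")
  expect_equal(sum(man$condition == "crouch"), 4)
  expect_equal(sum(man$condition == "incline"), 4)
  co2 <- generate_cohort(profs, grades = c(0, 12), duration = 90, seed = 5)
  expect_identical(co[[3]]$emg, co2[[3]]$emg)
  # duplicate participants rejected
  expect_error(generate_cohort(dplyr::bind_rows(profs[1, ], profs[1, ]),
                               duration = 90),
               class = "gaitccp_error_config")
})

test_that("sampled profiles satisfy their invariants", {
  profs <- sample_profiles(10, seed = 99)
  expect_equal(nrow(profs), 10)
  for (i in 1:10) {
    expect_true(all(profs$crouch_gains[[i]][c("VM", "RF")] > 1))
    expect_true(profs$rer[i] >= 0.7 && profs$rer[i] <= 1.1)
    expect_gt(profs$mass[i], 0)
  }
})

test_that("degenerate choice weights reduce to single-cost minimization", {
  costs <- make_choice_costs()
  met_only <- simulate_choice(costs, weights = c(w_met = 1, w_act = 0))
  act_only <- simulate_choice(costs, weights = c(w_met = 0, w_act = 1))
  base <- costs[costs$condition == "incline" & costs$grade == 0, ]
  cr <- costs[costs$condition == "crouch", ]
  for (g in unique(met_only$grade)) {
    inc <- costs[costs$condition == "incline" & costs$grade == g, ]
    expect_equal(
      met_only$selected[met_only$grade == g],
      if (mean(cr$c_met_p) < inc$c_met_p) "crouch" else "incline"
    )
    expect_equal(
      act_only$selected[act_only$grade == g],
      if (mean(cr$c_a2) < inc$c_a2) "crouch" else "incline"
    )
  }
})

test_that("ties select the incline and invalid weights are rejected", {
  costs <- make_choice_costs()
  # make crouch exactly equal to the 12% incline in both rescaled costs
  inc12 <- costs[costs$condition == "incline" & costs$grade == 12, ]
  costs$c_met_p[costs$condition == "crouch"] <- inc12$c_met_p
  costs$c_a2[costs$condition == "crouch"] <- inc12$c_a2
  ch <- simulate_choice(costs, weights = c(w_met = 1, w_act = 1))
  expect_equal(ch$selected[ch$grade == 12], "incline")
  expect_error(simulate_choice(costs, weights = c(w_met = 0, w_act = 0)),
               class = "gaitccp_error_config")
  expect_error(simulate_choice(costs[costs$grade != 0 | costs$condition == "crouch", ],
                               weights = c(w_met = 1, w_act = 1)),
               class = "gaitccp_error_config")
})

test_that("raising the activation weight moves the crouch transition to steeper grades", {
  costs <- make_choice_costs()
  post_grade <- function(w_act) {
    ch <- simulate_choice(costs, weights = c(w_met = 1, w_act = w_act))
    tr <- identify_transitions(ch)
    out <- tr$post_transition_grade
    if (is.na(out)) 30 else out # beyond the protocol = never transitions
  }
  sweep <- vapply(c(0, 0.1, 0.25, 0.5, 1, 2, 5), post_grade, numeric(1))
  expect_true(all(diff(sweep) >= 0))
  expect_lt(sweep[1], sweep[length(sweep)])
})
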