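choice_seq <- function(sel, id = "P1", grades = c(0, 6, 12, 18, 24)) {
  tibble::tibble(participant_id = id, grade = grades, selected = sel)
}

test_that("pre/post-transition grades follow the selection rule", {
  tr <- identify_transitions(choice_seq(c(rep("incline", 4), "crouch")))
  expect_equal(tr$pre_transition_grade, 18)
  expect_equal(tr$post_transition_grade, 24)
  expect_true(tr$monotone)

  all_crouch <- identify_transitions(choice_seq(rep("crouch", 5)))
  expect_true(is.na(all_crouch$pre_transition_grade))
  expect_equal(all_crouch$post_transition_grade, 0)

  all_incline <- identify_transitions(choice_seq(rep("incline", 5)))
  expect_equal(all_incline$pre_transition_grade, 24)
  expect_true(is.na(all_incline$post_transition_grade))

  mixed <- identify_transitions(
    choice_seq(c("incline", "crouch", "incline", "crouch", "crouch"))
  )
  expect_equal(mixed$pre_transition_grade, 12)
  expect_equal(mixed$post_transition_grade, 6)
  expect_false(mixed$monotone)
})

test_that("transition detection validates its input", {
  expect_error(identify_transitions(choice_seq(rep("inc", 5))),
               class = "gaitccp_error_data")
  expect_error(identify_transitions(choice_seq(rep("incline", 4),
                                               grades = c(0, 6, 12, 18))),
               class = "gaitccp_error_data")
})

test_that("the CCP rule and percentages match the worked example rows", {
  base100 <- cost_list(100, 100, 100, 100)
  # participant with a clear CCP: cheaper crouch metabolically, costlier in
  # mean squared activation
  r1 <- evaluate_ccp(cost_list(172.5, 566.0, 292.2, 167.1),
                     cost_list(189.5, 290.8, 196.8, 125.7), base100)
  expect_true(r1$ccp_a2)
  expect_true(r1$ccp_a_max)
  expect_true(r1$ccp_a_vol)
  expect_equal(r1$advantage_a2, 100 * (566.0 - 290.8) / 290.8,
               tolerance = 1e-12)
  expect_equal(round(r1$advantage_a2, 1), 94.6)
  expect_equal(round(r1$penalty_met, 0), 9)

  # participant whose metabolic power barely differs: no CCP
  r6 <- evaluate_ccp(cost_list(204.9, 1409.4, 747.6, 239.7),
                     cost_list(202.5, 454.2, 368.4, 154.4), base100)
  expect_false(r6$ccp_a2)
  expect_equal(round(r6$advantage_a2), 210)

  # excluded activation data propagates as NA
  rna <- evaluate_ccp(cost_list(170.9, NA, NA, NA),
                      cost_list(200.6, NA, NA, NA), base100)
  expect_true(is.na(rna$ccp_a2))
  expect_true(is.na(rna$advantage_a2))
  expect_false(is.na(rna$penalty_met))
})

test_that("exact ties never accept a CCP", {
  base <- cost_list(5, 2, 1.5, 1.2)
  same <- cost_list(6, 3, 2, 1.5)
  r <- evaluate_ccp(same, same, base)
  expect_false(r$ccp_a2)
  expect_false(r$ccp_a_max)
  expect_false(r$ccp_a_vol)
  expect_equal(r$advantage_a2, 0)
})

test_that("CCP percentages are invariant to common rescaling of a participant's costs", {
  cr <- cost_list(6.2, 3.1, 2.2, 1.4)
  inc <- cost_list(7.5, 1.9, 1.6, 1.2)
  base <- cost_list(4.1, 1.0, 1.0, 1.0)
  r1 <- evaluate_ccp(cr, inc, base)
  k <- 7.3
  r2 <- evaluate_ccp(lapply(cr, `*`, k), lapply(inc, `*`, k),
                     lapply(base, `*`, k))
  for (col in c("ccp_a2", "ccp_a_max", "ccp_a_vol")) {
    expect_identical(r1[[col]], r2[[col]])
  }
  for (col in c("advantage_a2", "advantage_a_max", "advantage_a_vol",
                "penalty_met")) {
    expect_equal(r1[[col]], r2[[col]], tolerance = 1e-12)
  }
})

test_that("swapping crouch and incline negates advantages and forbids two-way CCPs", {
  cr <- cost_list(6.2, 3.1, 2.2, 1.4)
  inc <- cost_list(7.5, 1.9, 1.6, 1.2)
  base <- cost_list(4.1, 1.0, 1.0, 1.0)
  fwd <- evaluate_ccp(cr, inc, base)
  rev <- evaluate_ccp(inc, cr, base)
  # sign flips up to the denominator convention
  expect_equal(sign(fwd$advantage_a2), -sign(rev$advantage_a2))
  expect_equal(sign(fwd$penalty_met), -sign(rev$penalty_met))
  expect_false(isTRUE(fwd$ccp_a2) && isTRUE(rev$ccp_a2))
})

test_that("degenerate denominators are rejected", {
  good <- cost_list(6, 3, 2, 1.5)
  expect_error(evaluate_ccp(good, good, cost_list(0, 1, 1, 1)),
               class = "gaitccp_error_data")
  expect_error(evaluate_ccp(good, cost_list(0, 3, 2, 1.5),
                            cost_list(5, 1, 1, 1)),
               class = "gaitccp_error_data")
})

test_that("the full worked-example cohort reproduces the reported CCP pattern", {
  res <- ccp_example_analysis()
  ccp <- res$ccp
  expect_equal(sum(ccp$ccp_a2, na.rm = TRUE), 7)
  expect_equal(sum(is.na(ccp$ccp_a2)), 2)
  expect_identical(ccp$participant_id[which(!ccp$ccp_a2)], "P06")
  # computed flags agree with the reported ones for every pairing
  for (pair in c("a2", "a_max", "a_vol")) {
    comp <- ccp[[paste0("ccp_", pair)]]
    rep_ <- ccp[[paste0("ccp_", pair, "_reported")]]
    expect_identical(comp, rep_ == "Y")
  }
})

test_that("group summaries average per-participant percentages with ranges", {
  res <- ccp_example_analysis()
  s <- res$summary_ccp
  expect_equal(s$n, rep(7, 4))
  one <- ccp_summary(res$ccp[res$ccp$participant_id == "P01", ],
                     restrict_to_ccp = TRUE)
  expect_equal(one$mean, one$min)
  expect_equal(one$mean, one$max)
  expect_error(ccp_summary(res$ccp[0, ]), class = "gaitccp_error_data")
})

test_that("ccp_table handles missing pre-transition inclines and crouch rules", {
  costs <- make_choice_costs()
  tr <- tibble::tibble(participant_id = "P1", pre_transition_grade = 12,
                       post_transition_grade = 18, monotone = TRUE)
  tab <- ccp_table(costs, tr)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$met_incline_pct, 100 * 1.9 / 1, tolerance = 1e-12)
  # initial/final crouch selection changes nothing here (equal crouch trials)
  tab_i <- ccp_table(costs, tr, crouch_rule = "initial")
  expect_equal(tab$a2_crouch_pct, tab_i$a2_crouch_pct)

  none <- tibble::tibble(participant_id = "P1",
                         pre_transition_grade = NA_real_,
                         post_transition_grade = 0, monotone = TRUE)
  tab0 <- ccp_table(costs, none)
  expect_equal(tab0$note, "no CCP evaluable")
  expect_true(is.na(tab0$ccp_a2))
})
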