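test_that("envelope of a zero signal is zero and output length matches input", {
  fs <- 2000
  x <- numeric(fs * 3)
  env <- compute_envelope(x, fs)
  expect_equal(length(env), length(x))
  expect_true(all(env == 0))
})

test_that("envelope is positively homogeneous in the raw signal", {
  fs <- 2000
  x <- withr::with_seed(5, rnorm(fs * 4))
  e1 <- compute_envelope(x, fs)
  e3 <- compute_envelope(3.7 * x, fs)
  expect_equal(e3, 3.7 * e1, tolerance = 1e-8)
})

test_that("envelope of an in-band sinusoid matches the rectified-mean oracle", {
  # |A sin| has mean 2A/pi; the 6 Hz low-pass keeps that DC level
  fs <- 2000
  amp <- 0.5
  x <- amp * sin(2 * pi * 100 * seq(0, 6, by = 1 / fs))
  env <- compute_envelope(x, fs)
  mid <- env[(2 * fs):(4 * fs)]
  expect_equal(mean(mid), 2 * amp / pi, tolerance = 0.02)
})

test_that("envelope input validation is strict", {
  expect_error(compute_envelope(rnorm(2000), sampling_rate = 600),
               class = "gaitccp_error_config")
  bad <- tibble::tibble(time_s = 1:6000 / 2000, VM = c(NA, rnorm(5999)))
  expect_error(compute_envelope(bad, 2000), class = "gaitccp_error_data",
               regexp = "VM")
  expect_error(compute_envelope(rnorm(1000), 2000),
               class = "gaitccp_error_data")
})

constant_envelopes <- function(value, n, fs = 2000) {
  m <- muscle_channels()
  df <- tibble::as_tibble(c(
    list(time_s = (seq_len(n) - 1) / fs),
    stats::setNames(rep(list(rep(value, n)), 7), m)
  ))
  df
}

test_that("a constant envelope yields a_ij equal to the constant, whatever the stride duration", {
  fs <- 2000
  # unequal stride durations by construction
  fz <- make_halfsine_grf(c(0.5, 1.4, 2.6, 3.5, 4.9, 5.8, 7.2), stance_s = 0.5,
                          fs = fs, total_s = 8)
  sw <- detect_strides(fz, fs)
  env <- constant_envelopes(0.37, length(fz), fs)
  act <- compute_activation(env, sw, n_strides = 5)
  expect_equal(act$a, rep(0.37, 35), tolerance = 1e-12)
  # self-normalized: every A equals 1
  expect_equal(act$A, rep(1, 35), tolerance = 1e-12)
})

test_that("the 0%-incline trial normalized against itself has unit per-muscle mean", {
  prof <- make_profile()
  tr <- generate_trial(prof, "incline", grade = 0, duration = 90, seed = 9)
  fs <- tr$sampling_rate
  n_win <- 20 * fs
  sw <- detect_strides(tr$grf$fz_n[1:n_win], fs)
  env <- compute_envelope(tr$emg[1:n_win, ], fs)
  act <- compute_activation(env, sw)
  means <- tapply(act$A, act$muscle, mean)
  expect_equal(as.numeric(means[muscle_channels()]), rep(1, 7),
               tolerance = 1e-10)
})

test_that("trapezoidal stride integrals match the closed form for a raised-cosine burst", {
  # envelope g/2 * (1 - cos(2 pi t / T)) integrates to g T / 2 over a stride
  fs <- 2000
  T_j <- 1.1
  g <- 0.8
  n <- round(8 * fs)
  tt <- (seq_len(n) - 1) / fs
  env_val <- g / 2 * (1 - cos(2 * pi * (tt %% T_j) / T_j))
  m <- muscle_channels()
  env <- tibble::as_tibble(c(list(time_s = tt),
                             stats::setNames(rep(list(env_val), 7), m)))
  onsets <- T_j * (0:6)
  fz <- make_halfsine_grf(onsets + 1e-9, stance_s = 0.6, fs = fs, total_s = 8)
  sw <- detect_strides(fz, fs)
  act <- compute_activation(env, sw, n_strides = 5)
  # closed form: time-average of the raised cosine over a full period = g/2
  expect_equal(act$a, rep(g / 2, 35), tolerance = 1e-3)
})

test_that("activation scales linearly with the raw EMG given a fixed baseline", {
  prof <- make_profile()
  tr <- generate_trial(prof, "incline", grade = 0, duration = 90, seed = 21)
  fs <- tr$sampling_rate
  n_win <- 20 * fs
  sw <- detect_strides(tr$grf$fz_n[1:n_win], fs)
  emg1 <- tr$emg[1:n_win, ]
  emg2 <- emg1
  for (m in muscle_channels()) emg2[[m]] <- 2.5 * emg2[[m]]
  act1 <- compute_activation(compute_envelope(emg1, fs), sw)
  bl <- baseline_means(act1)
  act2 <- compute_activation(compute_envelope(emg2, fs), sw, baseline = bl)
  expect_equal(act2$a, 2.5 * act1$a, tolerance = 1e-9)
  expect_equal(act2$A, 2.5 * act1$A, tolerance = 1e-9)
})

test_that("gain ratios between conditions are recovered exactly for identical seeds", {
  # identical seeds share carrier and stride schedule; only gains differ, and
  # the whole envelope pipeline is positively homogeneous per channel
  prof <- make_profile(slope = rep(0.05, 7))
  t0 <- generate_trial(prof, "incline", grade = 0, duration = 90, seed = 4)
  t24 <- generate_trial(prof, "incline", grade = 24, duration = 90, seed = 4)
  fs <- t0$sampling_rate
  n_win <- 20 * fs
  analyze <- function(tr, bl = NULL) {
    sw <- detect_strides(tr$grf$fz_n[1:n_win], fs)
    compute_activation(compute_envelope(tr$emg[1:n_win, ], fs), sw,
                       baseline = bl)
  }
  a0 <- analyze(t0)
  a24 <- analyze(t24, bl = a0)
  means <- tapply(a24$A, a24$muscle, mean)
  expect_equal(as.numeric(means[muscle_channels()]), rep(2.2, 7),
               tolerance = 1e-8)
})

test_that("insufficient strides and degenerate baselines fail loudly", {
  fs <- 2000
  fz <- make_halfsine_grf(c(0.5, 1.6, 2.7), fs = fs, total_s = 4)
  sw <- detect_strides(fz, fs)
  env <- constant_envelopes(1, length(fz), fs)
  expect_error(compute_activation(env, sw, n_strides = 5),
               class = "gaitccp_error_strides")
  fz5 <- make_halfsine_grf(seq(0.5, by = 1.1, length.out = 7), fs = fs,
                           total_s = 9)
  sw5 <- detect_strides(fz5, fs)
  env5 <- constant_envelopes(1, length(fz5), fs)
  zero_bl <- stats::setNames(c(0, rep(1, 6)), muscle_channels())
  expect_error(compute_activation(env5, sw5, baseline = zero_bl),
               class = "gaitccp_error_data", regexp = "degenerate")
})

test_that("excluded channels propagate as missing and costs refuse them", {
  fs <- 2000
  fz <- make_halfsine_grf(seq(0.5, by = 1.1, length.out = 7), fs = fs,
                          total_s = 9)
  sw <- detect_strides(fz, fs)
  env <- constant_envelopes(1, length(fz), fs)
  act <- compute_activation(env, sw, excluded_channels = "VM")
  expect_false("VM" %in% as.character(act$muscle))
  expect_error(generic_cost(act), class = "gaitccp_error_data",
               regexp = "incomplete")
})
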