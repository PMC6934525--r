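# Knee-angle geometry, raise-cycle segmentation and the per-phase feature
# computations.

make_frames <- function(t, hip, knee_l, ankle_l, knee_r = knee_l,
                        ankle_r = ankle_l) {
  n <- length(t)
  rep3 <- function(p) matrix(p, n, 3, byrow = TRUE)
  tibble::tibble(
    t = t,
    hip_center_x = rep3(hip)[, 1], hip_center_y = rep3(hip)[, 2],
    hip_center_z = rep3(hip)[, 3],
    left_knee_x = rep3(knee_l)[, 1], left_knee_y = rep3(knee_l)[, 2],
    left_knee_z = rep3(knee_l)[, 3],
    right_knee_x = rep3(knee_r)[, 1], right_knee_y = rep3(knee_r)[, 2],
    right_knee_z = rep3(knee_r)[, 3],
    left_ankle_x = rep3(ankle_l)[, 1], left_ankle_y = rep3(ankle_l)[, 2],
    left_ankle_z = rep3(ankle_l)[, 3],
    right_ankle_x = rep3(ankle_r)[, 1], right_ankle_y = rep3(ankle_r)[, 2],
    right_ankle_z = rep3(ankle_r)[, 3]
  )
}

test_that("knee_angle reproduces hand-computed geometries", {
  expect_equal(knee_angle(c(0, 1, 0), c(0, 0, 0), c(0, -1, 0)), pi)
  expect_equal(knee_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0)), pi / 2)
  expect_equal(knee_angle(c(0, 1, 0), c(0, 0, 0), c(1, -1, 0)), 3 * pi / 4,
               tolerance = 1e-12)
  expect_error(knee_angle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)),
               class = "dualgait_geometry_error")
})

test_that("knee_angle is invariant under rigid motions", {
  set.seed(21)
  for (i in 1:50) {
    hip <- rnorm(3); knee <- rnorm(3); ankle <- rnorm(3)
    a0 <- knee_angle(hip, knee, ankle)
    R <- random_rotation(); tr <- rnorm(3, sd = 5)
    a1 <- knee_angle(as.vector(R %*% hip + tr), as.vector(R %*% knee + tr),
                     as.vector(R %*% ankle + tr))
    expect_equal(a1, a0, tolerance = 1e-9)
  }
})

test_that("knee_angle_series recovers the simulator's ground-truth trace", {
  cfg <- noiseless_config(n_subjects = 2L)
  subj <- sample_subjects(cfg, 31L)[1, ]
  set.seed(31)
  sess <- simulate_trial(subj, 1L, cfg)
  ph <- sess$phases$physical
  for (side in c("left", "right")) {
    ser <- knee_angle_series(ph$frames, side)
    gt <- ph$ground_truth$angle[[side]]
    expect_equal(ser$t, gt$t)
    expect_equal(ser$angle, gt$angle, tolerance = 1e-9)
  }
  expect_error(knee_angle_series(ph$frames[1, ], "left"),
               class = "dualgait_validation_error")
})

test_that("a motionless straight leg gives a constant series and no cycles", {
  fr <- make_frames(seq(0, 3, 1 / 30), c(0, 1, 0), c(0, 0, 0), c(0, -1, 0))
  ser <- knee_angle_series(fr, "left")
  expect_true(all(abs(ser$angle - pi) < 1e-12))
  expect_equal(nrow(detect_raise_cycles(ser)), 0L)
})

test_that("raise-cycle detection recovers a closed-form waveform", {
  t <- seq(0, 5, 1 / 30)
  ser <- tibble::tibble(t = t, angle = 2.6 - 0.6 * pmax(0, sin(2 * pi * t)))
  cyc <- detect_raise_cycles(ser)
  expect_equal(nrow(cyc), 5L)
  expect_equal(cyc$amplitude, rep(0.6, 5), tolerance = 0.02)
  expect_true(all(diff(cyc$valley_t) > 0))
  expect_true(all(cyc$peak_t < cyc$valley_t))
  # time reversal finds the same number of cycles
  rev_ser <- tibble::tibble(t = t, angle = rev(ser$angle))
  expect_equal(nrow(detect_raise_cycles(rev_ser)), 5L)
})

test_that("detection finds exactly the scheduled simulator raises", {
  cfg <- noiseless_config(n_subjects = 2L)
  subj <- sample_subjects(cfg, 32L)[1, ]
  set.seed(32)
  sess <- simulate_trial(subj, 1L, cfg)
  ph <- sess$phases$physical
  for (side in c("left", "right")) {
    cyc <- detect_raise_cycles(knee_angle_series(ph$frames, side))
    k <- sum(ph$ground_truth$raises$foot == side)
    expect_equal(nrow(cyc), k)
  }
})

test_that("amplitude statistics match hand arithmetic and the generator", {
  expect_equal(knee_amplitude_stats(tibble::tibble(amplitude = 0.8)),
               list(mean = 0.8, sd = 0))
  expect_equal(knee_amplitude_stats(tibble::tibble(amplitude = c(0.5, 0.7))),
               list(mean = 0.6, sd = 0.1))
  expect_error(knee_amplitude_stats(tibble::tibble(amplitude = double())),
               class = "dualgait_missing_feature")

  # Monte-Carlo against the generator's configured amplitude distribution
  cfg <- cohort_config(amp_ref = 0.6, amp_slope = 0, amp_subject_sd = 0,
                       amp_cycle_sd = 0.05, position_noise_m = 0,
                       step_jitter = 0, step_jitter_subject_sdlog = 0,
                       step_interval_subject_sd = 0)
  subj <- sample_subjects(cfg, 33L)[1, ]
  set.seed(33)
  amps <- c()
  for (tr in 1:4) {
    sess <- simulate_trial(subj, tr, cfg)
    for (side in c("left", "right")) {
      cyc <- detect_raise_cycles(
        knee_angle_series(sess$phases$physical$frames, side))
      amps <- c(amps, cyc$amplitude)
    }
  }
  expect_gt(length(amps), 100)
  expect_lt(abs(mean(amps) - 0.6), 3 * 0.05 / sqrt(length(amps)) + 0.005)
})

test_that("step intervals use alternating-foot pairs only", {
  ev <- tibble::tibble(t = c(0, 0.5, 1), foot = c("left", "right", "left"))
  expect_equal(step_interval_stats(ev), list(mean = 0.5, sd = 0),
               ignore_attr = TRUE)
  ev2 <- tibble::tibble(t = c(0, 0.4, 1), foot = c("left", "right", "left"))
  expect_equal(step_interval_stats(ev2), list(mean = 0.5, sd = 0.1),
               ignore_attr = TRUE)
  # a same-foot pair is skipped, not counted
  ev3 <- tibble::tibble(t = c(0, 0.4, 1), foot = c("left", "left", "right"))
  s3 <- step_interval_stats(ev3)
  expect_equal(s3$mean, 0.6)
  expect_equal(attr(s3, "n_skipped"), 1L)
  expect_error(step_interval_stats(ev[1, ]),
               class = "dualgait_missing_feature")
})

test_that("answer statistics cover rate, timing and the binomial regime", {
  resp <- tibble::tibble(is_correct = c(TRUE, TRUE, TRUE, FALSE),
                         response_time = rep(1, 4))
  expect_equal(answer_stats(resp), list(rate = 0.75, mean_time = 1))
  expect_equal(answer_stats(tibble::tibble(is_correct = rep(TRUE, 5),
                                           response_time = 1:5))$rate, 1)
  expect_error(answer_stats(tibble::tibble(is_correct = logical(),
                                           response_time = double())),
               class = "dualgait_missing_feature")
  set.seed(35)
  draws <- rbinom(500, 1, 0.8) == 1
  mc <- answer_stats(tibble::tibble(is_correct = draws,
                                    response_time = rep(1, 500)))
  expect_identical(mc$rate, mean(draws))  # rate is exactly correct/total
  expect_lt(abs(mc$rate - 0.8), 3 * sqrt(0.8 * 0.2 / 500))
})

test_that("a noiseless session yields exact features and zero dispersions", {
  cfg <- noiseless_config(n_subjects = 2L)
  subj <- sample_subjects(cfg, 35L)[1, ]
  set.seed(35)
  sess <- simulate_trial(subj, 1L, cfg)
  f <- extract_features(sess)
  # dispersions vanish (up to double rounding of the timestamp arithmetic)
  expect_lt(f$step_interval_sd_single, 1e-12)
  expect_lt(f$step_interval_sd_dual, 1e-12)
  expect_lt(f$knee_amplitude_sd_single, 1e-12)
  expect_lt(f$knee_amplitude_sd_dual, 1e-12)
  expect_equal(f$step_interval_mean_single, 0.6)
  expect_equal(f$answer_rate_single, 1)
  # zero dual-task cost: the dual phase reproduces the single-task features
  for (base in feature_base_names()) {
    expect_equal(f[[paste0(base, "_dual")]], f[[paste0(base, "_single")]],
                 tolerance = 1e-9)
  }
})

test_that("a session without a dual phase is rejected", {
  cfg <- noiseless_config(n_subjects = 2L)
  subj <- sample_subjects(cfg, 36L)[1, ]
  set.seed(36)
  sess <- simulate_trial(subj, 1L, cfg)
  sess$phases$dual <- NULL
  expect_error(extract_features(sess), class = "dualgait_validation_error")
})
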