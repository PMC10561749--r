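# Gait-event detection from the skeleton and from foot IMU angular
# velocity, and stride pairing.

# skeleton whose ankle-minus-pelvis AP coordinate is a pure sinusoid
sine_skeleton <- function(T = 1.2, dur = 12, rate = 30) {
  ts <- seq(0, dur, by = 1 / rate)
  n <- length(ts)
  zero <- matrix(0, n, 3)
  ank <- cbind(rep(0.1, n), rep(0.08, n), sin(2 * pi * ts / T))
  skeleton_sequence(ts, list(PELVIS = zero, ANKLE_R = ank,
                             ANKLE_L = zero), rate_hz = rate)
}

test_that("sinusoidal relative AP coordinate yields extrema as IC/TO", {
  skel <- sine_skeleton()
  w <- select_window(c(0, 12), 12)
  ev <- detect_events_kinematic(skel, w, sides = "RIGHT")
  ic <- ev$time[ev$kind == "IC"]
  to <- ev$time[ev$kind == "TO"]
  exp_ic <- seq(0.3, 12, by = 1.2)
  exp_to <- seq(0.9, 12, by = 1.2)
  acc_ic <- event_accuracy(ic, exp_ic[exp_ic > 0.3 & exp_ic < 11.7], 1 / 30)
  acc_to <- event_accuracy(to, exp_to[exp_to > 0.3 & exp_to < 11.7], 1 / 30)
  expect_equal(acc_ic$sensitivity, 1)
  expect_equal(acc_to$sensitivity, 1)
})

test_that("standing (constant coordinate) raises insufficient-cycles errors", {
  ts <- seq(0, 12, by = 1 / 30)
  n <- length(ts)
  zero <- matrix(0, n, 3)
  skel <- skeleton_sequence(ts, list(PELVIS = zero, ANKLE_R = zero,
                                     ANKLE_L = zero))
  w <- select_window(c(0, 12), 12)
  expect_error(detect_events_kinematic(skel, w), "insufficient gait cycles")

  tsi <- seq(0, 12, by = 1 / 128)
  quiet <- imu_recording("FOOT_R", tsi, matrix(0, length(tsi), 3),
                         matrix(0, length(tsi), 3))
  expect_error(detect_events_imu(quiet, w), "insufficient gait cycles")
})

test_that("noise-free trials are segmented perfectly by both detectors", {
  res <- nf_analysis()
  tr <- res$trial; an <- res$analysis
  tol <- c(KINEMATIC = 1 / 30, IMU = 1 / 128)
  for (src in c("KINEMATIC", "IMU")) {
    for (sd in c("LEFT", "RIGHT")) {
      det <- an$events$time[an$events$source == src &
                              an$events$side == sd &
                              an$events$kind == "IC"]
      tru <- interior_truth_ic(tr, an, sd)
      acc <- event_accuracy(det, tru, tol[[src]])
      expect_equal(acc$sensitivity, 1)
      expect_true(all(abs(acc$errors) <= tol[[src]]))
    }
  }
})

test_that("a mirrored gyro mounting with a declared sign gives identical events", {
  res <- nf_analysis()
  tr <- res$trial
  w <- res$analysis$window
  foot <- filter_imu(tr$imus$FOOT_R)
  ev1 <- detect_events_imu(foot, w)
  flipped <- foot
  flipped$gyro <- -flipped$gyro
  ev2 <- detect_events_imu(flipped, w, ml_sign = -1)
  expect_equal(ev1$time, ev2$time)
  expect_identical(ev1$kind, ev2$kind)
})

test_that("invalid axis maps and non-foot sites are configuration errors", {
  res <- nf_analysis()
  foot <- res$trial$imus$FOOT_R
  expect_error(detect_events_imu(foot, res$analysis$window, ml_axis = 5),
               "axis mapping")
  expect_error(detect_events_imu(res$trial$imus$WRIST_L,
                                 res$analysis$window),
               "foot-mounted")
})

test_that("event alternation holds on noisy detections", {
  for (seed in 1:3) {
    tr <- simulate_trial(gait_profile(), duration_walk = 30, seed = seed)
    skel <- filter_skeleton(tr$skeleton)
    w <- select_window(trim_nonwalking(tr$belt), 25)
    ev_k <- detect_events_kinematic(skel, w)
    ev_i <- detect_events_imu(filter_imu(tr$imus$FOOT_L), w)
    expect_true(validate_alternation(ev_k))
    expect_true(validate_alternation(ev_i))
  }
})

test_that("stride pairing follows the IC-to-IC contract", {
  ev <- gait_events(c(0.3, 0.9, 1.5, 2.1, 2.7),
                    "RIGHT", c("IC", "TO", "IC", "TO", "IC"), "KINEMATIC")
  st <- pair_strides(ev)
  expect_equal(nrow(st), 2)
  expect_equal(st$ic_time, c(0.3, 1.5))
  expect_equal(st$to_time, c(0.9, 2.1))
  expect_true(all(st$complete))

  # single IC: no strides
  one <- gait_events(0.3, "RIGHT", "IC", "KINEMATIC")
  expect_equal(nrow(pair_strides(one)), 0)

  # missing TO: stride flagged but kept for time/length
  ev2 <- gait_events(c(0.3, 1.5, 2.1, 2.7),
                     "RIGHT", c("IC", "IC", "TO", "IC"), "KINEMATIC")
  st2 <- pair_strides(ev2)
  expect_equal(nrow(st2), 2)
  expect_false(st2$complete[1])
  expect_true(is.na(st2$to_time[1]))
  expect_equal(st2$stride_time, c(1.2, 1.2))
})
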