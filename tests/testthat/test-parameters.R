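# Gait parameters: belt translation, stride time/length (both modalities),
# support times, cadence, step width, margin of stability, arm swing.

test_that("belt translation integrates the speed log", {
  ts <- seq(0, 10, by = 1 / 64)
  belt_const <- treadmill_log(ts, rep(1, length(ts)))
  expect_equal(belt_translation(belt_const, 0, 1.2), 1.2, tolerance = 1e-9)
  expect_equal(belt_translation(belt_const, 3, 3), 0)
  expect_error(belt_translation(belt_const, -1, 2), "outside")

  ramp <- treadmill_log(ts, pmin(ts / 2, 1) * ifelse(ts <= 2, 1, 1))
  expect_equal(belt_translation(ramp, 0, 2), 1.0, tolerance = 1e-9)
})

test_that("stride time recovers the simulated mean and dispersion", {
  res <- nf_analysis(stride_time = 1.1)
  st <- res$analysis$stride_table
  for (src in c("KINEMATIC", "IMU")) {
    m <- mean(st$stride_time[st$source == src])
    expect_lt(abs(m - 1.1), (1 / 30) / sqrt(100))
  }

  # jittered: per-stride SD matches the generator's recorded jitter
  trj <- simulate_trial(nf_profile(stride_time = 1.1, stride_cv = 0.03),
                        duration_walk = 126, seed = 9)
  anj <- analyze_trial(trj$skeleton, trj$imus, trj$belt)
  stj <- anj$stride_table
  sd_true <- sd(trj$truth$stride_times)
  sd_det <- sd(stj$stride_time[stj$source == "IMU" & stj$side == "RIGHT"])
  expect_lt(abs(sd_det - sd_true), 0.2 * sd_true)
})

test_that("kinematic stride length is ankle displacement plus belt term", {
  # stationary ankle at both ICs: pure belt term
  ts <- seq(0, 10, by = 1 / 30)
  n <- length(ts)
  zero <- matrix(0, n, 3)
  ank <- cbind(rep(0.1, n), rep(0.08, n), rep(0.35, n))
  skel <- skeleton_sequence(ts, list(PELVIS = zero, ANKLE_R = ank,
                                     ANKLE_L = zero))
  belt <- treadmill_log(seq(0, 10, by = 1 / 64),
                        rep(1, length(seq(0, 10, by = 1 / 64))))
  st <- data.frame(source = "KINEMATIC", side = "RIGHT", ic_time = 2,
                   next_ic_time = 3.2, stride_time = 1.2, to_time = 2.7,
                   contra_to = NA, contra_ic = NA, complete = TRUE)
  expect_equal(stride_length_kinematic(skel, st, belt), 1.2,
               tolerance = 1e-9)

  # anterior ankle drift adds to the belt term
  ank2 <- ank; ank2[, 3] <- 0.35 + 0.02 * (ts >= 3)
  skel2 <- skeleton_sequence(ts, list(PELVIS = zero, ANKLE_R = ank2,
                                      ANKLE_L = zero))
  st2 <- st; st2$next_ic_time <- 3.5
  expect_equal(stride_length_kinematic(skel2, st2, belt),
               1.5 + 0.02, tolerance = 1e-9)
})

test_that("double integration reproduces constant-acceleration displacement", {
  ts <- seq(-0.5, 1.5, by = 1 / 128)
  n <- length(ts)
  foot <- imu_recording("FOOT_R", ts,
                        cbind(rep(0, n), rep(0, n), rep(2, n)),
                        matrix(0, n, 3))
  belt <- treadmill_log(seq(-0.5, 1.5, by = 1 / 64),
                        rep(0, length(seq(-0.5, 1.5, by = 1 / 64))))
  st <- data.frame(source = "IMU", side = "RIGHT", ic_time = -0.2,
                   next_ic_time = 1, stride_time = 1.2, to_time = 0,
                   contra_to = NA, contra_ic = NA, complete = TRUE)
  d <- stride_length_imu(foot, st, belt, dedrift = FALSE)
  expect_equal(d, 1.0, tolerance = 1e-6) # a t^2 / 2 with v_TO = 0
})

test_that("dedrifting removes injected accelerometer bias", {
  res <- nf_analysis()
  tr <- res$trial
  an <- res$analysis
  st_imu <- an$stride_table[an$stride_table$source == "IMU" &
                              an$stride_table$side == "RIGHT", ]
  foot <- filter_imu(tr$imus$FOOT_R)
  foot$accel[, 3] <- foot$accel[, 3] + 0.05
  strides <- data.frame(source = "IMU", side = "RIGHT",
                        ic_time = st_imu$ic_time,
                        next_ic_time = st_imu$ic_time + st_imu$stride_time,
                        stride_time = st_imu$stride_time,
                        to_time = st_imu$ic_time +
                          0.6 * st_imu$stride_time,
                        contra_to = NA, contra_ic = NA, complete = TRUE)
  foot_clean <- filter_imu(tr$imus$FOOT_R)
  len_on <- stride_length_imu(foot, strides, tr$belt, dedrift = TRUE)
  len_off <- stride_length_imu(foot, strides, tr$belt, dedrift = FALSE)
  len_base <- stride_length_imu(foot_clean, strides, tr$belt,
                                dedrift = FALSE)
  true_len <- 1.2
  err_on <- abs(mean(len_on) - true_len)
  expect_lt(err_on, 0.02)
  expect_lt(err_on, abs(mean(len_off) - true_len))
  # relative to the bias-free baseline, the un-dedrifted error is the bias
  # integrated twice over the swing: b S^2 / 2
  swing <- 0.4 * 1.2
  expect_lt(abs((mean(len_off) - mean(len_base)) - 0.05 * swing^2 / 2),
            0.3 * 0.05 * swing^2 / 2)
})

test_that("support times follow the duty-factor closed forms", {
  # detected (IMU) events, duty 0.6, T = 1.2 s
  res <- nf_analysis()
  st <- res$analysis$stride_table
  imu <- st[st$source == "IMU", ]
  expect_lt(abs(mean(imu$single_support, na.rm = TRUE) - 0.4 * 1.2), 1 / 30)
  expect_lt(abs(mean(imu$double_support, na.rm = TRUE) - 0.2 * 1.2), 1 / 30)

  # ground-truth events, duty exactly 0.5: double support vanishes
  tr <- simulate_trial(nf_profile(duty_factor = 0.5, stride_time = 1.0),
                       duration_walk = 20, seed = 2)
  su <- support_times(pair_strides(truth_events(tr)))
  expect_lt(abs(mean(su$single_support, na.rm = TRUE) - 0.5), 1e-6)
  expect_lt(abs(mean(su$double_support, na.rm = TRUE)), 1e-6)

  # left-only events: absent fields, no crash
  ev <- gait_events(c(0.3, 0.9, 1.5, 2.1, 2.7), "LEFT",
                    c("IC", "TO", "IC", "TO", "IC"), "IMU")
  su2 <- support_times(pair_strides(ev))
  expect_true(all(is.na(su2$single_support)))
})

test_that("cadence counts bilateral initial contacts per minute", {
  times <- seq(0.25, 59.9, by = 0.5)[1:120]
  ev <- gait_events(times, rep(c("LEFT", "RIGHT"), 60), "IC", "IMU")
  w <- select_window(c(0, 60), 60)
  expect_equal(cadence(ev, w), 120)

  res <- nf_analysis()
  expect_true(all(abs(res$analysis$summary$cadence_spm - 100) <= 1))

  empty <- gait_events(numeric(0), character(0), character(0),
                       character(0))
  expect_error(cadence(empty, w), "insufficient gait cycles")
})

test_that("step width is the ML ankle separation at initial contact", {
  ts <- seq(0, 4, by = 1 / 30)
  n <- length(ts)
  mk <- function(x) cbind(rep(x, n), rep(0.08, n), rep(0, n))
  skel <- skeleton_sequence(ts, list(PELVIS = mk(0), ANKLE_L = mk(-0.06),
                                     ANKLE_R = mk(0.06)))
  ev <- gait_events(c(1, 1.5, 2), c("RIGHT", "LEFT", "RIGHT"), "IC",
                    "KINEMATIC")
  sw <- step_width(skel, ev)
  expect_equal(sw$step_width, rep(0.12, 3))

  # simulated recovery at default step width
  res <- nf_analysis()
  expect_lt(abs(res$analysis$summary$step_width_m[1] - 0.12), 0.005)

  # single side only: empty result
  ev_l <- gait_events(1, "LEFT", "IC", "KINEMATIC")
  expect_equal(nrow(step_width(skel, ev_l)), 0)
})

test_that("margin of stability reduces to geometry at zero CoM velocity", {
  ts <- seq(0, 2, by = 1 / 30)
  n <- length(ts)
  mk <- function(x, y, z) cbind(rep(x, n), rep(y, n), rep(z, n))
  skel <- skeleton_sequence(ts, list(
    PELVIS = mk(0, 0.9, 0), ANKLE_R = mk(0.10, 0.08, 0.3),
    ANKLE_L = mk(-0.10, 0.08, 0), FOOT_R = mk(0.10, 0.05, 0.48)))
  ev <- gait_events(1, "RIGHT", "IC", "KINEMATIC")
  m <- margin_of_stability(skel, ev, mos_params(0.981))
  expect_equal(m$mos_ml, 0.10)
  expect_equal(m$mos_ap, 0.48)
})

test_that("the velocity offset v / omega0 matches the hand computation", {
  # l = 0.981 m -> omega0 = 3.1623 1/s; v = 0.31623 m/s toward the foot
  ts <- seq(0, 2, by = 1 / 30)
  n <- length(ts)
  pel <- cbind(0.31623 * ts, rep(0.9, n), rep(0, n))
  ank <- cbind(rep(0.31623 + 0.10, n), rep(0.08, n), rep(0.3, n))
  skel <- skeleton_sequence(ts, list(PELVIS = pel, ANKLE_R = ank,
                                     ANKLE_L = ank))
  ev <- gait_events(1, "RIGHT", "IC", "KINEMATIC")
  m <- margin_of_stability(skel, ev, mos_params(0.981))
  expect_lt(abs(m$mos_ml - (0.10 - 0.31623 / sqrt(9.81 / 0.981))), 1e-6)
  expect_lt(abs(m$mos_ml), 1e-5)
})

test_that("MoS from a noisy skeleton tracks the true-CoM oracle", {
  p <- gait_profile(noise_skeleton_m = 0.003, noise_wrist_m = 0.003,
                    noise_accel = 0, noise_gyro = 0)
  tr <- simulate_trial(p, duration_walk = 126, seed = 31)
  tr0 <- simulate_trial(noise_free(p), duration_walk = 126, seed = 31)
  ev <- truth_events(tr)
  w <- select_window(c(tr$truth$walk_start, tr$truth$walk_end), 120)
  ev <- ev[in_window(ev$time, w), ]
  params <- mos_params(0.9)
  skel_noisy <- filter_skeleton(tr$skeleton)
  m_noisy <- margin_of_stability(skel_noisy, ev, params)
  # oracle: identical base of support, CoM replaced by the true trajectory
  skel_oracle <- skel_noisy
  skel_oracle$joints$PELVIS <- tr0$truth$com[, c("x", "y", "z")]
  m_true <- margin_of_stability(skel_oracle, ev, params)
  expect_lt(abs(mean(m_noisy$mos_ml) - mean(m_true$mos_ml)), 0.01)
  expect_lt(abs(mean(m_noisy$mos_ap) - mean(m_true$mos_ap)), 0.01)
})

test_that("gyro arm swing integrates to the analytic amplitude", {
  T <- 1.1
  ts <- seq(0, 30, by = 1 / 128)
  A <- 15 * pi / 180
  gyro <- cbind(A * (2 * pi / T) * cos(2 * pi * ts / T), 0 * ts, 0 * ts)
  wrist <- imu_recording("WRIST_L", ts, matrix(0, length(ts), 3), gyro)
  w <- select_window(c(0, 30), 30)
  amps <- arm_swing_imu(wrist, w)
  expect_lt(abs(mean(amps) - 30), 0.5)

  quiet <- imu_recording("WRIST_L", ts, matrix(0, length(ts), 3),
                         matrix(0, length(ts), 3))
  expect_equal(arm_swing_imu(quiet, w), 0)
})

test_that("arm swing recovery from the simulator ground truth", {
  res <- nf_analysis()
  s <- res$analysis$summary
  expect_lt(abs(s$arm_swing_l_deg[s$source == "IMU"] - 40), 1)
  expect_lt(abs(s$arm_swing_r_deg[s$source == "IMU"] - 40), 1)
})

test_that("cosine-theorem arm swing matches constructed geometries", {
  mk_arm_skel <- function(A_deg, T = 1.1, dur = 20, r = 1) {
    ts <- seq(0, dur, by = 1 / 30)
    n <- length(ts)
    alpha <- (A_deg / 2) * pi / 180 * sin(2 * pi * ts / T)
    sh <- cbind(rep(0.18, n), rep(1.45, n), rep(0, n))
    wr <- sh + r * cbind(rep(0, n), -cos(alpha), sin(alpha))
    skeleton_sequence(ts, list(PELVIS = sh * 0, SHOULDER_R = sh,
                               WRIST_R = wr, ANKLE_L = sh * 0,
                               ANKLE_R = sh * 0))
  }
  w <- select_window(c(0, 20), 20)
  out <- arm_swing_kinematic(mk_arm_skel(90), w, sides = "RIGHT")
  expect_lt(abs(mean(out$amplitude_deg) - 90), 1)
  # chord equal to the diameter: degenerate 180-degree swing
  out2 <- arm_swing_kinematic(mk_arm_skel(180), w, sides = "RIGHT")
  expect_lt(abs(mean(out2$amplitude_deg) - 180), 1)
})

test_that("wrist noise inflates the cosine-theorem amplitude as predicted", {
  p <- gait_profile(arm_length = 0.6, noise_skeleton_m = 0,
                    noise_wrist_m = 0.025, noise_accel = 0, noise_gyro = 0)
  tr <- simulate_trial(p, duration_walk = 126, seed = 17)
  skel <- filter_skeleton(tr$skeleton)
  w <- select_window(c(tr$truth$walk_start, tr$truth$walk_end), 120)
  out <- arm_swing_kinematic(skel, w)
  measured <- mean(out$amplitude_deg)

  # Monte-Carlo oracle: chord inflation under isotropic Gaussian noise at
  # the effective (filtered) noise level
  set.seed(99)
  noise <- matrix(rnorm(3 * 4000, sd = 0.025), ncol = 3)
  noise_f <- apply(noise, 2, butterworth_lowpass,
                   spec = skeleton_filter_default(), rate_hz = 30)
  sigma_eff <- mean(apply(noise_f[500:3500, ], 2, sd))
  r <- 0.6
  half <- 20 * pi / 180
  p1 <- r * c(0, -cos(half), sin(half))
  p2 <- r * c(0, -cos(half), -sin(half))
  draws <- vapply(seq_len(20000), function(i) {
    cc <- sqrt(sum((p1 - p2 + rnorm(3, sd = sigma_eff * sqrt(2)))^2))
    cc <- min(cc, 2 * r)
    acos((2 * r^2 - cc^2) / (2 * r^2)) * 180 / pi
  }, numeric(1))
  oracle <- mean(draws)
  expect_gte(measured, 39.5) # bias is upward
  expect_lt(abs(measured - oracle), 2)
})

test_that("window summaries pool sides and keep arm swing per side", {
  st <- data.frame(source = "KINEMATIC", side = c("LEFT", "RIGHT"),
                   ic_time = c(1, 1.5), stride_time = c(1.1, 1.3),
                   stride_length = c(1.1, 1.2),
                   single_support = NA_real_, double_support = NA_real_,
                   step_width = NA_real_, mos_ml = NA_real_,
                   mos_ap = NA_real_)
  w <- select_window(c(0, 60), 60)
  s <- summarize_window(st, w, "P1", "KINEMATIC",
                        arm_swing = list(LEFT = c(30, 32), RIGHT = 40))
  expect_equal(s$stride_time_s, 1.2)
  expect_equal(s$arm_swing_l_deg, 31)
  expect_equal(s$arm_swing_r_deg, 40)
  expect_equal(s$n_strides, 2L)

  empty <- st[0, ]
  expect_error(summarize_window(empty, w, "P1", "KINEMATIC"),
               "no strides")
})
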