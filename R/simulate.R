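# Synthetic treadmill-gait generator with analytic ground truth.
#
# The walker is a kinematic stick model on a treadmill, described in the
# canonical camera/world frame (X right, Y up, Z anterior):
#   * stance foot rides the belt: camera-frame AP velocity = -v_belt(t);
#   * swing foot returns anteriorly along a quintic profile whose boundary
#     conditions are position/velocity/acceleration matched to the belt at
#     toe-off and land the ankle at a fixed home station with zero
#     camera-frame velocity at initial contact (heel-strike impact: the
#     velocity jump to -v_belt happens on the stance side of the boundary,
#     so the AP maximum of the ankle track coincides with the true IC);
#   * the pelvis midpoint (centre-of-mass proxy) oscillates mediolaterally
#     at stride frequency and vertically at twice stride frequency;
#   * wrists swing about fixed shoulder points in the sagittal plane,
#     anti-phase to the ipsilateral leg;
#   * the foot pitch rate is a stylized stance-flat / swing-peaked waveform
#     with a dominant positive mid-swing peak and sharp negative dips at
#     toe-off and initial contact.
# IMU channels are analytic time derivatives of these trajectories
# (world-aligned, gravity-free, i.e. the IDEALIZED sensor mode), sampled at
# 128 Hz; the skeleton at 30 Hz; the belt log at 64 Hz.

#' Gait profile for the synthetic walker
#'
#' Defaults describe a typical older adult walking at a comfortable
#' treadmill speed; measurement-noise defaults reflect reported device
#' accuracy (about 3 mm for most depth-camera joints, about 25 mm for the
#' wrists).
#'
#' @param belt_speed Target belt speed, m/s.
#' @param stride_time Mean stride duration, s.
#' @param stride_cv Coefficient of variation of stride time (unitless).
#' @param duty_factor Stance fraction of the stride (0-1).
#' @param step_width Mediolateral ankle separation, m.
#' @param leg_length Leg length, m (pendulum length, pelvis height).
#' @param pelvis_sway_ml ML pelvis sway amplitude, m.
#' @param pelvis_bounce_v Vertical pelvis bounce amplitude, m.
#' @param arm_swing_deg_l,arm_swing_deg_r Peak-to-peak arm swing, degrees.
#' @param arm_length Shoulder-to-wrist distance, m.
#' @param foot_clearance Swing foot lift, m.
#' @param noise_skeleton_m Gaussian SD of skeleton joint noise, m.
#' @param noise_wrist_m Wrist-specific skeleton noise SD, m.
#' @param noise_accel IMU accelerometer noise SD, m/s^2.
#' @param noise_gyro IMU gyroscope noise SD, rad/s.
#' @param phase_lr Left-right phase offset in strides (0.5 = symmetric).
#' @return An object of class `gait_profile`.
#' @export
gait_profile <- function(belt_speed = 1.05, stride_time = 1.1,
                         stride_cv = 0.02, duty_factor = 0.60,
                         step_width = 0.12, leg_length = 0.9,
                         pelvis_sway_ml = 0.03, pelvis_bounce_v = 0.015,
                         arm_swing_deg_l = 40, arm_swing_deg_r = 40,
                         arm_length = 0.6, foot_clearance = 0.05,
                         noise_skeleton_m = 0.003, noise_wrist_m = 0.025,
                         noise_accel = 0.05, noise_gyro = 0.01,
                         phase_lr = 0.5) {
  p <- list(belt_speed = belt_speed, stride_time = stride_time,
            stride_cv = stride_cv, duty_factor = duty_factor,
            step_width = step_width, leg_length = leg_length,
            pelvis_sway_ml = pelvis_sway_ml, pelvis_bounce_v = pelvis_bounce_v,
            arm_swing_deg_l = arm_swing_deg_l,
            arm_swing_deg_r = arm_swing_deg_r,
            arm_length = arm_length, foot_clearance = foot_clearance,
            noise_skeleton_m = noise_skeleton_m, noise_wrist_m = noise_wrist_m,
            noise_accel = noise_accel, noise_gyro = noise_gyro,
            phase_lr = phase_lr)
  stopifnot(p$stride_time > 0, p$belt_speed > 0,
            p$duty_factor > 0, p$duty_factor < 1,
            p$stride_cv >= 0, p$step_width >= 0, p$leg_length > 0,
            p$arm_length > 0, p$foot_clearance >= 0,
            p$noise_skeleton_m >= 0, p$noise_wrist_m >= 0,
            p$noise_accel >= 0, p$noise_gyro >= 0)
  structure(p, class = "gait_profile")
}

#' A noise-free copy of a gait profile
#'
#' @param profile A [gait_profile()].
#' @return The profile with all measurement-noise SDs set to zero.
#' @export
noise_free <- function(profile) {
  profile$noise_skeleton_m <- 0
  profile$noise_wrist_m <- 0
  profile$noise_accel <- 0
  profile$noise_gyro <- 0
  profile
}

# quintic boundary-condition matrix in normalized time tau in [0, 1]:
# rows = pos/vel/acc at 0, pos/vel/acc at 1 (derivatives scaled by S, S^2)
QUINTIC_M <- matrix(c(
  1, 0, 0, 0, 0, 0,
  0, 1, 0, 0, 0, 0,
  0, 0, 2, 0, 0, 0,
  1, 1, 1, 1, 1, 1,
  0, 1, 2, 3, 4, 5,
  0, 0, 2, 6, 12, 20
), nrow = 6, byrow = TRUE)

# analytic belt model: standing, linear ramp, steady, abrupt stop
belt_model <- function(v_target, t1, t2, t3) {
  ramp <- t2 - t1
  v <- function(t) {
    out <- numeric(length(t))
    i <- t >= t1 & t < t2
    out[i] <- v_target * (t[i] - t1) / ramp
    out[t >= t2 & t < t3] <- v_target
    out
  }
  B2 <- v_target * ramp / 2
  B <- function(t) {
    out <- numeric(length(t))
    i <- t >= t1 & t < t2
    out[i] <- v_target * (t[i] - t1)^2 / (2 * ramp)
    i <- t >= t2 & t < t3
    out[i] <- B2 + v_target * (t[i] - t2)
    out[t >= t3] <- B2 + v_target * (t3 - t2)
    out
  }
  vdot <- function(t) {
    out <- numeric(length(t))
    out[t >= t1 & t < t2] <- v_target / ramp
    out
  }
  list(v = v, B = B, vdot = vdot, v_target = v_target,
       t1 = t1, t2 = t2, t3 = t3)
}

# ankle AP/vertical trajectory with analytic derivatives
eval_foot <- function(tq, ic, to, z_home, bm, clearance, ankle_h = 0.08) {
  m <- length(ic)
  K <- m - 1
  n <- length(tq)
  z <- rep(z_home, n); zd <- numeric(n); zdd <- numeric(n)
  y <- rep(ankle_h, n); yd <- numeric(n); ydd <- numeric(n)

  S <- ic[-1] - to
  p0 <- z_home - (bm$B(to) - bm$B(ic[-m]))
  rhs <- rbind(p0, -bm$v(to) * S, -bm$vdot(to) * S^2,
               rep(z_home, K), rep(0, K), rep(0, K))
  coef <- solve(QUINTIC_M, rhs) # 6 x K

  idx <- findInterval(tq, ic)
  post <- which(idx == m)
  if (length(post)) {
    z[post] <- z_home - (bm$B(tq[post]) - bm$B(ic[m]))
    zd[post] <- -bm$v(tq[post])
    zdd[post] <- -bm$vdot(tq[post])
  }
  ins <- which(idx >= 1 & idx <= K)
  k <- idx[ins]
  stance <- tq[ins] < to[k]
  ws <- ins[stance]; ks <- k[stance]
  if (length(ws)) {
    z[ws] <- z_home - (bm$B(tq[ws]) - bm$B(ic[ks]))
    zd[ws] <- -bm$v(tq[ws])
    zdd[ws] <- -bm$vdot(tq[ws])
  }
  wg <- ins[!stance]; kg <- k[!stance]
  if (length(wg)) {
    Sk <- S[kg]
    tau <- (tq[wg] - to[kg]) / Sk
    P <- t(coef[, kg, drop = FALSE])
    z[wg] <- P[, 1] + tau * (P[, 2] + tau * (P[, 3] +
             tau * (P[, 4] + tau * (P[, 5] + tau * P[, 6]))))
    zd[wg] <- (P[, 2] + tau * (2 * P[, 3] + tau * (3 * P[, 4] +
               tau * (4 * P[, 5] + tau * 5 * P[, 6])))) / Sk
    zdd[wg] <- (2 * P[, 3] + tau * (6 * P[, 4] + tau * (12 * P[, 5] +
                tau * 20 * P[, 6]))) / Sk^2
    y[wg] <- ankle_h + clearance * sin(pi * tau)^2
    yd[wg] <- clearance * pi / Sk * sin(2 * pi * tau)
    ydd[wg] <- clearance * 2 * pi^2 / Sk^2 * cos(2 * pi * tau)
  }
  list(z = z, zd = zd, zdd = zdd, y = y, yd = yd, ydd = ydd)
}

# continuous stride phase driven by the right-side IC clock; frozen outside
eval_phase <- function(tq, ic) {
  m <- length(ic); K <- m - 1
  Tk <- diff(ic)
  idx <- findInterval(tq, ic)
  phi <- numeric(length(tq)); dphi <- numeric(length(tq))
  phi[idx == m] <- K
  w <- which(idx >= 1 & idx <= K)
  k <- idx[w]
  phi[w] <- (k - 1) + (tq[w] - ic[k]) / Tk[k]
  dphi[w] <- 1 / Tk[k]
  list(phi = phi, dphi = dphi)
}

# stylized foot pitch rate: positive mid-swing peak, negative TO/IC dips
foot_gyro_ml <- function(tq, ic, to, peak = 4, dip = 1.2,
                         sigma_peak_frac = 0.12, sigma_dip = 0.025) {
  w <- numeric(length(tq))
  S <- ic[-1] - to
  add_gauss <- function(w, center, sigma, amp) {
    for (i in seq_along(center)) {
      j <- which(tq >= center[i] - 5 * sigma[i] &
                 tq <= center[i] + 5 * sigma[i])
      w[j] <- w[j] + amp * exp(-0.5 * ((tq[j] - center[i]) / sigma[i])^2)
    }
    w
  }
  w <- add_gauss(w, (to + ic[-1]) / 2, sigma_peak_frac * S, peak)
  w <- add_gauss(w, to, rep(sigma_dip, length(to)), -dip)
  w <- add_gauss(w, ic, rep(sigma_dip, length(ic)), -dip)
  w
}

#' Simulate a full treadmill trial with ground truth
#'
#' Trial structure: `stand_s` of quiet standing, a linear belt ramp of
#' `ramp_s`, `duration_walk` seconds of steady walking, an abrupt belt stop
#' and a final `stand_s` of standing. All randomness (stride-time jitter,
#' measurement noise) derives from `seed`; two calls with the same seed are
#' identical.
#'
#' @param profile A [gait_profile()].
#' @param duration_walk Steady walking duration, s (must cover a few
#'   strides; use >= 120 plus a margin for a full analysis window).
#' @param seed Integer seed fixing all randomness.
#' @param stand_s Standing bookend duration, s.
#' @param ramp_s Belt ramp-up duration, s.
#' @param skeleton_hz,imu_hz,belt_hz Device sample rates.
#' @return A list of class `gait_trial` with elements `skeleton`
#'   ([skeleton_sequence]), `imus` (named list of six [imu_recording]s),
#'   `belt` ([treadmill_log]), `truth` (ground-truth events, per-stride
#'   parameters and the noise-free centre-of-mass track) and `profile`.
#' @export
simulate_trial <- function(profile, duration_walk = 126, seed = 1,
                           stand_s = 3, ramp_s = 2, skeleton_hz = 30,
                           imu_hz = 128, belt_hz = 64) {
  stopifnot(inherits(profile, "gait_profile"))
  p <- profile
  if (p$duty_factor * p$stride_time < 2 / skeleton_hz) {
    stop("stance shorter than 2 skeleton frames: events unresolvable",
         call. = FALSE)
  }
  if (duration_walk < 3 * p$stride_time) {
    stop("duration_walk must cover at least a few strides", call. = FALSE)
  }
  set.seed(seed)

  t1 <- stand_s; t2 <- t1 + ramp_s; t3 <- t2 + duration_walk
  t4 <- t3 + stand_s
  bm <- belt_model(p$belt_speed, t1, t2, t3)

  # right-side IC clock with truncated-Gaussian stride-time jitter
  n_max <- ceiling(duration_walk / (p$stride_time * 0.8)) + 2
  eps <- pmin(3, pmax(-3, rnorm(n_max)))
  Tk_all <- p$stride_time * (1 + p$stride_cv * eps)
  ic_r <- t2 + c(0, cumsum(Tk_all))
  ic_r <- ic_r[ic_r <= t3 + 1e-9]
  K <- length(ic_r) - 1
  Tk <- diff(ic_r)
  to_r <- ic_r[-length(ic_r)] + p$duty_factor * Tk
  ic_l <- ic_r[-length(ic_r)] + p$phase_lr * Tk
  Tl <- diff(ic_l)
  to_l <- ic_l[-length(ic_l)] + p$duty_factor * Tl

  z_home <- p$belt_speed * p$duty_factor * p$stride_time / 2
  ankle_h <- 0.08
  x_ankle <- c(LEFT = -p$step_width / 2, RIGHT = p$step_width / 2)
  sh_h <- p$leg_length + 0.55
  x_sh <- c(LEFT = -0.18, RIGHT = 0.18)
  psi_sway <- -0.1 * pi

  # analytic state of every modelled point at arbitrary times
  model_state <- function(tq) {
    foot <- list(
      RIGHT = eval_foot(tq, ic_r, to_r, z_home, bm, p$foot_clearance, ankle_h),
      LEFT = eval_foot(tq, ic_l, to_l, z_home, bm, p$foot_clearance, ankle_h)
    )
    ph <- eval_phase(tq, ic_r)
    two_pi <- 2 * pi
    pel <- list(
      x = p$pelvis_sway_ml * sin(two_pi * ph$phi + psi_sway),
      xd = p$pelvis_sway_ml * two_pi * ph$dphi *
        cos(two_pi * ph$phi + psi_sway),
      xdd = -p$pelvis_sway_ml * (two_pi * ph$dphi)^2 *
        sin(two_pi * ph$phi + psi_sway),
      y = p$leg_length + p$pelvis_bounce_v * sin(2 * two_pi * ph$phi),
      ydd = -p$pelvis_bounce_v * (2 * two_pi * ph$dphi)^2 *
        sin(2 * two_pi * ph$phi)
    )
    arm <- lapply(c(LEFT = "LEFT", RIGHT = "RIGHT"), function(sd) {
      A <- (if (sd == "LEFT") p$arm_swing_deg_l else p$arm_swing_deg_r) *
        pi / 180 / 2
      sgn <- if (sd == "LEFT") 1 else -1
      alpha <- sgn * A * sin(two_pi * ph$phi)
      alphad <- sgn * A * two_pi * ph$dphi * cos(two_pi * ph$phi)
      alphadd <- -sgn * A * (two_pi * ph$dphi)^2 * sin(two_pi * ph$phi)
      r <- p$arm_length
      list(
        pos = cbind(x = rep(x_sh[[sd]], length(tq)),
                    y = sh_h - r * cos(alpha),
                    z = r * sin(alpha)),
        acc = cbind(x = rep(0, length(tq)),
                    y = r * (alphadd * sin(alpha) + alphad^2 * cos(alpha)),
                    z = r * (alphadd * cos(alpha) - alphad^2 * sin(alpha))),
        gyro_ml = alphad
      )
    })
    list(foot = foot, pelvis = pel, arm = arm, phase = ph)
  }

  # ---- skeleton stream (30 Hz) -------------------------------------------
  ts_sk <- seq(0, t4, by = 1 / skeleton_hz)
  st <- model_state(ts_sk)
  n_sk <- length(ts_sk)
  zero <- rep(0, n_sk)
  com <- cbind(x = st$pelvis$x, y = st$pelvis$y, z = zero)
  joints_true <- list(
    PELVIS = com,
    SHOULDER_L = cbind(x = rep(x_sh[["LEFT"]], n_sk), y = rep(sh_h, n_sk),
                       z = zero),
    SHOULDER_R = cbind(x = rep(x_sh[["RIGHT"]], n_sk), y = rep(sh_h, n_sk),
                       z = zero),
    WRIST_L = st$arm$LEFT$pos,
    WRIST_R = st$arm$RIGHT$pos,
    ANKLE_L = cbind(x = rep(x_ankle[["LEFT"]], n_sk), y = st$foot$LEFT$y,
                    z = st$foot$LEFT$z),
    ANKLE_R = cbind(x = rep(x_ankle[["RIGHT"]], n_sk), y = st$foot$RIGHT$y,
                    z = st$foot$RIGHT$z),
    FOOT_L = cbind(x = rep(x_ankle[["LEFT"]], n_sk),
                   y = st$foot$LEFT$y - 0.03, z = st$foot$LEFT$z + 0.18),
    FOOT_R = cbind(x = rep(x_ankle[["RIGHT"]], n_sk),
                   y = st$foot$RIGHT$y - 0.03, z = st$foot$RIGHT$z + 0.18)
  )
  joints <- lapply(names(joints_true), function(nm) {
    sdn <- if (nm %in% c("WRIST_L", "WRIST_R")) p$noise_wrist_m
           else p$noise_skeleton_m
    m <- joints_true[[nm]]
    if (sdn > 0) m <- m + matrix(rnorm(length(m), sd = sdn), ncol = 3)
    m
  })
  names(joints) <- names(joints_true)
  skeleton <- skeleton_sequence(ts_sk, joints, rate_hz = skeleton_hz)

  # ---- IMU streams (128 Hz, IDEALIZED world-aligned, gravity-free) -------
  ts_imu <- seq(0, t4, by = 1 / imu_hz)
  sti <- model_state(ts_imu)
  n_imu <- length(ts_imu)
  zero_i <- rep(0, n_imu)
  mk_imu <- function(site, accel, gyro) {
    if (p$noise_accel > 0) {
      accel <- accel + matrix(rnorm(length(accel), sd = p$noise_accel),
                              ncol = 3)
    }
    if (p$noise_gyro > 0) {
      gyro <- gyro + matrix(rnorm(length(gyro), sd = p$noise_gyro), ncol = 3)
    }
    imu_recording(site, ts_imu, accel, gyro, rate_hz = imu_hz)
  }
  pelvis_acc <- cbind(sti$pelvis$xdd, sti$pelvis$ydd, zero_i)
  imus <- list(
    FOOT_L = mk_imu("FOOT_L",
                    cbind(zero_i, sti$foot$LEFT$ydd, sti$foot$LEFT$zdd),
                    cbind(foot_gyro_ml(ts_imu, ic_l, to_l), zero_i, zero_i)),
    FOOT_R = mk_imu("FOOT_R",
                    cbind(zero_i, sti$foot$RIGHT$ydd, sti$foot$RIGHT$zdd),
                    cbind(foot_gyro_ml(ts_imu, ic_r, to_r), zero_i, zero_i)),
    WRIST_L = mk_imu("WRIST_L", sti$arm$LEFT$acc,
                     cbind(sti$arm$LEFT$gyro_ml, zero_i, zero_i)),
    WRIST_R = mk_imu("WRIST_R", sti$arm$RIGHT$acc,
                     cbind(sti$arm$RIGHT$gyro_ml, zero_i, zero_i)),
    LUMBAR = mk_imu("LUMBAR", pelvis_acc, cbind(zero_i, zero_i, zero_i)),
    STERNUM = mk_imu("STERNUM", pelvis_acc, cbind(zero_i, zero_i, zero_i))
  )

  # ---- belt log (64 Hz) --------------------------------------------------
  ts_belt <- seq(0, t4, by = 1 / belt_hz)
  belt <- treadmill_log(ts_belt, bm$v(ts_belt), rate_hz = belt_hz)

  # ---- ground truth ------------------------------------------------------
  stride_tab <- function(ic, side) {
    K <- length(ic) - 1
    if (K < 1) return(NULL)
    data.frame(side = side, ic_time = ic[-length(ic)],
               stride_time = diff(ic),
               stride_length = bm$B(ic[-1]) - bm$B(ic[-length(ic)]))
  }
  truth <- list(
    ic_times = list(LEFT = ic_l, RIGHT = ic_r),
    to_times = list(LEFT = to_l, RIGHT = to_r),
    strides = rbind(stride_tab(ic_r, "RIGHT"), stride_tab(ic_l, "LEFT")),
    step_width = p$step_width,
    arm_swing_deg = c(LEFT = p$arm_swing_deg_l, RIGHT = p$arm_swing_deg_r),
    com = cbind(time = ts_sk, com),
    duty_factor = p$duty_factor,
    stride_times = Tk,
    walk_start = t2, walk_end = t3
  )

  structure(list(skeleton = skeleton, imus = imus, belt = belt,
                 truth = truth, profile = p,
                 timeline = list(stand_s = stand_s, ramp_s = ramp_s,
                                 walk_start = t2, walk_end = t3, end = t4)),
            class = "gait_trial")
}

#' Ground-truth events as a gait-event table
#'
#' @param trial A `gait_trial` from [simulate_trial()].
#' @param source Source label to stamp on the events.
#' @return A [gait_events] table of the true ICs and TOs.
#' @export
truth_events <- function(trial, source = "KINEMATIC") {
  tr <- trial$truth
  ev <- do.call(rbind, lapply(c("LEFT", "RIGHT"), function(sd) {
    rbind(
      data.frame(time = tr$ic_times[[sd]], side = sd, kind = "IC"),
      data.frame(time = tr$to_times[[sd]], side = sd, kind = "TO")
    )
  }))
  gait_events(ev$time, ev$side, ev$kind, source, score = 1)
}

#' Transform world-frame IMU channels into the sensor frame
#'
#' `IDEALIZED` mode returns world-aligned, gravity-free channels unchanged
#' (the generator's native output, suited to exact oracle tests).
#' `REALISTIC` mode rotates channels into a sensor frame pitched about the
#' mediolateral (X) axis by `pitch` and adds gravity to the accelerometer,
#' i.e. it reports specific force: a stationary, flat sensor reads +9.81
#' m/s^2 on its vertical channel.
#'
#' @param accel n-by-3 world-frame linear acceleration, m/s^2 (gravity-free).
#' @param gyro n-by-3 world-frame angular velocity, rad/s.
#' @param pitch Pitch angle per sample, radians (rotation about ML axis).
#' @param mode `"IDEALIZED"` or `"REALISTIC"`.
#' @return List with rotated `accel` and `gyro` matrices.
#' @export
imu_sensor_frame <- function(accel, gyro, pitch,
                             mode = c("IDEALIZED", "REALISTIC")) {
  mode <- match.arg(mode)
  accel <- as.matrix(accel); gyro <- as.matrix(gyro)
  if (mode == "IDEALIZED") {
    return(list(accel = accel, gyro = gyro))
  }
  stopifnot(length(pitch) == nrow(accel))
  f <- accel
  f[, 2] <- f[, 2] + GRAVITY # specific force: subtract g pointing down
  c_ <- cos(pitch); s_ <- sin(pitch)
  rot <- function(m) {
    cbind(m[, 1], c_ * m[, 2] + s_ * m[, 3], -s_ * m[, 2] + c_ * m[, 3])
  }
  list(accel = rot(f), gyro = rot(gyro))
}

#' Synthetic cohort of paired method summaries
#'
#' Generates participant-level window means for two methods with an
#' injected between-method bias and noise, for exercising the agreement
#' pipeline at cohort scale without full trial simulation.
#'
#' @param n Number of participants.
#' @param true_mean,true_sd Population mean / SD of the parameter.
#' @param bias Systematic method difference (IMU minus kinematic), same
#'   units as the parameter.
#' @param sd_diff SD of the random between-method difference.
#' @param parameter Name of the parameter column.
#' @param seed Optional integer seed.
#' @return Data frame with columns `participant`, `source` and the
#'   parameter, two rows per participant.
#' @export
simulate_cohort_summaries <- function(n = 54, true_mean = 1.25,
                                      true_sd = 0.15, bias = -0.005,
                                      sd_diff = 0.03,
                                      parameter = "stride_length_m",
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  base <- rnorm(n, true_mean, true_sd)
  imu <- base + bias + rnorm(n, 0, sd_diff)
  out <- data.frame(
    participant = rep(sprintf("P%02d", seq_len(n)), each = 2),
    source = rep(c("KINEMATIC", "IMU"), n)
  )
  out[[parameter]] <- as.vector(rbind(base, imu))
  out
}
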