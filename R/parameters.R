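# Per-stride gait parameters from events + streams, for each modality.
# Strides are ipsilateral IC-to-IC; belt-relative spatial quantities add the
# treadmill translation (integral of belt speed) over the relevant interval.

belt_range_check <- function(belt, t0, t1) {
  if (t0 > t1) stop("interval start after end", call. = FALSE)
  rng <- range(belt$timestamps)
  if (t0 < rng[1] - 1e-9 || t1 > rng[2] + 1e-9) {
    stop("interval outside the treadmill log", call. = FALSE)
  }
}

belt_speed_at <- function(belt, t) {
  approx(belt$timestamps, belt$speed, xout = t, rule = 2)$y
}

#' Treadmill translation over a time interval
#'
#' Trapezoidal integral of the logged belt speed over `[t0, t1]`, i.e. the
#' distance the belt surface travels.
#'
#' @param belt A [treadmill_log].
#' @param t0,t1 Interval bounds in seconds, inside the log.
#' @return Distance in metres.
#' @export
belt_translation <- function(belt, t0, t1) {
  belt_range_check(belt, t0, t1)
  if (t1 == t0) return(0)
  inner <- belt$timestamps[belt$timestamps > t0 & belt$timestamps < t1]
  x <- c(t0, inner, t1)
  y <- belt_speed_at(belt, x)
  pracma::trapz(x, y)
}

#' Stride times from a stride table
#'
#' @param strides Output of [pair_strides()].
#' @return Numeric vector of ipsilateral IC-to-IC durations, seconds.
#' @export
stride_time <- function(strides) {
  if (nrow(strides) < 1) stop("no strides", call. = FALSE)
  strides$stride_time
}

#' Kinematic stride length (ankle displacement plus belt translation)
#'
#' Per stride, the change in the leading ankle's anteroposterior coordinate
#' between consecutive ipsilateral initial contacts plus the treadmill
#' translation over the stride.
#'
#' @param skel A filtered [skeleton_sequence].
#' @param strides Output of [pair_strides()] (kinematic source).
#' @param belt A [treadmill_log].
#' @return Numeric vector, metres per stride (NA where the ankle track is
#'   unusable at an IC).
#' @export
stride_length_kinematic <- function(skel, strides, belt) {
  vapply(seq_len(nrow(strides)), function(i) {
    sd <- strides$side[i]
    joint <- paste0("ANKLE_", substr(sd, 1, 1))
    z <- joint_at(skel, joint, c(strides$ic_time[i],
                                 strides$next_ic_time[i]))[, 3]
    if (any(!is.finite(z))) return(NA_real_)
    (z[2] - z[1]) +
      belt_translation(belt, strides$ic_time[i], strides$next_ic_time[i])
  }, numeric(1))
}

#' Inertial stride length (double integration plus belt translation)
#'
#' Per stride of the instrumented foot, the anteroposterior acceleration is
#' double-integrated from toe-off to the following ipsilateral initial
#' contact, starting from the camera-frame velocity of the stance foot at
#' toe-off (`-belt speed`: the foot is still riding the belt), and the
#' treadmill translation over the swing is added. Optional dedrifting
#' applies a linear correction to the integrated velocity so that it ends
#' at the foot's camera-frame landing velocity (`v_ic`, default 0),
#' removing accelerometer bias accumulated over the swing.
#'
#' @param foot A filtered foot [imu_recording].
#' @param strides Output of [pair_strides()] (IMU source; only rows of this
#'   foot's side are used).
#' @param belt A [treadmill_log].
#' @param dedrift Apply the linear velocity correction (default TRUE).
#' @param v_ic Camera-frame AP velocity of the foot at initial contact used
#'   as the dedrifting target, m/s.
#' @param ap_axis Acceleration column carrying the anteroposterior axis.
#' @param belt_interval `"swing"` (default) integrates belt translation over
#'   toe-off to initial contact; `"stride"` over the full IC-to-IC stride.
#' @return Numeric vector, metres, aligned with the rows of `strides` for
#'   this foot's side (NA for strides missing their toe-off).
#' @export
stride_length_imu <- function(foot, strides, belt, dedrift = TRUE, v_ic = 0,
                              ap_axis = 3,
                              belt_interval = c("swing", "stride")) {
  belt_interval <- match.arg(belt_interval)
  side <- if (foot$site == "FOOT_L") "LEFT" else "RIGHT"
  rows <- which(strides$side == side)
  ts <- foot$timestamps
  az <- foot$accel[, ap_axis]
  vapply(rows, function(i) {
    t_to <- strides$to_time[i]
    t_ic <- strides$next_ic_time[i]
    if (is.na(t_to)) return(NA_real_)
    inner <- which(ts > t_to & ts < t_ic)
    x <- c(t_to, ts[inner], t_ic)
    a <- c(approx(ts, az, t_to)$y, az[inner], approx(ts, az, t_ic)$y)
    v <- -belt_speed_at(belt, t_to) + pracma::cumtrapz(x, a)[, 1]
    if (dedrift) {
      v <- v + (v_ic - v[length(v)]) * (x - t_to) / (t_ic - t_to)
    }
    d <- pracma::trapz(x, v)
    tr <- if (belt_interval == "swing") {
      belt_translation(belt, t_to, t_ic)
    } else {
      belt_translation(belt, strides$ic_time[i], t_ic)
    }
    d + tr
  }, numeric(1))
}

#' Single and double support times
#'
#' Per stride, single support is the contralateral swing (contralateral
#' toe-off to contralateral initial contact inside the stride); double
#' support is the sum of the two bilateral-contact intervals (each side's
#' IC to the other side's TO).
#'
#' @param strides Output of [pair_strides()] with contralateral events.
#' @return Data frame with `single_support` and `double_support`, seconds
#'   (NA where contralateral events or the own toe-off are missing).
#' @export
support_times <- function(strides) {
  single <- strides$contra_ic - strides$contra_to
  double <- (strides$contra_to - strides$ic_time) +
    (strides$to_time - strides$contra_ic)
  data.frame(single_support = single, double_support = double)
}

#' Cadence in steps per minute
#'
#' Number of initial contacts (both sides) inside the analysis window,
#' scaled to a minute.
#'
#' @param events A [gait_events] table (one source).
#' @param window An `analysis_window`.
#' @return Steps per minute.
#' @export
cadence <- function(events, window) {
  n <- sum(events$kind == "IC" & in_window(events$time, window))
  if (n == 0) stop("insufficient gait cycles", call. = FALSE)
  n / window$length_s * 60
}

#' Step width at each initial contact
#'
#' Mediolateral separation of the two ankle centres at each IC.
#'
#' @param skel A filtered [skeleton_sequence].
#' @param events A [gait_events] table with bilateral ICs.
#' @return Data frame `time`, `side`, `step_width` (metres), one row per IC.
#' @export
step_width <- function(skel, events) {
  ic <- events[events$kind == "IC", , drop = FALSE]
  if (!all(c("LEFT", "RIGHT") %in% ic$side) ||
      is.null(skel$joints$ANKLE_L) || is.null(skel$joints$ANKLE_R)) {
    return(data.frame(time = numeric(0), side = character(0),
                      step_width = numeric(0)))
  }
  xl <- joint_at(skel, "ANKLE_L", ic$time)[, 1]
  xr <- joint_at(skel, "ANKLE_R", ic$time)[, 1]
  data.frame(time = ic$time, side = ic$side, step_width = abs(xr - xl))
}

#' Inverted-pendulum parameters for the margin of stability
#'
#' @param leg_length Pendulum length in metres; if `NULL`, estimate it from
#'   the data with [estimate_pendulum_length()].
#' @param g Gravitational acceleration, m/s^2.
#' @return Object of class `mos_params` with fields `l`, `g` and the
#'   eigenfrequency `omega0 = sqrt(g / l)`.
#' @export
mos_params <- function(leg_length, g = GRAVITY) {
  stopifnot(leg_length > 0, g > 0)
  structure(list(l = leg_length, g = g, omega0 = sqrt(g / leg_length)),
            class = "mos_params")
}

#' @rdname mos_params
#' @param skel A [skeleton_sequence].
#' @param events IC events used as sampling instants.
#' @export
estimate_pendulum_length <- function(skel, events) {
  ic <- events[events$kind == "IC", , drop = FALSE]
  d <- vapply(seq_len(nrow(ic)), function(i) {
    joint <- paste0("ANKLE_", substr(ic$side[i], 1, 1))
    sqrt(sum((joint_at(skel, joint, ic$time[i]) -
                joint_at(skel, "PELVIS", ic$time[i]))^2))
  }, numeric(1))
  mean(d)
}

# central-difference velocity of an n-by-3 track (forward/backward at edges)
track_velocity <- function(ts, m) {
  n <- length(ts)
  v <- matrix(NA_real_, n, 3)
  v[2:(n - 1), ] <- (m[3:n, ] - m[1:(n - 2), ]) / (ts[3:n] - ts[1:(n - 2)])
  v[1, ] <- (m[2, ] - m[1, ]) / (ts[2] - ts[1])
  v[n, ] <- (m[n, ] - m[n - 1, ]) / (ts[n] - ts[n - 1])
  v
}

#' Margin of stability at each initial contact
#'
#' Extrapolated centre of mass: `XCoM = CoM + CoM_velocity / omega0`, with
#' the CoM estimated as the pelvis midpoint and its velocity by central
#' differences on the filtered pelvis track. The mediolateral margin is the
#' signed distance from the XCoM to the leading ankle's ML position
#' (positive = XCoM medial of the foot, stable); the anteroposterior margin
#' is the leading toe's AP position minus the XCoM (positive = XCoM behind
#' the anterior base-of-support bound).
#'
#' @param skel A filtered [skeleton_sequence] with PELVIS, ankles and
#'   (for the AP margin) toe landmarks.
#' @param events A [gait_events] table; ICs are used.
#' @param params A [mos_params()].
#' @return Data frame `time`, `side`, `mos_ml`, `mos_ap` (metres; `mos_ap`
#'   NA when the toe landmark is absent).
#' @export
margin_of_stability <- function(skel, events, params) {
  stopifnot(inherits(params, "mos_params"))
  ic <- events[events$kind == "IC", , drop = FALSE]
  ts <- skel$timestamps
  pel <- skel$joints$PELVIS
  vel <- track_velocity(ts, pel)
  com_i <- vapply(1:3, function(j) approx(ts, pel[, j], ic$time)$y,
                  numeric(nrow(ic)))
  vel_i <- vapply(1:3, function(j) approx(ts, vel[, j], ic$time)$y,
                  numeric(nrow(ic)))
  com_i <- matrix(com_i, ncol = 3); vel_i <- matrix(vel_i, ncol = 3)
  xcom_ml <- com_i[, 1] + vel_i[, 1] / params$omega0
  xcom_ap <- com_i[, 3] + vel_i[, 3] / params$omega0
  res <- data.frame(time = ic$time, side = ic$side,
                    mos_ml = NA_real_, mos_ap = NA_real_)
  for (sd in c("LEFT", "RIGHT")) {
    rows <- which(ic$side == sd)
    if (!length(rows)) next
    suffix <- substr(sd, 1, 1)
    ankle <- paste0("ANKLE_", suffix)
    if (!is.null(skel$joints[[ankle]])) {
      ax <- joint_at(skel, ankle, ic$time[rows])[, 1]
      sgn <- if (sd == "RIGHT") 1 else -1
      res$mos_ml[rows] <- sgn * (ax - xcom_ml[rows])
    }
    toe <- paste0("FOOT_", suffix)
    if (!is.null(skel$joints[[toe]])) {
      tz <- joint_at(skel, toe, ic$time[rows])[, 3]
      res$mos_ap[rows] <- tz - xcom_ap[rows]
    }
  }
  res
}

#' Arm swing amplitude from a wrist gyroscope
#'
#' The angular velocity is projected on its dominant rotation axis (first
#' principal axis of the gyro covariance inside the window) and integrated
#' to an angle. Swing cycles run between successive upward zero crossings
#' of the projected angular velocity; within each cycle the angle is
#' linearly dedrifted (line through its endpoint values removed) and the
#' amplitude is its peak-to-peak range.
#'
#' @param wrist A filtered wrist [imu_recording].
#' @param window An `analysis_window`.
#' @return Numeric vector of per-cycle amplitudes in degrees (a single 0
#'   when no swing cycles are present).
#' @export
arm_swing_imu <- function(wrist, window) {
  if (!wrist$site %in% c("WRIST_L", "WRIST_R")) {
    stop("arm_swing_imu requires a wrist recording", call. = FALSE)
  }
  sel <- which(in_window(wrist$timestamps, window))
  ts <- wrist$timestamps[sel]
  G <- wrist$gyro[sel, , drop = FALSE]
  cv <- stats::cov(G)
  axis <- eigen(cv, symmetric = TRUE)$vectors[, 1]
  om <- as.vector(G %*% axis)
  theta <- pracma::cumtrapz(ts, om)[, 1] * 180 / pi
  up <- which(om[-length(om)] < 0 & om[-1] >= 0)
  if (length(up) < 2) return(0)
  # sub-sample crossing times and angle values
  frac <- -om[up] / (om[up + 1] - om[up])
  t_cross <- ts[up] + frac * (ts[up + 1] - ts[up])
  th_cross <- theta[up] + frac * (theta[up + 1] - theta[up])
  cyc_len <- diff(t_cross)
  keep <- cyc_len > 0.5 * median(cyc_len)
  amps <- vapply(which(keep), function(i) {
    j <- which(ts > t_cross[i] & ts < t_cross[i + 1])
    tt <- c(t_cross[i], ts[j], t_cross[i + 1])
    th <- c(th_cross[i], theta[j], th_cross[i + 1])
    drift <- th[1] + (th[length(th)] - th[1]) *
      (tt - tt[1]) / (tt[length(tt)] - tt[1])
    diff(range(th - drift))
  }, numeric(1))
  if (!length(amps)) 0 else amps
}

#' Arm swing amplitude from the skeleton (cosine theorem)
#'
#' The arm length is the median shoulder-to-wrist distance in the window.
#' Successive anteroposterior extremes of the wrist (most anterior / most
#' posterior positions relative to the shoulder) give a chord `c`; the
#' swing amplitude follows from the cosine theorem on the isosceles
#' triangle with sides `r`, `r`, `c`:
#' `amplitude = acos((2 r^2 - c^2) / (2 r^2))`.
#' Chords exceeding the diameter (noise) are clamped to `2 r` and flagged.
#'
#' @param skel A filtered [skeleton_sequence] with shoulder and wrist
#'   tracks.
#' @param window An `analysis_window`.
#' @param sides Sides to analyse.
#' @return Data frame `side`, `time` (mid-swing), `amplitude_deg`,
#'   `clamped`.
#' @export
arm_swing_kinematic <- function(skel, window, sides = c("LEFT", "RIGHT")) {
  sel <- which(in_window(skel$timestamps, window))
  ts <- skel$timestamps[sel]
  out <- NULL
  for (sd in sides) {
    suffix <- substr(sd, 1, 1)
    sh <- skel$joints[[paste0("SHOULDER_", suffix)]]
    wr <- skel$joints[[paste0("WRIST_", suffix)]]
    if (is.null(sh) || is.null(wr)) next
    rel <- wr[sel, , drop = FALSE] - sh[sel, , drop = FALSE]
    r <- median(sqrt(rowSums(rel^2)))
    z <- rel[, 3]
    amp <- diff(quantile(z, c(0.05, 0.95))) / 2
    if (!is.finite(amp) || amp <= 0) next
    pick <- function(x) {
      rough <- find_peaks(x, min_prominence = 0.3 * amp)
      if (nrow(rough) < 2) return(rough)
      find_peaks(x, min_prominence = 0.3 * amp,
                 min_distance = max(1, round(0.5 * median(diff(rough$index)))))
    }
    ant <- pick(z); post <- pick(-z)
    if (nrow(ant) < 1 || nrow(post) < 1) next
    ext <- rbind(data.frame(index = ant$index, kind = "ANT",
                            score = ant$prominence),
                 data.frame(index = post$index, kind = "POST",
                            score = post$prominence))
    ext$time <- ts[ext$index]
    ext2 <- enforce_alternation(ext)
    if (nrow(ext2) < 2) next
    for (i in seq_len(nrow(ext2) - 1)) {
      p1 <- rel[ext2$index[i], ]
      p2 <- rel[ext2$index[i + 1], ]
      cc <- sqrt(sum((p1 - p2)^2))
      clamped <- cc > 2 * r
      if (clamped) cc <- 2 * r
      a_deg <- acos(pmin(1, pmax(-1, (2 * r^2 - cc^2) / (2 * r^2)))) *
        180 / pi
      out <- rbind(out, data.frame(
        side = sd, time = mean(c(ext2$time[i], ext2$time[i + 1])),
        amplitude_deg = a_deg, clamped = clamped))
    }
  }
  if (is.null(out)) {
    out <- data.frame(side = character(0), time = numeric(0),
                      amplitude_deg = numeric(0), clamped = logical(0))
  }
  out
}

#' Average stride parameters over the analysis window
#'
#' Arithmetic mean of each per-stride parameter over all strides (both
#' sides pooled) whose initial contact lies in the window; arm swing is
#' averaged within side. Stride counts and the realized window length are
#' recorded.
#'
#' @param stride_table Per-stride parameter table (see [analyze_trial()]).
#' @param window An `analysis_window`.
#' @param participant Participant identifier.
#' @param source `"KINEMATIC"` or `"IMU"`.
#' @param arm_swing Optional named list (`LEFT`, `RIGHT`) of per-cycle arm
#'   swing amplitudes in degrees.
#' @param cadence Optional cadence, steps/min.
#' @return One-row data frame (a summary row).
#' @export
summarize_window <- function(stride_table, window, participant, source,
                             arm_swing = NULL, cadence = NA_real_) {
  st <- stride_table[in_window(stride_table$ic_time, window), , drop = FALSE]
  if (nrow(st) < 1) stop("no strides in window", call. = FALSE)
  m <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  data.frame(
    participant = participant, source = source, n_strides = nrow(st),
    window_s = window$length_s,
    stride_time_s = m(st$stride_time),
    stride_length_m = m(st$stride_length),
    single_support_s = m(st$single_support),
    double_support_s = m(st$double_support),
    step_width_m = m(st$step_width),
    mos_ml_m = m(st$mos_ml),
    mos_ap_m = m(st$mos_ap),
    arm_swing_l_deg = if (is.null(arm_swing)) NA_real_
                      else m(arm_swing$LEFT),
    arm_swing_r_deg = if (is.null(arm_swing)) NA_real_
                      else m(arm_swing$RIGHT),
    cadence_spm = cadence
  )
}
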