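# Domain containers shared by all pipeline stages. Plain lists / data.frames
# with light S3 classes and strict constructors; all kinematic quantities are
# stored in the canonical body frame (X right, Y up, Z anterior), metres.

#' Skeleton joint-position time series
#'
#' Container for a depth-camera pose-estimation stream: per-frame 3D positions
#' of named joints in the canonical body frame.
#'
#' @param timestamps Numeric vector of frame times in seconds, strictly
#'   increasing.
#' @param joints Named list of n-by-3 numeric matrices (columns x, y, z in
#'   metres, canonical frame), one per joint, each with `length(timestamps)`
#'   rows.
#' @param rate_hz Nominal frame rate in Hz (default 30).
#' @return An object of class `skeleton_sequence`.
#' @export
skeleton_sequence <- function(timestamps, joints, rate_hz = 30) {
  stopifnot(is.numeric(timestamps), length(timestamps) > 0, rate_hz > 0)
  if (any(diff(timestamps) <= 0)) {
    stop("skeleton timestamps must be strictly increasing", call. = FALSE)
  }
  if (is.null(names(joints)) || any(!nzchar(names(joints)))) {
    stop("joints must be a named list", call. = FALSE)
  }
  joints <- lapply(joints, function(m) {
    m <- as.matrix(m)
    if (nrow(m) != length(timestamps) || ncol(m) != 3) {
      stop("each joint array must be n-by-3 with n = length(timestamps)",
           call. = FALSE)
    }
    colnames(m) <- CANONICAL_AXES
    m
  })
  structure(
    list(timestamps = as.numeric(timestamps), joints = joints,
         rate_hz = rate_hz),
    class = "skeleton_sequence"
  )
}

#' @export
print.skeleton_sequence <- function(x, ...) {
  cat(sprintf(
    "<skeleton_sequence> %d frames @ %g Hz, %.1f s, joints: %s\n",
    length(x$timestamps), x$rate_hz, diff(range(x$timestamps)),
    paste(names(x$joints), collapse = ", ")
  ))
  invisible(x)
}

#' Single-site IMU recording
#'
#' @param site One of [IMU_SITES].
#' @param timestamps Sample times in seconds, strictly increasing.
#' @param accel n-by-3 linear acceleration, m/s^2.
#' @param gyro n-by-3 angular velocity, rad/s.
#' @param rate_hz Sample rate in Hz (default 128).
#' @param axes Character note describing the axis convention of the channels
#'   (default `"canonical"`: world-aligned, x = ML, y = vertical, z = AP).
#' @return An object of class `imu_recording`.
#' @export
imu_recording <- function(site, timestamps, accel, gyro, rate_hz = 128,
                          axes = "canonical") {
  site <- match.arg(site, IMU_SITES)
  stopifnot(rate_hz > 0)
  if (any(diff(timestamps) <= 0)) {
    stop("IMU timestamps must be strictly increasing", call. = FALSE)
  }
  accel <- as.matrix(accel); gyro <- as.matrix(gyro)
  n <- length(timestamps)
  if (nrow(accel) != n || nrow(gyro) != n || ncol(accel) != 3 ||
      ncol(gyro) != 3) {
    stop("accel and gyro must be n-by-3 with n = length(timestamps)",
         call. = FALSE)
  }
  colnames(accel) <- paste0("a", CANONICAL_AXES)
  colnames(gyro) <- paste0("g", CANONICAL_AXES)
  structure(
    list(site = site, timestamps = as.numeric(timestamps), accel = accel,
         gyro = gyro, rate_hz = rate_hz, axes = axes),
    class = "imu_recording"
  )
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("<imu_recording> site %s, %d samples @ %g Hz\n",
              x$site, length(x$timestamps), x$rate_hz))
  invisible(x)
}

#' Treadmill belt-speed log
#'
#' @param timestamps Sample times in seconds, strictly increasing.
#' @param speed Belt speed in m/s, non-negative.
#' @param rate_hz Log rate in Hz (default 64).
#' @return An object of class `treadmill_log`.
#' @export
treadmill_log <- function(timestamps, speed, rate_hz = 64) {
  stopifnot(length(timestamps) == length(speed), rate_hz > 0)
  if (any(diff(timestamps) <= 0)) {
    stop("treadmill timestamps must be strictly increasing", call. = FALSE)
  }
  if (any(speed < 0)) {
    stop("belt speed must be non-negative", call. = FALSE)
  }
  structure(
    list(timestamps = as.numeric(timestamps), speed = as.numeric(speed),
         rate_hz = rate_hz),
    class = "treadmill_log"
  )
}

#' Typed gait-event list
#'
#' @param time Event times in seconds.
#' @param side `"LEFT"` or `"RIGHT"` per event.
#' @param kind `"IC"` (initial contact) or `"TO"` (toe-off) per event.
#' @param source `"KINEMATIC"` or `"IMU"` per event (scalar recycled).
#' @param score Optional detection score (peak prominence), used to break
#'   alternation ties.
#' @return A `data.frame` of class `gait_events`, sorted by time.
#' @export
gait_events <- function(time, side, kind, source, score = NA_real_) {
  n <- length(time)
  side <- rep_len(as.character(side), n)
  kind <- rep_len(as.character(kind), n)
  source <- rep_len(as.character(source), n)
  score <- rep_len(as.numeric(score), n)
  stopifnot(all(side %in% c("LEFT", "RIGHT")),
            all(kind %in% c("IC", "TO")),
            all(source %in% c("KINEMATIC", "IMU")))
  ev <- data.frame(time = as.numeric(time), side = side, kind = kind,
                   source = source, score = score,
                   stringsAsFactors = FALSE)
  ev <- ev[order(ev$time), , drop = FALSE]
  rownames(ev) <- NULL
  class(ev) <- c("gait_events", "data.frame")
  ev
}

#' Check the IC/TO alternation invariant
#'
#' Events from one source and side must alternate IC, TO, IC, TO in time.
#'
#' @param events A [gait_events] data frame.
#' @return `TRUE` invisibly, or an error describing the violation.
#' @export
validate_alternation <- function(events) {
  for (src in unique(events$source)) {
    for (sd in unique(events$side)) {
      k <- events$kind[events$source == src & events$side == sd]
      if (length(k) > 1 && any(k[-1] == k[-length(k)])) {
        stop(sprintf("events for %s/%s do not alternate IC/TO", src, sd),
             call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

#' Participant metadata
#'
#' @param id Participant identifier.
#' @param preferred_speed Preferred treadmill walking speed, m/s (> 0).
#' @param leg_length Leg length in metres (> 0), used as the inverted-pendulum
#'   length for the margin of stability.
#' @param group `"FALLER"` or `"NON_FALLER"` (history of falls).
#' @return An object of class `participant_meta`.
#' @export
participant_meta <- function(id, preferred_speed, leg_length,
                             group = c("NON_FALLER", "FALLER")) {
  group <- match.arg(group)
  stopifnot(preferred_speed > 0, leg_length > 0)
  structure(
    list(id = as.character(id), preferred_speed = preferred_speed,
         leg_length = leg_length, group = group),
    class = "participant_meta"
  )
}

# internal: interpolate a joint track at arbitrary times (linear); n-by-3
joint_at <- function(skel, joint, t) {
  m <- skel$joints[[joint]]
  if (is.null(m)) stop(sprintf("joint %s not present", joint), call. = FALSE)
  out <- vapply(seq_len(3), function(j) {
    approx(skel$timestamps, m[, j], xout = t, rule = 2)$y
  }, numeric(length(t)))
  matrix(out, ncol = 3, dimnames = list(NULL, CANONICAL_AXES))
}
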