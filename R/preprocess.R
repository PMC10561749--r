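# Stream conditioning: low-pass filtering, trimming of non-walking segments
# via the belt log, and selection of the analysis window.

#' Low-pass Butterworth filter specification
#'
#' Defaults follow the processing conventions of the pipeline: IMU channels
#' use a 4th-order, 10 Hz low-pass; skeleton coordinates a 1st-order, 6 Hz
#' low-pass. Filters are applied forward-backward (zero phase) by default so
#' that event times are not lagged differently across modalities; the stated
#' order is the per-pass design order.
#'
#' @param order Filter design order (per pass).
#' @param cutoff_hz Cut-off frequency, Hz; must be below the Nyquist
#'   frequency of the signal it is applied to.
#' @param zero_phase Apply forward-backward (`TRUE`, default) or single-pass.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(order, cutoff_hz, zero_phase = TRUE) {
  stopifnot(order >= 1, cutoff_hz > 0)
  structure(list(order = as.integer(order), cutoff_hz = cutoff_hz,
                 zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

#' Apply a low-pass Butterworth filter
#'
#' @param x Numeric vector or matrix (filtered by column), uniformly sampled.
#' @param spec A [filter_spec()].
#' @param rate_hz Sample rate of `x` in Hz.
#' @return Filtered signal, same shape as `x`.
#' @export
butterworth_lowpass <- function(x, spec, rate_hz) {
  stopifnot(inherits(spec, "filter_spec"), rate_hz > 0)
  if (spec$cutoff_hz >= rate_hz / 2) {
    stop("filter cutoff must be below the Nyquist frequency", call. = FALSE)
  }
  if (is.matrix(x)) {
    out <- apply(x, 2, butterworth_lowpass, spec = spec, rate_hz = rate_hz)
    dimnames(out) <- dimnames(x)
    return(out)
  }
  if (length(x) <= 3 * spec$order) {
    stop("signal too short for the requested filter order", call. = FALSE)
  }
  if (any(!is.finite(x))) stop("non-finite values in signal", call. = FALSE)
  bf <- signal::butter(spec$order, 2 * spec$cutoff_hz / rate_hz,
                       type = "low")
  if (spec$zero_phase) {
    # forward-backward with odd-reflection padding and DC-offset removal,
    # so edge transients decay inside the padding (DC gain is exactly 1)
    n <- length(x)
    np <- min(n - 1, ceiling(6 * rate_hz / spec$cutoff_hz))
    xe <- c(2 * x[1] - x[(np + 1):2], x, 2 * x[n] - x[(n - 1):(n - np)])
    run <- function(v) {
      as.numeric(signal::filter(bf, v - v[1])) + v[1]
    }
    y <- rev(run(rev(run(xe))))
    y[(np + 1):(np + n)]
  } else {
    as.numeric(signal::filter(bf, x))
  }
}

#' Default pipeline filters
#'
#' The stream conventions of the pipeline: IMU channels 4th-order 10 Hz,
#' skeleton coordinates 1st-order 6 Hz, both zero-phase.
#' @return A [filter_spec()].
#' @export
imu_filter_default <- function() filter_spec(order = 4, cutoff_hz = 10)

#' @rdname imu_filter_default
#' @export
skeleton_filter_default <- function() filter_spec(order = 1, cutoff_hz = 6)

#' Filter all channels of a stream object
#'
#' Convenience wrappers applying [butterworth_lowpass()] to every joint of a
#' skeleton sequence or every accel/gyro channel of an IMU recording.
#'
#' @param skel A [skeleton_sequence].
#' @param spec A [filter_spec()]; defaults to the stream's convention.
#' @return The filtered stream object.
#' @export
filter_skeleton <- function(skel, spec = skeleton_filter_default()) {
  skel$joints <- lapply(skel$joints, butterworth_lowpass, spec = spec,
                        rate_hz = skel$rate_hz)
  skel
}

#' @rdname filter_skeleton
#' @param imu An [imu_recording].
#' @export
filter_imu <- function(imu, spec = imu_filter_default()) {
  imu$accel <- butterworth_lowpass(imu$accel, spec, imu$rate_hz)
  imu$gyro <- butterworth_lowpass(imu$gyro, spec, imu$rate_hz)
  imu
}

#' Detect the walking segment from the belt log
#'
#' The walking segment is the longest interval during which the belt speed
#' stays above `speed_threshold` for at least `debounce_s` seconds; isolated
#' spikes shorter than the debounce are rejected.
#'
#' @param belt A [treadmill_log].
#' @param speed_threshold Belt speed threshold, m/s (default 0.2, far below
#'   any preferred walking speed).
#' @param debounce_s Minimum sustained duration, seconds (default 2).
#' @return Numeric `c(t_start, t_end)` of the walking segment.
#' @export
trim_nonwalking <- function(belt, speed_threshold = 0.2, debounce_s = 2) {
  moving <- belt$speed > speed_threshold
  if (!any(moving)) stop("no walking detected", call. = FALSE)
  r <- rle(moving)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  dur <- belt$timestamps[ends] - belt$timestamps[starts]
  ok <- which(r$values & dur >= debounce_s)
  if (!length(ok)) stop("no walking detected", call. = FALSE)
  best <- ok[which.max(dur[ok])]
  c(belt$timestamps[starts[best]], belt$timestamps[ends[best]])
}

#' Select the analysis window
#'
#' The analysis window is the last `length_s` seconds of the walking
#' segment; if the segment is shorter, the whole segment is used with a
#' warning.
#'
#' @param segment Numeric `c(t_start, t_end)` from [trim_nonwalking()].
#' @param length_s Target window length in seconds (default 120).
#' @return List with `t_start`, `t_end` and realized `length_s`, of class
#'   `analysis_window`.
#' @export
select_window <- function(segment, length_s = 120) {
  stopifnot(length(segment) == 2, segment[2] > segment[1])
  t_start <- segment[2] - length_s
  if (t_start < segment[1]) {
    warning(sprintf(
      "walking segment (%.1f s) shorter than requested window (%g s); clipped",
      diff(segment), length_s))
    t_start <- segment[1]
  }
  structure(list(t_start = t_start, t_end = segment[2],
                 length_s = segment[2] - t_start),
            class = "analysis_window")
}

#' Test whether times fall inside an analysis window
#'
#' @param t Numeric vector of times, seconds.
#' @param window An `analysis_window` from [select_window()].
#' @return Logical vector.
#' @export
in_window <- function(t, window) {
  t >= window$t_start & t <= window$t_end
}
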