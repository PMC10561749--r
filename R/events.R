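# Gait-event detection: initial contact (IC) and toe-off (TO), estimated
# independently from the skeleton stream (coordinate-based) and from the
# foot-mounted IMU's mediolateral angular velocity.

# drop the lesser-score member of any same-kind adjacent pair until the
# event sequence alternates IC/TO
enforce_alternation <- function(df) {
  df <- df[order(df$time), , drop = FALSE]
  repeat {
    if (nrow(df) < 2) break
    same <- which(df$kind[-1] == df$kind[-nrow(df)])
    if (!length(same)) break
    i <- same[1]
    drop <- if (isTRUE(df$score[i] < df$score[i + 1])) i else i + 1
    df <- df[-drop, , drop = FALSE]
  }
  df
}

# fractional-index -> time on a (uniform) timestamp grid
index_to_time <- function(ts, frac_idx) {
  lo <- pmax(1, pmin(length(ts) - 1, floor(frac_idx)))
  ts[lo] + (frac_idx - lo) * (ts[lo + 1] - ts[lo])
}

#' Detect gait events from the skeleton stream (coordinate-based)
#'
#' For each side the relative anteroposterior coordinate
#' `r(t) = Z_ankle(t) - Z_pelvis(t)` is evaluated inside the analysis
#' window. Initial contacts are the local maxima of `r` (foot most anterior
#' relative to the pelvis), toe-offs its local minima. Peaks are picked in
#' two passes: a rough pass estimates the median stride time from
#' high-prominence maxima, a constrained pass then enforces a minimum
#' inter-peak spacing of `spacing_frac` of that stride time. Event times are
#' refined to sub-frame precision with a three-point parabola, and the
#' IC/TO alternation is enforced by dropping the lesser-prominence member of
#' any same-kind pair.
#'
#' @param skel A filtered [skeleton_sequence].
#' @param window An `analysis_window` from [select_window()].
#' @param sides Sides to detect (default both).
#' @param ankle_joint Landmark driving the detector (default `"ANKLE"`;
#'   `"FOOT"` uses the toe).
#' @param min_prom_frac Prominence floor as a fraction of the half
#'   peak-to-peak amplitude of `r`.
#' @param spacing_frac Minimum peak spacing as a fraction of the median
#'   stride time.
#' @param min_amplitude Minimum half amplitude of `r` (m) for the signal to
#'   count as walking.
#' @return A [gait_events] table with `source = "KINEMATIC"`.
#' @export
detect_events_kinematic <- function(skel, window,
                                    sides = c("LEFT", "RIGHT"),
                                    ankle_joint = "ANKLE",
                                    min_prom_frac = 0.3,
                                    spacing_frac = 0.5,
                                    min_amplitude = 0.05) {
  sel <- which(in_window(skel$timestamps, window))
  if (length(sel) < 10) stop("insufficient gait cycles", call. = FALSE)
  ts <- skel$timestamps[sel]
  pelvis_z <- skel$joints$PELVIS[sel, 3]
  out <- NULL
  for (sd in sides) {
    joint <- paste0(ankle_joint, "_", substr(sd, 1, 1))
    if (is.null(skel$joints[[joint]])) {
      stop(sprintf("required joint %s missing", joint), call. = FALSE)
    }
    r <- skel$joints[[joint]][sel, 3] - pelvis_z
    amp <- diff(quantile(r, c(0.05, 0.95))) / 2
    if (!is.finite(amp) || amp < min_amplitude) {
      stop("insufficient gait cycles", call. = FALSE)
    }
    one_kind <- function(x, kind) {
      rough <- find_peaks(x, min_prominence = min_prom_frac * amp)
      if (nrow(rough) < 3) stop("insufficient gait cycles", call. = FALSE)
      stride_samples <- median(diff(rough$index))
      pk <- find_peaks(x, min_prominence = min_prom_frac * amp,
                       min_distance = max(1, round(spacing_frac *
                                                     stride_samples)))
      idx <- vapply(pk$index, refine_peak, numeric(1), x = x)
      data.frame(time = index_to_time(ts, idx), kind = kind,
                 score = pk$prominence)
    }
    ev <- rbind(one_kind(r, "IC"), one_kind(-r, "TO"))
    ev <- enforce_alternation(ev)
    if (sum(ev$kind == "IC") < 3) {
      stop("insufficient gait cycles", call. = FALSE)
    }
    out <- rbind(out, data.frame(ev, side = sd))
  }
  ev <- gait_events(out$time, out$side, out$kind, "KINEMATIC", out$score)
  validate_alternation(ev)
  ev
}

#' Detect gait events from a foot-mounted IMU
#'
#' Uses the mediolateral angular velocity of the foot. Dominant positive
#' mid-swing peaks are found with a prominence floor of `min_prom_frac`
#' times the median swing-peak height and a minimum spacing of
#' `spacing_frac` of the median stride time. For each swing peak, initial
#' contact is the first local minimum of the angular velocity after the
#' peak and toe-off the last local minimum before it (pre-swing minimum
#' convention).
#'
#' @param foot A filtered [imu_recording] from site `FOOT_L` or `FOOT_R`.
#' @param window An `analysis_window`.
#' @param ml_axis Gyro column carrying the mediolateral axis (1-3).
#' @param ml_sign +1 or -1, declared sensor mounting sign.
#' @param min_prom_frac Swing-peak prominence floor (fraction of median
#'   swing-peak height).
#' @param spacing_frac Minimum swing-peak spacing (fraction of median
#'   stride time).
#' @param min_dip_frac Prominence floor for the IC/TO minima (fraction of
#'   median swing-peak height).
#' @param min_peak_rate Minimum swing-peak angular velocity (rad/s) for the
#'   signal to count as walking.
#' @return A [gait_events] table with `source = "IMU"`.
#' @export
detect_events_imu <- function(foot, window, ml_axis = 1, ml_sign = 1,
                              min_prom_frac = 0.3, spacing_frac = 0.5,
                              min_dip_frac = 0.05, min_peak_rate = 0.5) {
  if (!foot$site %in% c("FOOT_L", "FOOT_R")) {
    stop("IMU event detection requires a foot-mounted recording",
         call. = FALSE)
  }
  if (!ml_axis %in% 1:3 || !ml_sign %in% c(-1, 1)) {
    stop("invalid mediolateral axis mapping", call. = FALSE)
  }
  side <- if (foot$site == "FOOT_L") "LEFT" else "RIGHT"
  sel <- which(in_window(foot$timestamps, window))
  if (length(sel) < 20) stop("insufficient gait cycles", call. = FALSE)
  ts <- foot$timestamps[sel]
  w <- ml_sign * foot$gyro[sel, ml_axis]

  rough <- find_peaks(w, min_prominence = min_peak_rate)
  rough <- rough[rough$value >= min_peak_rate, , drop = FALSE]
  if (nrow(rough) < 3) stop("insufficient gait cycles", call. = FALSE)
  med_h <- median(rough$value)
  stride_samples <- median(diff(rough$index))
  peaks <- find_peaks(w, min_prominence = min_prom_frac * med_h,
                      min_distance = max(1, round(spacing_frac *
                                                    stride_samples)))
  peaks <- peaks[peaks$value >= min_prom_frac * med_h, , drop = FALSE]
  if (nrow(peaks) < 2) stop("insufficient gait cycles", call. = FALSE)

  dips <- find_peaks(-w, min_prominence = min_dip_frac * med_h)
  ev <- NULL
  bounds <- c(0L, peaks$index, length(w) + 1L)
  for (i in seq_len(nrow(peaks))) {
    p <- peaks$index[i]
    before <- dips[dips$index > bounds[i] & dips$index < p, , drop = FALSE]
    after <- dips[dips$index > p & dips$index < bounds[i + 2], ,
                  drop = FALSE]
    if (nrow(before)) {
      j <- before$index[nrow(before)] # last minimum before the swing peak
      ev <- rbind(ev, data.frame(
        time = index_to_time(ts, refine_peak(-w, j)), kind = "TO",
        score = before$prominence[nrow(before)]))
    }
    if (nrow(after)) {
      j <- after$index[1] # first minimum after the swing peak
      ev <- rbind(ev, data.frame(
        time = index_to_time(ts, refine_peak(-w, j)), kind = "IC",
        score = after$prominence[1]))
    }
  }
  if (is.null(ev) || sum(ev$kind == "IC") < 3) {
    stop("insufficient gait cycles", call. = FALSE)
  }
  ev <- enforce_alternation(ev)
  ev <- gait_events(ev$time, side, ev$kind, "IMU", ev$score)
  validate_alternation(ev)
  ev
}

#' Pair consecutive initial contacts into strides
#'
#' Per side, consecutive ICs define strides (ipsilateral IC-to-IC). Each
#' stride carries its own toe-off and the contralateral IC/TO falling inside
#' it, needed for support times. Strides missing their own TO are flagged
#' (`complete = FALSE`): they keep stride time/length but are excluded from
#' support-time computation. Incomplete boundary strides are dropped.
#'
#' @param events A [gait_events] table from one source (both sides).
#' @return Data frame with one row per stride: `source`, `side`, `ic_time`,
#'   `next_ic_time`, `stride_time`, `to_time`, `contra_to`, `contra_ic`,
#'   `complete`.
#' @export
pair_strides <- function(events) {
  out <- NULL
  for (src in unique(events$source)) {
    e <- events[events$source == src, , drop = FALSE]
    for (sd in intersect(c("LEFT", "RIGHT"), unique(e$side))) {
      ic <- sort(e$time[e$side == sd & e$kind == "IC"])
      to <- sort(e$time[e$side == sd & e$kind == "TO"])
      other <- setdiff(c("LEFT", "RIGHT"), sd)
      c_ic <- sort(e$time[e$side == other & e$kind == "IC"])
      c_to <- sort(e$time[e$side == other & e$kind == "TO"])
      if (length(ic) < 2) next
      # half-open with a small tolerance so a contralateral TO coinciding
      # with the stride's own IC (duty factor exactly 0.5) still resolves
      first_in <- function(x, a, b) {
        hit <- x[x > a - 1e-9 & x < b - 1e-9]
        if (length(hit)) hit[1] else NA_real_
      }
      rows <- lapply(seq_len(length(ic) - 1), function(k) {
        a <- ic[k]; b <- ic[k + 1]
        own_to <- first_in(to, a, b)
        cto <- first_in(c_to, a, b)
        cic <- if (is.na(cto)) NA_real_ else first_in(c_ic, cto, b)
        data.frame(source = src, side = sd, ic_time = a, next_ic_time = b,
                   stride_time = b - a, to_time = own_to, contra_to = cto,
                   contra_ic = cic, complete = !is.na(own_to))
      })
      out <- rbind(out, do.call(rbind, rows))
    }
  }
  if (is.null(out)) {
    out <- data.frame(source = character(0), side = character(0),
                      ic_time = numeric(0), next_ic_time = numeric(0),
                      stride_time = numeric(0), to_time = numeric(0),
                      contra_to = numeric(0), contra_ic = numeric(0),
                      complete = logical(0))
  }
  out[order(out$source, out$ic_time), , drop = FALSE]
}
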