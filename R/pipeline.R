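# End-to-end dual-modality analysis of a single trial: filtering, window
# selection, event detection per modality, per-stride parameters and the
# window summary row for each source.

# match per-IC values (step width, MoS) onto stride rows by side + IC time
match_ic_values <- function(strides, ic_df, column, tol = 0.05) {
  vapply(seq_len(nrow(strides)), function(i) {
    cand <- which(ic_df$side == strides$side[i] &
                    abs(ic_df$time - strides$ic_time[i]) < tol)
    if (length(cand)) ic_df[[column]][cand[1]] else NA_real_
  }, numeric(1))
}

#' Analyse one treadmill trial with both modalities
#'
#' Runs the full pipeline: low-pass filtering (skeleton 6 Hz 1st order, IMU
#' 10 Hz 4th order, zero-phase), walking-segment trimming from the belt
#' log, selection of the last `window_s` seconds of walking, independent
#' event detection from the skeleton and from the foot IMUs, stride
#' pairing, and all gait parameters per stride and averaged over the
#' window.
#'
#' The kinematic source contributes stride time/length, support times,
#' step width, margin of stability and arm swing (cosine theorem); the IMU
#' source contributes stride time/length, support times and arm swing
#' (wrist gyro integration). Parameters a source cannot measure are NA in
#' its rows.
#'
#' @param skeleton A [skeleton_sequence] (raw; filtered internally).
#' @param imus Named list of [imu_recording]s including `FOOT_L`, `FOOT_R`
#'   (and `WRIST_L`, `WRIST_R` for arm swing).
#' @param belt A [treadmill_log].
#' @param meta Optional [participant_meta]; supplies the participant id and
#'   the pendulum length (otherwise estimated from the data).
#' @param window_s Analysis window length, s (default 120).
#' @param dedrift Dedrift the IMU swing-velocity integration (default
#'   TRUE).
#' @return List of class `trial_analysis`: `window`, `events`,
#'   `stride_table` (per-stride parameters, both sources), `summary` (one
#'   summary row per source), `arm_swing`, `pendulum_length_m`.
#' @export
analyze_trial <- function(skeleton, imus, belt, meta = NULL, window_s = 120,
                          dedrift = TRUE) {
  skel_f <- filter_skeleton(skeleton)
  imus_f <- lapply(imus, filter_imu)
  segment <- trim_nonwalking(belt)
  window <- select_window(segment, window_s)
  pid <- if (is.null(meta)) "P1" else meta$id

  ev_kin <- detect_events_kinematic(skel_f, window)
  ev_imu_l <- detect_events_imu(imus_f$FOOT_L, window)
  ev_imu_r <- detect_events_imu(imus_f$FOOT_R, window)
  ev_imu <- gait_events(c(ev_imu_l$time, ev_imu_r$time),
                        c(ev_imu_l$side, ev_imu_r$side),
                        c(ev_imu_l$kind, ev_imu_r$kind), "IMU",
                        c(ev_imu_l$score, ev_imu_r$score))
  events <- gait_events(c(ev_kin$time, ev_imu$time),
                        c(ev_kin$side, ev_imu$side),
                        c(ev_kin$kind, ev_imu$kind),
                        c(ev_kin$source, ev_imu$source),
                        c(ev_kin$score, ev_imu$score))

  # ---- kinematic source --------------------------------------------------
  st_kin <- pair_strides(ev_kin)
  sup_kin <- support_times(st_kin)
  sw <- step_width(skel_f, ev_kin)
  leg <- if (!is.null(meta)) meta$leg_length
         else estimate_pendulum_length(skel_f, ev_kin)
  mos <- margin_of_stability(skel_f, ev_kin, mos_params(leg))
  arm_kin <- arm_swing_kinematic(skel_f, window)
  tab_kin <- data.frame(
    source = "KINEMATIC", side = st_kin$side, ic_time = st_kin$ic_time,
    stride_time = st_kin$stride_time,
    stride_length = stride_length_kinematic(skel_f, st_kin, belt),
    single_support = sup_kin$single_support,
    double_support = sup_kin$double_support,
    step_width = match_ic_values(st_kin, sw, "step_width"),
    mos_ml = match_ic_values(st_kin, mos, "mos_ml"),
    mos_ap = match_ic_values(st_kin, mos, "mos_ap")
  )
  arm_kin_list <- list(LEFT = arm_kin$amplitude_deg[arm_kin$side == "LEFT"],
                       RIGHT = arm_kin$amplitude_deg[arm_kin$side == "RIGHT"])
  sum_kin <- summarize_window(tab_kin, window, pid, "KINEMATIC",
                              arm_swing = arm_kin_list,
                              cadence = cadence(ev_kin, window))

  # ---- IMU source --------------------------------------------------------
  st_imu <- pair_strides(ev_imu)
  sup_imu <- support_times(st_imu)
  sl_imu <- rep(NA_real_, nrow(st_imu))
  for (site in c("FOOT_L", "FOOT_R")) {
    side <- if (site == "FOOT_L") "LEFT" else "RIGHT"
    rows <- which(st_imu$side == side)
    if (length(rows)) {
      sl_imu[rows] <- stride_length_imu(imus_f[[site]], st_imu, belt,
                                        dedrift = dedrift)
    }
  }
  arm_imu_list <- list(
    LEFT = if (!is.null(imus_f$WRIST_L))
      arm_swing_imu(imus_f$WRIST_L, window) else NA_real_,
    RIGHT = if (!is.null(imus_f$WRIST_R))
      arm_swing_imu(imus_f$WRIST_R, window) else NA_real_
  )
  tab_imu <- data.frame(
    source = "IMU", side = st_imu$side, ic_time = st_imu$ic_time,
    stride_time = st_imu$stride_time,
    stride_length = sl_imu,
    single_support = sup_imu$single_support,
    double_support = sup_imu$double_support,
    step_width = NA_real_, mos_ml = NA_real_, mos_ap = NA_real_
  )
  sum_imu <- summarize_window(tab_imu, window, pid, "IMU",
                              arm_swing = arm_imu_list,
                              cadence = cadence(ev_imu, window))

  structure(
    list(window = window, events = events,
         stride_table = rbind(tab_kin, tab_imu),
         summary = rbind(sum_kin, sum_imu),
         arm_swing = list(KINEMATIC = arm_kin_list, IMU = arm_imu_list),
         pendulum_length_m = leg),
    class = "trial_analysis"
  )
}

#' @export
print.trial_analysis <- function(x, ...) {
  cat(sprintf("<trial_analysis> window [%.1f, %.1f] s\n",
              x$window$t_start, x$window$t_end))
  print(x$summary, digits = 4, row.names = FALSE)
  invisible(x)
}
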