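#!/usr/bin/env Rscript
# Simulate one exemplar treadmill trial (3 s standing bookends, belt ramp,
# 126 s steady walking at 1.05 m/s) and write the three device streams in
# their on-disk dialects plus the ground truth. This is the raw material
# for the dual-modality pipeline in 02_dual_pipeline.R.

suppressMessages(library(gaitagree))

out_dir <- "results/trial_example"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

profile <- gait_profile() # typical older adult, realistic device noise
trial <- simulate_trial(profile, duration_walk = 126, seed = 42)

write_skeleton(trial$skeleton, file.path(out_dir, "skeleton.csv"))
for (site in names(trial$imus)) {
  write_imu(trial$imus[[site]], file.path(out_dir, paste0("imu_", site, ".csv")))
}
write_treadmill(trial$belt, file.path(out_dir, "belt.csv"))
jsonlite::write_json(
  list(ic_times = trial$truth$ic_times, to_times = trial$truth$to_times,
       step_width = trial$truth$step_width,
       arm_swing_deg = as.list(trial$truth$arm_swing_deg),
       stride_times = trial$truth$stride_times),
  file.path(out_dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)

message(sprintf(
  "simulated %.0f s trial: %d skeleton frames, %d IMU samples x 6 sites, %d belt samples",
  trial$timeline$end, length(trial$skeleton$timestamps),
  length(trial$imus$FOOT_L$timestamps), length(trial$belt$timestamps)))
message(sprintf("ground truth: %d right strides, mean stride time %.3f s",
                length(trial$truth$stride_times),
                mean(trial$truth$stride_times)))
message("streams written to ", out_dir)
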