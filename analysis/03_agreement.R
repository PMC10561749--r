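#!/usr/bin/env Rscript
# Method agreement across the synthetic cohort: per-parameter normality,
# paired t-tests, convergent-validity correlations and Bland-Altman limits
# of agreement (differences as IMU minus depth-camera), mirroring how a
# validation study compares the two systems. Writes the report table and
# per-parameter scatter data; renders Bland-Altman figures when ggplot2 is
# available.

suppressMessages(library(gaitagree))

summaries <- read.csv("results/cohort_summaries.csv")
rep_ <- full_report(summaries)
print(rep_)

tables <- list(agreement_report = rep_$report)
for (par in names(rep_$bland_altman)) {
  ba <- merge(rep_$bland_altman[[par]],
              summaries[summaries$source == "KINEMATIC",
                        c("participant", "group")], by = "participant")
  tables[[paste0("bland_altman_", par)]] <- ba
  tables[[paste0("correlation_", par)]] <- rep_$correlation[[par]]
}
write_results(tables, "results")
message(sprintf("wrote agreement report for %d parameters to results/",
                nrow(rep_$report)))

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  dir.create("results/figures", showWarnings = FALSE)
  for (par in c("stride_length_m", "stride_time_s")) {
    row <- rep_$report[rep_$report$parameter == par, ]
    if (!nrow(row)) next
    ba <- tables[[paste0("bland_altman_", par)]]
    gg <- ggplot(ba, aes(mean, diff, shape = group)) +
      geom_point(size = 2) +
      geom_hline(yintercept = row$mean_diff) +
      geom_hline(yintercept = c(row$loa_low, row$loa_high),
                 linetype = "dotted") +
      scale_shape_manual(values = c(FALLER = 17, NON_FALLER = 1)) +
      labs(x = paste("mean of methods,", par),
           y = "difference (IMU - depth camera)",
           title = sprintf("Bland-Altman: %s (n = %d)", par, row$n)) +
      theme_minimal()
    ggsave(sprintf("results/figures/bland_altman_%s.pdf", par), gg,
           width = 6, height = 4)
  }
  message("figures in results/figures/")
}
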