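#!/usr/bin/env Rscript
# Step 2 — MVIC torque extraction from synthetic dynamometry.
#
# For each subject and knee configuration (75 and 90 deg), three maximal
# trapezoidal contractions are generated as a raw voltage trace (so the
# vendor volts-to-Nm conversion is exercised), then processed with the
# published chain: 20 Hz zero-phase Butterworth low-pass, conversion to Nm,
# noise-threshold segmentation (mu + 3 sigma of a contraction-free window),
# and 2 Hz-smoothed per-trial peak extraction; the MVIC is the maximum
# across trials. Trial-to-trial plateau variability of 2% and 2 Nm sensor
# noise are simulated.
#
# Output: results/mvic_per_subject.csv with extracted vs true MVIC.

suppressMessages(library(biomechkit))
subjects <- read.csv("results/cohort_subjects.csv")
set.seed(2)

params <- segmentation_params(noise_window = c(400, 3600))

rows <- do.call(rbind, lapply(seq_len(nrow(subjects)), function(i) {
  s <- subjects[i, ]
  do.call(rbind, lapply(c(75, 90), function(angle) {
    true_mvic <- if (angle == 75) s$mvic_75_nm else s$mvic_90_nm
    plateaus <- true_mvic * (1 - abs(rnorm(3, 0, 0.02)))
    plateaus[sample(3, 1)] <- true_mvic   # best trial hits the true maximum
    g <- gen_mvic_trace(n_trials = 3, plateau_nm = plateaus, noise_sd = 2,
                        units = "V", seed = sample.int(2^31 - 1, 1))
    res <- mvic_pipeline(g$signal, params, knee_angle_deg = angle)
    data.frame(id = s$id, cohort = s$cohort, knee_angle_deg = angle,
               n_trials = nrow(res$windows),
               mvic_true_nm = true_mvic,
               mvic_extracted_nm = res$mvic$mvic_nm,
               retest_flag = res$mvic$retest_flag)
  }))
}))

write.csv(rows, "results/mvic_per_subject.csv", row.names = FALSE)

rel_err <- abs(rows$mvic_extracted_nm / rows$mvic_true_nm - 1)
cat(sprintf("Extracted MVIC for %d subject-configurations.\n", nrow(rows)))
cat(sprintf("Recovery error: median %.2f%%, max %.2f%% (all trials segmented: %s)\n",
            100 * median(rel_err), 100 * max(rel_err),
            all(rows$n_trials == 3)))
cat("Written: results/mvic_per_subject.csv\n")
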