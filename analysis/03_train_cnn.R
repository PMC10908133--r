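#!/usr/bin/env Rscript
# Stage 3 — the serotonin:dopamine ratio CNN.
# Builds the convex-mixture training set from the synthetic cohort, trains
# the 11-layer CNN at the reduced profile (~3 min on one CPU), evaluates the
# held-out RMSE and the pure-analyte endpoints, and emulates the
# post-levodopa experiment as a mixture-ratio ramp from 1 to 0.6 over
# 120 min.

suppressPackageStartupMessages(library(serovolt))
seed <- 1
dir.create("results", showWarnings = FALSE)

prof <- experiment_profile("test")
bundle <- run_experiment(prof, seed = seed, out_dir = NULL, stages = "cnn")

write.csv(bundle$cnn_history, "results/cnn_history.csv", row.names = FALSE)
write.csv(bundle$cnn_eval, "results/cnn_eval.csv", row.names = FALSE)
write.csv(bundle$ldopa_ratio_timecourse, "results/cnn_ldopa_timecourse.csv",
          row.names = FALSE)
write.csv(bundle$ldopa_ratio_slope, "results/cnn_ldopa_slope.csv",
          row.names = FALSE)

ev <- bundle$cnn_eval
cat(sprintf("held-out RMSE %.3f | pure serotonin mean %.3f | pure dopamine mean %.3f\n",
            ev$test_rmse, ev$pure_serotonin_mean, ev$pure_dopamine_mean))
sl <- bundle$ldopa_ratio_slope
cat(sprintf("post-levodopa predicted ratio slope %.4g /min (generating ramp %.4g /min)\n",
            sl$slope_per_min, sl$true_slope_per_min))
cat("wrote cnn_history.csv, cnn_eval.csv, cnn_ldopa_timecourse.csv, cnn_ldopa_slope.csv\n")
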