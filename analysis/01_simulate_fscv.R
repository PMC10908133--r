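#!/usr/bin/env Rscript
# Stage 1 — synthetic raw data.
# Generates the source color-plot cohort (28 hippocampal serotonin plots from
# 7 animals, 21 striatal dopamine plots from 3 animals) at the reduced
# profile, plus the ambient-serotonin (FSCAV) series for both groups, and
# summarises every evoked trace (Amp_max, Simpson AUC, decay half-life).

suppressPackageStartupMessages(library(serovolt))
seed <- 1
dir.create("results", showWarnings = FALSE)

prof <- experiment_profile("test")
bundle <- run_experiment(prof, seed = seed, out_dir = "results",
                         stages = "fscv")
tm <- bundle$trace_metrics
cat(sprintf("generated %d serotonin and %d dopamine color plots (%dx%d)\n",
            sum(tm$analyte == "serotonin"), sum(tm$analyte == "dopamine"),
            prof$n_rows, prof$n_frames))
by_an <- aggregate(amp_max_nM ~ analyte, tm, mean)
cat(sprintf("mean evoked amplitude: serotonin %.2f nM, dopamine %.1f nM\n",
            by_an$amp_max_nM[by_an$analyte == "serotonin"],
            by_an$amp_max_nM[by_an$analyte == "dopamine"]))

# ambient serotonin series, one per group, written as CSV
for (g in c("control", "mptp")) {
  ser <- generate_fscav_series(g, seed = seed + match(g, c("control", "mptp")))
  write_fscav_series(ser, file.path("results", paste0("fscav_", g, ".csv")))
  sl <- fscav_epoch_slopes(ser)
  cat(sprintf("%s FSCAV: baseline ~%.1f nM, post-SSRI slope %.3f nM/min\n",
              g, mean(ser$concentration[1:30]),
              sl$slope[sl$label == "escit"]))
}

# one compact example plot of each analyte in the CSV + JSON dialect
ch <- generate_fixture_cohort(seed = serovolt:::child_seed(seed, 1),
                              n_rows = 24, n_frames = 40, t0_stim = 1)
write_color_plot(ch$serotonin[[1]], "results/example_serotonin_plot.csv")
write_color_plot(ch$dopamine[[1]], "results/example_dopamine_plot.csv")
cat("wrote trace_metrics.csv, fscav_*.csv and two example plots under results/\n")
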