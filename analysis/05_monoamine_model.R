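#!/usr/bin/env Rscript
# Stage 5 — the serotonin-dopamine projection model.
# Calibrates the reduced DRN/hippocampus model (35 nM serotonin and
# 0.000968 uM DRN serotonin at full SNc survival; escitalopram input solved
# for 50% peak SERT occupancy), then runs the three in silico experiments:
# the degeneration sweep, escitalopram at f = 1 vs f = 0.35 (MPTP), and
# levodopa dopamine pulses across survival fractions.

suppressPackageStartupMessages(library(serovolt))
dir.create("results", showWarnings = FALSE)

params <- calibrate_monoamine()
cat(sprintf("calibrated gains: synthesis %.1f nM/h, DA release %.1f nM/h, escitalopram I0 %.3f\n",
            params$synthesis, params$da_release, params$escit_I0))

bundle <- run_experiment(experiment_profile("test"), seed = 1,
                         stages = "ode")
write.csv(bundle$degeneration, "results/degeneration_sweep.csv",
          row.names = FALSE)
write.csv(bundle$escit_model, "results/escit_model_timecourse.csv",
          row.names = FALSE)
write.csv(bundle$ldopa_amplitudes, "results/ldopa_amplitudes.csv",
          row.names = FALSE)

sw <- bundle$degeneration
cat(sprintf("relative hippocampal serotonin: %.1f%% at f=0.4, %.1f%% at f=0.3\n",
            sw$serotonin_rel[sw$f == 0.4], sw$serotonin_rel[sw$f == 0.3]))
cat(sprintf("dopamine homeostasis: %.0f%% of normal at f=0.2\n",
            sw$dopamine_rel[sw$f == 0.2]))
esc <- bundle$escit_model
cat(sprintf("SSRI response: control %.1f -> %.1f nM, MPTP %.1f -> %.1f nM (peak occupancy %.1f%%)\n",
            esc$control_nM[1], max(esc$control_nM),
            esc$mptp_nM[1], max(esc$mptp_nM), 100 * max(esc$occupancy)))
amp <- bundle$ldopa_amplitudes
cat(sprintf("levodopa dopamine pulse: %.1f nM at f=0.2 vs %.1f nM at f=1 (non-monotone in f)\n",
            amp$amplitude_nM[amp$f == 0.2], amp$amplitude_nM[amp$f == 1]))
cat("wrote degeneration_sweep.csv, escit_model_timecourse.csv, ldopa_amplitudes.csv\n")
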