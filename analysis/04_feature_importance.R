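#!/usr/bin/env Rscript
# Stage 4 — which color-plot samples matter.
# Randomisation-based feature importance of the ratio CNN at a compact scale
# (small plots, 3 training repetitions, 2x2 blocks; the full-scale procedure
# uses 15 repetitions). After each training, every input block is replaced by
# U(-1, 1) noise across an evaluation set and the RMSE inflation is recorded.

suppressPackageStartupMessages(library(serovolt))
seed <- 1
dir.create("results", showWarnings = FALSE)

cohort <- generate_fixture_cohort(seed = serovolt:::child_seed(seed, 1),
                                  n_rows = 32, n_frames = 50, t0_stim = 1)
mixtures <- generate_training_set(cohort$serotonin, cohort$dopamine,
                                  n_total = 400,
                                  seed = serovolt:::child_seed(seed, 4))
cfg <- cnn_config(input_dim = c(32, 50), conv_features = c(8, 4),
                  dense_units = c(16, 8))
tc <- training_config(learning_rate = 1e-3, epochs = 40, batch_size = 30,
                      steps_per_epoch = NULL, validation_steps = NULL)
train_fn <- function(dataset, s) train_cnn(dataset, cfg, tc, seed = s)

imp <- feature_importance(mixtures, train_fn, n_rep = 3, block = c(2, 2),
                          n_eval = 80, seed = seed)
write.csv(imp$importance, "results/importance_map.csv", row.names = FALSE)

axis <- cohort$serotonin[[1]]$potential_axis
row_score <- rowMeans(imp$importance)
top <- order(row_score, decreasing = TRUE)[1:5]
cat(sprintf("most informative potentials: %s V\n",
            paste(sprintf("%.2f", sort(axis[top])), collapse = ", ")))
cat(sprintf("serotonin oxidation centre 0.65 V, dopamine 0.45 V; max row score %.2f at %.2f V\n",
            max(row_score), axis[which.max(row_score)]))
cat("wrote importance_map.csv\n")
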