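#' Experiment profiles
#'
#' Two code-identical scales for the workflow. The \code{"full"}
#' profile matches the study's scale: 220 x 300 color plots (30 s at 10 Hz),
#' 5000 mixtures per animal, the full-width CNN (275 + 100 convolution
#' features) trained for 500 epochs with the 4-step/5-validation-step caps.
#' The \code{"test"} profile is the reduced desk scale used by the test
#' suite: 64 x 100 plots, 1000 mixtures, a narrow CNN (16 + 8 features,
#' 32 + 16 dense units) trained 100 epochs under the same step caps.
#'
#' @param name \code{"full"} or \code{"test"}.
#' @return List of profile settings: plot dims, stimulation onset, mixture
#'   counts, [cnn_config()] and [training_config()].
#' @export
experiment_profile <- function(name = c("test", "full")) {
  name <- match.arg(name)
  if (name == "full") {
    list(
      name = "full", n_rows = 220L, n_frames = 300L, t0_stim = 5,
      n_per_animal = 5000L, n_total = NULL,
      cnn = cnn_config(input_dim = c(220, 300), conv_features = c(275, 100),
                       dense_units = c(128, 64)),
      training = training_config(epochs = 500, steps_per_epoch = 4,
                                 validation_steps = 5)
    )
  } else {
    list(
      name = "test", n_rows = 64L, n_frames = 100L, t0_stim = 2,
      n_per_animal = 5000L, n_total = 1000L,
      cnn = cnn_config(input_dim = c(64, 100), conv_features = c(16, 8),
                       dense_units = c(32, 16)),
      training = training_config(epochs = 100, steps_per_epoch = 4,
                                 validation_steps = 5)
    )
  }
}

profile_cohort <- function(profile, seed) {
  generate_fixture_cohort(seed = seed, n_rows = profile$n_rows,
                          n_frames = profile$n_frames,
                          t0_stim = profile$t0_stim)
}

profile_training_set <- function(profile, cohort, seed) {
  generate_training_set(cohort$serotonin, cohort$dopamine,
                        n_per_animal = profile$n_per_animal,
                        n_total = profile$n_total, seed = seed)
}

# standardized pure source plots stacked into an array for CNN evaluation
stack_plots <- function(plots) {
  std <- lapply(plots, function(p)
    if (isTRUE(p$meta$standardized)) p else standardize_plot(p))
  d <- dim(std[[1]]$current)
  arr <- array(0, c(d, length(std)))
  for (k in seq_along(std)) arr[, , k] <- std[[k]]$current
  arr
}

#' Run the full synthetic workflow
#'
#' Chains the stages of the study's computational pipeline on synthetic
#' data: source-cohort generation and trace metrics (\code{"fscv"}),
#' Michaelis-Menten fitting of the group-average trace and the FSCAV
#' summary (\code{"kinetics"}), CNN training with endpoint evaluation and a
#' levodopa-like ratio-ramp prediction (\code{"cnn"}), and the
#' degeneration / escitalopram / levodopa model experiments (\code{"ode"}).
#' All outputs are data.frames, optionally written as CSV under
#' \code{out_dir} together with a metadata JSON (seed, profile, settings).
#'
#' @param profile An [experiment_profile()] (or its name).
#' @param seed Integer master seed.
#' @param out_dir Optional output directory for CSV tables.
#' @param stages Character subset of
#'   \code{c("fscv", "kinetics", "cnn", "ode")}.
#' @return Named list of result tables (a report bundle), with the trained
#'   CNN fit attached as \code{cnn_fit} when the CNN stage ran.
#' @export
run_experiment <- function(profile = experiment_profile("test"), seed = 1,
                           out_dir = NULL,
                           stages = c("fscv", "kinetics", "cnn", "ode")) {
  if (is.character(profile)) profile <- experiment_profile(profile)
  stop_if(!all(stages %in% c("fscv", "kinetics", "cnn", "ode")),
          "unknown stage name")
  bundle <- list()
  cohort <- NULL

  if (any(c("fscv", "kinetics", "cnn") %in% stages)) {
    cohort <- profile_cohort(profile, child_seed(seed, 1))
  }

  if ("fscv" %in% stages) {
    rows <- lapply(c(cohort$serotonin, cohort$dopamine), function(p) {
      tr <- extract_trace(p, if (p$meta$analyte == "serotonin") 0.65 else 0.45)
      data.frame(id = p$meta$id, analyte = p$meta$analyte,
                 animal = p$meta$animal,
                 amp_max_nM = peak_amplitude(tr),
                 auc_nMs = auc_simpson(tr),
                 t_half_s = tryCatch(half_life(tr), error = function(e) NA))
    })
    bundle$trace_metrics <- do.call(rbind, rows)
  }

  if ("kinetics" %in% stages) {
    traces <- lapply(cohort$serotonin, extract_trace, potential = 0.65)
    avg <- rowMeans(vapply(traces, `[[`, numeric(length(traces[[1]]$time)),
                           "concentration"))
    avg_trace <- evoked_trace(traces[[1]]$time, avg,
                              stim_window = traces[[1]]$stim_window)
    # fit on the post-onset segment, the model's domain
    post <- avg_trace$time >= avg_trace$stim_window[1]
    fit_trace <- evoked_trace(
      avg_trace$time[post] - avg_trace$stim_window[1],
      avg_trace$concentration[post], stim_window = c(0, 2))
    fit <- fit_mm(fit_trace)
    bundle$mm_fit <- data.frame(
      vmax1 = fit$params$vmax1, km1 = fit$params$km1,
      rmax = fit$params$rmax, residual_norm = fit$residual_norm,
      iterations = fit$iterations, converged = fit$converged)
    ser_ctrl <- generate_fscav_series("control", seed = child_seed(seed, 2))
    ser_mptp <- generate_fscav_series("mptp", seed = child_seed(seed, 3))
    means <- fscav_reference_means()
    summ <- escit_effect_summary(setNames(means$before, means$group),
                                 setNames(means$after, means$group),
                                 series = ser_ctrl)
    bundle$fscav_differences <- summ$differences
    bundle$fscav_slopes_control <- summ$slopes
    bundle$fscav_slopes_mptp <- fscav_epoch_slopes(ser_mptp)
  }

  if ("cnn" %in% stages) {
    mixtures <- profile_training_set(profile, cohort, child_seed(seed, 4))
    fit <- train_cnn(mixtures, profile$cnn, profile$training,
                     seed = child_seed(seed, 5))
    test_pred <- predict_ratio(fit$model, mixtures$x[, , fit$test, drop = FALSE])
    pure_ser <- predict_ratio(fit$model, stack_plots(cohort$serotonin))
    pure_dop <- predict_ratio(fit$model, stack_plots(cohort$dopamine))
    bundle$cnn_history <- fit$history
    bundle$cnn_eval <- data.frame(
      test_rmse = evaluate_rmse(test_pred, mixtures$ratio[fit$test]),
      pure_serotonin_mean = mean(pure_ser),
      pure_dopamine_mean = mean(pure_dop))
    # levodopa emulation: ratio ramps 1 -> 0.6 over 120 min
    ramp <- ldopa_ramp_predictions(fit$model, cohort,
                                   seed = child_seed(seed, 6))
    bundle$ldopa_ratio_timecourse <- ramp
    bundle$ldopa_ratio_slope <- data.frame(
      slope_per_min = ratio_timecourse_slope(ramp),
      true_slope_per_min = (0.6 - 1) / 120)
    bundle$cnn_fit <- fit
  }

  if ("ode" %in% stages) {
    params <- calibrate_monoamine()
    bundle$degeneration <- degeneration_sweep(seq(0.1, 1, by = 0.1), params)
    esc <- simulate_escit_experiment(f = 1, params = params)
    esc_mptp <- simulate_escit_experiment(f = 0.35, params = params)
    bundle$escit_model <- data.frame(
      time_min = esc$time_min, control_nM = esc$serotonin_nM,
      mptp_nM = esc_mptp$serotonin_nM, occupancy = esc$occupancy)
    amps <- vapply(c(0.05, 0.2, 1), function(f)
      attr(simulate_ldopa(f, params = params), "amplitude"), numeric(1))
    bundle$ldopa_amplitudes <- data.frame(f = c(0.05, 0.2, 1),
                                          amplitude_nM = amps)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in setdiff(names(bundle), "cnn_fit")) {
      utils::write.csv(bundle[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    }
    jsonlite::write_json(
      list(seed = seed, profile = profile$name, stages = stages,
           n_rows = profile$n_rows, n_frames = profile$n_frames),
      file.path(out_dir, "metadata.json"), auto_unbox = TRUE)
  }
  bundle
}

# Predict the serotonin:dopamine ratio over an emulated post-levodopa series
# in which the generating mixture ratio ramps linearly from 1 to 0.6 over
# 120 min. Several mixtures are averaged per time point.
ldopa_ramp_predictions <- function(model, cohort, n_per_time = 8,
                                   time_min = seq(0, 120, by = 10),
                                   ratio_from = 1, ratio_to = 0.6,
                                   seed = 1) {
  ser <- lapply(cohort$serotonin, standardize_plot)
  dop <- lapply(cohort$dopamine, standardize_plot)
  true_r <- ratio_from + (ratio_to - ratio_from) * time_min / max(time_min)
  preds <- with_seed(seed, vapply(seq_along(time_min), function(k) {
    ia <- sample.int(length(ser), n_per_time, replace = TRUE)
    ib <- sample.int(length(dop), n_per_time, replace = TRUE)
    mean(vapply(seq_len(n_per_time), function(j) {
      mx <- mix_plots(ser[[ia[j]]], dop[[ib[j]]], true_r[k])
      predict_ratio(model, mx$plot)
    }, numeric(1)))
  }, numeric(1)))
  data.frame(time = time_min, ratio = preds, true_ratio = true_r)
}

#' Acceptance-check table over the workflow's quantitative anchors
#'
#' Recomputes the workflow's headline quantities from scratch and compares
#' each against its reference value: the printed-arithmetic checks (SERT
#' Vmax1 percent decrease after escitalopram, ambient-serotonin increases,
#' the current-to-concentration factor), the kinetic parameter recovery on a
#' noiseless self-generated trace, the model calibration anchors (35 nM
#' baseline, 50% peak occupancy), the degeneration-sweep brackets, and -
#' when a trained CNN is supplied or \code{run_cnn = TRUE} - the pure-analyte
#' prediction endpoints. Failures are rows with \code{pass = FALSE}, never
#' exceptions; checks that were not run carry \code{NA}.
#'
#' @param profile An [experiment_profile()] or name.
#' @param seed Integer seed.
#' @param cnn_fit Optional result of [train_cnn()] (reused instead of
#'   retraining); its cohort must come from the same seed.
#' @param run_cnn Train the CNN if no fit is supplied (slow).
#' @param out_csv Optional path for the CSV table.
#' @return data.frame with one row per check: \code{check},
#'   \code{value}, \code{expected}, \code{cmp}, \code{tol}, \code{pass}.
#' @export
run_acceptance <- function(profile = experiment_profile("test"), seed = 1,
                           cnn_fit = NULL, run_cnn = FALSE, out_csv = NULL) {
  if (is.character(profile)) profile <- experiment_profile(profile)
  rows <- list()
  add <- function(check, value, expected, cmp, tol) {
    pass <- if (is.na(value)) NA else switch(cmp,
      eq = abs(value - expected) <= tol,
      ge = value >= expected,
      le = value <= expected)
    rows[[length(rows) + 1]] <<- data.frame(
      check = check, value = value, expected = expected, cmp = cmp,
      tol = tol, pass = pass)
  }

  ref <- mm_reference_params()
  pre <- ref[ref$group == "saline" & ref$phase == "pre", "vmax1"]
  post <- ref[ref$group == "saline" & ref$phase == "post_escit", "vmax1"]
  add("vmax1_decrease_control_pct", 100 * (1 - post / pre), 70, "eq", 0.5)

  means <- fscav_reference_means()
  summ <- escit_effect_summary(setNames(means$before, means$group),
                               setNames(means$after, means$group))
  d <- summ$differences
  add("fscav_increase_control_nM",
      d$difference[d$group == "control"], 32.69, "eq", 0.005)
  add("fscav_increase_mptp_nM",
      d$difference[d$group == "mptp"], 15.23, "eq", 0.005)

  mptp <- mm_group_params()$mptp
  tr <- simulate_mm(mptp, duration = 30, dt = 0.1)
  fit <- fit_mm(tr)
  add("mptp_vmax1_recovered_nM_s", fit$params$vmax1, 12.15, "eq",
      0.02 * 12.15)

  params <- calibrate_monoamine()
  eq <- simulate_steady_state(1, params)
  add("steady_state_serotonin_nM", eq$serotonin_nM, 35, "eq", 0.35)
  esc <- simulate_escit_experiment(f = 1, params = params)
  add("peak_sert_occupancy_pct", 100 * attr(esc, "peak_occupancy"), 50,
      "eq", 1)

  sweep <- degeneration_sweep(c(0.3, 0.4, 1), params)
  add("relative_serotonin_f040_pct",
      sweep$serotonin_rel[sweep$f == 0.4], 34, "ge", 0)
  add("relative_serotonin_f030_pct",
      sweep$serotonin_rel[sweep$f == 0.3], 43, "le", 0)

  add("calibration_nM_per_nA", current_to_concentration(1), 49.5, "eq", 1e-12)

  if (is.null(cnn_fit) && run_cnn) {
    cohort <- profile_cohort(profile, child_seed(seed, 1))
    mixtures <- profile_training_set(profile, cohort, child_seed(seed, 4))
    cnn_fit <- train_cnn(mixtures, profile$cnn, profile$training,
                         seed = child_seed(seed, 5))
  }
  if (!is.null(cnn_fit)) {
    cohort <- profile_cohort(profile, child_seed(seed, 1))
    pure_ser <- mean(predict_ratio(cnn_fit$model,
                                   stack_plots(cohort$serotonin)))
    pure_dop <- mean(predict_ratio(cnn_fit$model,
                                   stack_plots(cohort$dopamine)))
  } else {
    pure_ser <- NA_real_
    pure_dop <- NA_real_
  }
  add("cnn_pure_serotonin_mean", pure_ser, 1, "eq", 0.15)
  add("cnn_pure_dopamine_mean", pure_dop, 0, "eq", 0.15)

  out <- do.call(rbind, rows)
  if (!is.null(out_csv)) utils::write.csv(out, out_csv, row.names = FALSE)
  out
}
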