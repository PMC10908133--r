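# Shared fixtures, memoised so expensive objects are built once per run.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# small waveform profile used throughout the unit tests (16 x 20 plots)
tiny_spec <- function() waveform_spec()

tiny_cohort <- function() {
  cached("tiny_cohort",
         generate_fixture_cohort(seed = 11, n_rows = 16, n_frames = 20,
                                 t0_stim = 0.5))
}

tiny_mixtures <- function() {
  cached("tiny_mixtures", {
    ch <- tiny_cohort()
    generate_training_set(ch$serotonin, ch$dopamine, n_total = 240, seed = 5)
  })
}

tiny_cnn_config <- function() {
  cnn_config(input_dim = c(16, 20), conv_features = c(4, 3),
             dense_units = c(12, 6))
}

tiny_training_config <- function(epochs = 30) {
  training_config(learning_rate = 2e-3, epochs = epochs, batch_size = 30,
                  steps_per_epoch = NULL, validation_steps = NULL)
}

tiny_cnn_fit <- function() {
  cached("tiny_cnn_fit",
         train_cnn(tiny_mixtures(), tiny_cnn_config(), tiny_training_config(),
                   seed = 21))
}

calibrated_params <- function() {
  cached("monoamine_params", calibrate_monoamine())
}

# reduced-profile CNN training used by the acceptance endpoints (expensive;
# built at most once per test run)
acceptance_cnn <- function() {
  cached("acceptance_cnn", {
    prof <- experiment_profile("test")
    cohort <- generate_fixture_cohort(seed = serovolt:::child_seed(1, 1),
                                      n_rows = prof$n_rows,
                                      n_frames = prof$n_frames,
                                      t0_stim = prof$t0_stim)
    mixtures <- generate_training_set(cohort$serotonin, cohort$dopamine,
                                      n_total = prof$n_total,
                                      seed = serovolt:::child_seed(1, 4))
    fit <- train_cnn(mixtures, prof$cnn, prof$training,
                     seed = serovolt:::child_seed(1, 5))
    list(fit = fit, mixtures = mixtures, cohort = cohort)
  })
}
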