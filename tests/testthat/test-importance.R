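# Hand-built mixture set whose informative pixels are known: plot = r * A +
# (1 - r) * B where A and B are fixed standardized patterns that differ only
# in rows 3-6 vs 9-12; rows 17-24 are structurally zero in every plot.
synthetic_importance_set <- function(n = 160, seed = 12) {
  h <- 24; w <- 18
  A <- matrix(0, h, w); A[3:6, 5:14] <- 1
  B <- matrix(0, h, w); B[9:12, 5:14] <- 1
  A <- (A - mean(A)) / sd(A)
  B <- (B - mean(B)) / sd(B)
  with_seed <- serovolt:::with_seed
  with_seed(seed, {
    r <- runif(n)
    x <- array(0, c(h, w, n))
    for (k in seq_len(n)) {
      x[, , k] <- r[k] * A + (1 - r[k]) * B + rnorm(h * w, 0, 0.02)
    }
    structure(list(x = x, ratio = r,
                   parents = data.frame(serotonin = 1, dopamine = 1),
                   dims = c(h, w)),
              class = "mixture_set")
  })
}

test_that("randomization importance highlights the informative rows", {
  ds <- synthetic_importance_set()
  cfg <- cnn_config(input_dim = c(24, 18), conv_features = c(4, 3),
                    dense_units = c(10, 5))
  tc <- training_config(learning_rate = 2e-3, epochs = 25, batch_size = 30,
                        steps_per_epoch = NULL, validation_steps = NULL,
                        input_noise_sd = 0.02)
  train_fn <- function(dataset, seed) train_cnn(dataset, cfg, tc, seed = seed)
  imp <- feature_importance(ds, train_fn, n_rep = 2, block = c(2, 2),
                            n_eval = 60, seed = 7)
  expect_equal(max(imp$importance), 1)
  expect_true(all(imp$importance >= 0))
  expect_equal(dim(imp$importance), c(24L, 18L))
  signal <- mean(imp$raw[c(3:6, 9:12), 5:14])
  dead <- mean(imp$raw[18:24, ])
  expect_gt(signal, dead)
  # structurally empty pixels leave the error essentially unchanged
  expect_lt(abs(dead - 1), 0.25)
  expect_gt(signal, 1.05)
  expect_error(feature_importance(ds, train_fn, n_rep = 0), "n_rep")
})
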