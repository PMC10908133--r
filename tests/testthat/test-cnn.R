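test_that("activation functions match their printed constants", {
  expect_equal(selu(1), 1.051)
  expect_equal(selu(0), 0)
  expect_equal(selu(-50), -1.051 * 1.673, tolerance = 1e-9) # limit -s*alpha
  # continuity and monotonicity of the continuous form
  xs <- seq(-4, 4, by = 1e-3)
  expect_true(all(diff(selu(xs)) > 0))
  expect_lt(abs(selu(1e-9) - selu(-1e-9)), 1e-6)
  # the printed variant is offset by s*(alpha - 1) at 0-
  expect_equal(selu(-1e-12, printed_form = TRUE), 1.051 * (1.673 - 1),
               tolerance = 1e-9)
  expect_equal(leaky_relu(2), 2)
  expect_equal(leaky_relu(-10), -1.0)
  expect_equal(leaky_relu(0), 0)
})

test_that("the architecture enumerates 11 layers with the printed widths", {
  cfg <- cnn_config(input_dim = c(220, 300))
  expect_equal(cfg$n_layers, 11L)
  expect_equal(cfg$conv_features, c(275L, 100L))
  expect_equal(cfg$kernel, 3L)
  expect_equal(cfg$pool, 3L)
  m <- build_cnn(cnn_config(input_dim = c(16, 20), conv_features = c(4, 3),
                            dense_units = c(12, 6)), seed = 1)
  expect_equal(dim(m$weights$conv1_W), c(9L, 4L))
  expect_equal(dim(m$weights$dense3_W), c(6L, 1L)) # unity output node
  expect_error(cnn_config(input_dim = c(2, 2)), "smaller")
})

test_that("backpropagation matches finite differences", {
  set.seed(31)
  cfg <- cnn_config(input_dim = c(12, 14), conv_features = c(3, 2),
                    dense_units = c(6, 4))
  m <- build_cnn(cfg, seed = 3)
  x <- array(rnorm(12 * 14 * 3), c(12, 14, 3))
  y <- runif(3)
  fw <- serovolt:::cnn_forward(m, x, keep = TRUE)
  grads <- serovolt:::cnn_backward(m, fw$cache, sign(fw$pred - y) / 3)
  h <- 1e-6
  loss_at <- function(model) mean(abs(serovolt:::cnn_forward(model, x)$pred - y))
  for (nm in names(m$weights)) {
    idx <- sample(length(m$weights[[nm]]), min(4, length(m$weights[[nm]])))
    for (i in idx) {
      up <- m; up$weights[[nm]][i] <- up$weights[[nm]][i] + h
      dn <- m; dn$weights[[nm]][i] <- dn$weights[[nm]][i] - h
      fd <- (loss_at(up) - loss_at(dn)) / (2 * h)
      expect_equal(grads[[nm]][i], fd, tolerance = 1e-4,
                   label = paste("gradient of", nm))
    }
  }
})

test_that("training is deterministic under a fixed seed", {
  mx <- tiny_mixtures()
  cfg <- tiny_cnn_config()
  tc <- tiny_training_config(epochs = 3)
  a <- train_cnn(mx, cfg, tc, seed = 99)
  b <- train_cnn(mx, cfg, tc, seed = 99)
  expect_identical(a$history, b$history)
  expect_identical(a$model$weights, b$model$weights)
  c <- train_cnn(mx, cfg, tc, seed = 100)
  expect_false(identical(a$history$train_mae, c$history$train_mae))
})

test_that("a small trained model interpolates the mixture ratio", {
  fit <- tiny_cnn_fit()
  mx <- tiny_mixtures()
  preds <- predict_ratio(fit$model, mx$x[, , fit$test, drop = FALSE])
  truth <- mx$ratio[fit$test]
  expect_lt(evaluate_rmse(preds, truth), 0.2)
  # monotone mean response over ratio bins
  bins <- cut(truth, breaks = seq(0, 1, by = 0.25))
  bin_means <- tapply(preds, bins, mean)
  expect_true(all(diff(bin_means) > 0))
})

test_that("prediction is invariant to plot provenance (file vs memory)", {
  fit <- tiny_cnn_fit()
  ch <- tiny_cohort()
  p <- standardize_plot(ch$serotonin[[1]])
  path <- tempfile(fileext = ".csv")
  write_color_plot(p, path)
  q <- read_color_plot(path)
  expect_identical(predict_ratio(fit$model, p), predict_ratio(fit$model, q))
  expect_error(predict_ratio(fit$model, matrix(0, 4, 4)), "shape")
})

test_that("RMSE evaluation matches direct arithmetic", {
  expect_equal(evaluate_rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(evaluate_rmse(c(1, 2, 3) + 0.5, c(1, 2, 3)), 0.5)
  expect_equal(evaluate_rmse(c(0, 1, 1), c(1, 1, 0)),
               sqrt((1 + 0 + 1) / 3))
  expect_error(evaluate_rmse(numeric(0), numeric(0)), "empty")
  expect_error(evaluate_rmse(1:3, 1:4), "mismatch")
})

test_that("timecourse slopes are exact on linear series", {
  expect_equal(ratio_timecourse_slope(data.frame(time = 0:10,
                                                 ratio = rep(0.8, 11))), 0)
  expect_equal(ratio_timecourse_slope(data.frame(time = 0:10,
                                                 ratio = 1 - 0.003 * (0:10))),
               -0.003, tolerance = 1e-12)
  expect_error(ratio_timecourse_slope(data.frame(time = 1:2,
                                                 ratio = c(1, 2))), "3")
})
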