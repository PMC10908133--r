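#' Scaled exponential linear unit (SELU)
#'
#' \deqn{f(x) = s x \;(x > 0), \qquad f(x) = s\,\alpha\,(e^x - 1) \;(x \le 0)}
#' with the constants \eqn{s = 1.051}, \eqn{\alpha = 1.673}. This is the
#' standard continuous form (0 at the origin, approaching \eqn{-s\alpha} as
#' \eqn{x \to -\infty}). A variant that multiplies only \eqn{\alpha e^x} by
#' \eqn{s} before subtracting 1, which is discontinuous at 0, is available
#' via \code{printed_form = TRUE}.
#'
#' @param x Numeric input (vectorised).
#' @param s,alpha Activation constants.
#' @param printed_form Use the discontinuous variant \eqn{s(\alpha e^x - 1)}
#'   for \eqn{x \le 0}.
#' @return Activated values.
#' @export
#' @examples
#' selu(1)  # 1.051
#' selu(0)  # 0
selu <- function(x, s = 1.051, alpha = 1.673, printed_form = FALSE) {
  pos <- x > 0
  ex <- exp(pmin(x, 0))
  neg <- if (printed_form) s * (alpha * ex - 1) else s * alpha * (ex - 1)
  s * x * pos + neg * (1 - pos)
}

# derivative of the continuous SELU (used in backprop; the printed form has
# the same derivative for x != 0)
selu_grad <- function(x, s = 1.051, alpha = 1.673) {
  pos <- x > 0
  s * pos + s * alpha * exp(pmin(x, 0)) * (1 - pos)
}

#' Leaky rectified linear unit
#'
#' Identity for positive inputs, slope 0.1 otherwise.
#'
#' @param x Numeric input (vectorised).
#' @param slope Negative-side slope (default 0.1).
#' @return Activated values.
#' @export
#' @examples
#' leaky_relu(-10) # -1
leaky_relu <- function(x, slope = 0.1) {
  pmax(x, 0) + slope * pmin(x, 0)
}

#' CNN architecture configuration
#'
#' The ratio-regression network is an 11-layer sequential model:
#' convolution (\code{conv_features[1]} filters, 3x3, SELU) -> max pooling
#' (3x3) -> leaky ReLU -> convolution (\code{conv_features[2]} filters, 3x3,
#' ReLU) -> leaky ReLU -> flatten -> dense -> leaky ReLU -> dense ->
#' leaky ReLU -> dense(1). Counting the two convolutions, the pool, the four
#' leaky ReLU layers, the flatten and the three dense layers gives 11.
#' Defaults follow the full-scale design (275 and 100 convolution features);
#' the reduced test profile narrows the widths (see
#' [experiment_profile()]).
#'
#' @param input_dim Input plot dimensions \code{c(rows, cols)}.
#' @param conv_features Filter counts of the two convolution layers.
#' @param kernel Convolution kernel size (square).
#' @param pool Max-pooling window (and stride).
#' @param dense_units Hidden widths of the first two dense layers (the third
#'   is the unity output node).
#' @param leaky_slope Negative-side slope of the leaky ReLU layers.
#' @param selu_constants \code{c(s, alpha)} of the SELU activation.
#' @param selu_printed_form Use the discontinuous SELU variant.
#' @return An object of class \code{cnn_config}.
#' @export
cnn_config <- function(input_dim = c(64, 100), conv_features = c(275, 100),
                       kernel = 3, pool = 3, dense_units = c(128, 64),
                       leaky_slope = 0.1, selu_constants = c(1.051, 1.673),
                       selu_printed_form = FALSE) {
  stop_if(any(input_dim < kernel), "input smaller than the convolution kernel")
  h1 <- input_dim[1] - kernel + 1
  w1 <- input_dim[2] - kernel + 1
  stop_if(h1 < pool || w1 < pool, "input too small for the pooling window")
  hp <- (h1 - pool) %/% pool + 1
  wp <- (w1 - pool) %/% pool + 1
  stop_if(hp < kernel || wp < kernel,
          "pooled map smaller than the second convolution kernel")
  h2 <- hp - kernel + 1
  w2 <- wp - kernel + 1
  structure(list(
    input_dim = as.integer(input_dim),
    conv_features = as.integer(conv_features), kernel = as.integer(kernel),
    pool = as.integer(pool), dense_units = as.integer(dense_units),
    leaky_slope = leaky_slope, selu_constants = selu_constants,
    selu_printed_form = selu_printed_form,
    # derived feature-map dims
    conv1_dim = c(h1, w1), pool_dim = c(hp, wp), conv2_dim = c(h2, w2),
    flat_features = h2 * w2 * conv_features[2],
    n_layers = 11L
  ), class = "cnn_config")
}

# ---- low-level array helpers ---------------------------------------------

# Patch index matrix for one (H, W) plane: rows = output positions in
# column-major order, columns = the K*K offsets (column-major) of the patch.
patch_index <- function(H, W, K, stride = 1L) {
  io <- seq(1L, H - K + 1L, by = stride)
  jo <- seq(1L, W - K + 1L, by = stride)
  pos <- as.vector(outer(io, (jo - 1L) * H, `+`)) # top-left linear index
  off <- as.vector(outer(0:(K - 1L), (0:(K - 1L)) * H, `+`))
  outer(pos, off, `+`)
}

# Expand a single-plane patch index over channels (new columns).
patch_index_channels <- function(P, H, W, C) {
  if (C == 1L) return(P)
  do.call(cbind, lapply(0:(C - 1L), function(c) P + c * H * W))
}

# (HoWo*N) x C matrix (sample-major rows) -> (Ho, Wo, C, N) array
mat_to_maps <- function(m, ho, wo, C, N) {
  tmp <- array(m, c(ho * wo, N, C))
  array(aperm(tmp, c(1, 3, 2)), c(ho, wo, C, N))
}

# inverse of mat_to_maps
maps_to_mat <- function(a) {
  d <- dim(a)
  tmp <- array(a, c(d[1] * d[2], d[3], d[4]))
  m <- aperm(tmp, c(1, 3, 2))
  dim(m) <- c(d[1] * d[2] * d[4], d[3])
  m
}

glorot <- function(nin, nout, dims) {
  lim <- sqrt(6 / (nin + nout))
  array(runif(prod(dims), -lim, lim), dims)
}

#' Build an untrained ratio-regression CNN
#'
#' Initialises the 11-layer network of [cnn_config()] with Glorot-uniform
#' kernels and zero biases. The returned model is deterministic given the
#' seed.
#'
#' @param config A [cnn_config()].
#' @param seed Integer seed for the weight initialisation.
#' @return An object of class \code{ratio_model} (untrained).
#' @export
build_cnn <- function(config = cnn_config(), seed = 1) {
  stopifnot(inherits(config, "cnn_config"))
  K <- config$kernel
  f <- config$conv_features
  du <- config$dense_units
  Fflat <- config$flat_features
  w <- with_seed(seed, list(
    conv1_W = glorot(K * K, K * K * f[1], c(K * K, f[1])),
    conv1_b = numeric(f[1]),
    conv2_W = glorot(K * K * f[1], K * K * f[2], c(K * K * f[1], f[2])),
    conv2_b = numeric(f[2]),
    dense1_W = glorot(Fflat, du[1], c(Fflat, du[1])),
    dense1_b = numeric(du[1]),
    dense2_W = glorot(du[1], du[2], c(du[1], du[2])),
    dense2_b = numeric(du[2]),
    dense3_W = glorot(du[2], 1, c(du[2], 1)),
    dense3_b = numeric(1)
  ))
  structure(list(config = config, weights = w, trained = FALSE,
                 cache = new.env(parent = emptyenv())),
            class = "ratio_model")
}

#' @export
print.ratio_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<ratio_model> %d-layer CNN, input %dx%d, conv %d+%d features, dense %s+1%s\n",
    cfg$n_layers, cfg$input_dim[1], cfg$input_dim[2], cfg$conv_features[1],
    cfg$conv_features[2], paste(cfg$dense_units, collapse = "+"),
    if (x$trained) " (trained)" else " (untrained)"))
  invisible(x)
}

# fetch (and cache) the patch/pool index matrices for a given batch size
cnn_indices <- function(model) {
  env <- model$cache
  if (!is.null(env$idx)) return(env$idx)
  cfg <- model$config
  H <- cfg$input_dim[1]; W <- cfg$input_dim[2]; K <- cfg$kernel
  P1 <- patch_index(H, W, K)
  h1 <- cfg$conv1_dim[1]; w1 <- cfg$conv1_dim[2]
  Ppool <- patch_index(h1, w1, cfg$pool, stride = cfg$pool)
  hp <- cfg$pool_dim[1]; wp <- cfg$pool_dim[2]
  P2 <- patch_index_channels(patch_index(hp, wp, K), hp, wp,
                             cfg$conv_features[1])
  storage.mode(P1) <- "integer"
  storage.mode(Ppool) <- "integer"
  storage.mode(P2) <- "integer"
  env$idx <- list(P1 = P1, Ppool = Ppool, P2 = P2)
  env$idx
}

# Forward pass over a batch. x: (H, W, N) array (single input channel).
# Returns predictions and, when `keep` is TRUE, the caches for backprop.
cnn_forward <- function(model, x, keep = FALSE) {
  cfg <- model$config
  w <- model$weights
  ix <- cnn_indices(model)
  d <- dim(x)
  N <- if (length(d) == 2) 1L else d[3]
  dim(x) <- c(cfg$input_dim[1], cfg$input_dim[2], 1L, N)
  sc <- cfg$selu_constants
  slope <- cfg$leaky_slope
  C1 <- cfg$conv_features[1]
  C2 <- cfg$conv_features[2]

  # conv1 + SELU
  cols1 <- .im2col_cpp(x, ix$P1, N, prod(cfg$input_dim))
  z1 <- cols1 %*% w$conv1_W
  z1 <- z1 + matrix(w$conv1_b, nrow(z1), ncol(z1), byrow = TRUE)
  a1 <- .selu_fwd_cpp(z1, sc[1], sc[2], cfg$selu_printed_form)
  dim(a1) <- dim(z1)
  a1_maps <- mat_to_maps(a1, cfg$conv1_dim[1], cfg$conv1_dim[2], C1, N)

  # maxpool over each (channel, sample) plane, then leaky ReLU
  plane1 <- prod(cfg$conv1_dim)
  pool <- .pool_fwd_cpp(a1_maps, ix$Ppool, C1 * N, plane1)
  pooled <- array(pool$values, c(cfg$pool_dim[1], cfg$pool_dim[2], C1, N))
  l1 <- .leaky_fwd_cpp(pooled, slope)
  dim(l1) <- dim(pooled)

  # conv2 + ReLU (the following leaky ReLU is the identity on relu output)
  cols2 <- .im2col_cpp(l1, ix$P2, N, prod(cfg$pool_dim) * C1)
  z2 <- cols2 %*% w$conv2_W
  z2 <- z2 + matrix(w$conv2_b, nrow(z2), ncol(z2), byrow = TRUE)
  l2 <- .relu_fwd_cpp(z2)
  dim(l2) <- dim(z2)
  l2_maps <- mat_to_maps(l2, cfg$conv2_dim[1], cfg$conv2_dim[2], C2, N)

  # flatten + dense stack
  xf <- l2_maps
  dim(xf) <- c(cfg$flat_features, N)
  h1d <- crossprod(w$dense1_W, xf) + w$dense1_b
  lh1 <- .leaky_fwd_cpp(h1d, slope)
  dim(lh1) <- dim(h1d)
  h2d <- crossprod(w$dense2_W, lh1) + w$dense2_b
  lh2 <- .leaky_fwd_cpp(h2d, slope)
  dim(lh2) <- dim(h2d)
  out <- as.numeric(crossprod(w$dense3_W, lh2) + w$dense3_b)

  if (!keep) return(list(pred = out))
  list(pred = out,
       cache = list(N = N, cols1 = cols1, z1 = z1,
                    pool_arg = pool$argmax, a1_len = length(a1),
                    pooled = pooled, cols2 = cols2, z2 = z2,
                    xf = xf, h1d = h1d, lh1 = lh1, h2d = h2d, lh2 = lh2))
}

# Backward pass: gradient of the scalar loss wrt all weights, given
# dL/dpred. Returns a list shaped like model$weights.
cnn_backward <- function(model, cache, dpred) {
  cfg <- model$config
  w <- model$weights
  ix <- cnn_indices(model)
  sc <- cfg$selu_constants
  slope <- cfg$leaky_slope
  N <- cache$N
  C1 <- cfg$conv_features[1]

  dpred <- matrix(dpred, 1, N)
  # dense3
  g_dense3_W <- cache$lh2 %*% t(dpred)
  g_dense3_b <- sum(dpred)
  dlh2 <- w$dense3_W %*% dpred
  dh2 <- .leaky_bwd_cpp(cache$h2d, dlh2, slope)
  dim(dh2) <- dim(dlh2)
  # dense2
  g_dense2_W <- cache$lh1 %*% t(dh2)
  g_dense2_b <- rowSums(dh2)
  dlh1 <- w$dense2_W %*% dh2
  dh1 <- .leaky_bwd_cpp(cache$h1d, dlh1, slope)
  dim(dh1) <- dim(dlh1)
  # dense1
  g_dense1_W <- cache$xf %*% t(dh1)
  g_dense1_b <- rowSums(dh1)
  dxf <- w$dense1_W %*% dh1

  # un-flatten -> (identity leaky) -> ReLU -> conv2
  dl2_maps <- array(dxf, c(cfg$conv2_dim[1], cfg$conv2_dim[2],
                           cfg$conv_features[2], N))
  dl2 <- maps_to_mat(dl2_maps)
  dz2 <- .relu_bwd_cpp(cache$z2, dl2)
  dim(dz2) <- dim(dl2)
  g_conv2_W <- crossprod(cache$cols2, dz2)
  g_conv2_b <- colSums(dz2)
  dcols2 <- tcrossprod(dz2, w$conv2_W)
  dl1 <- .col2im_cpp(dcols2, ix$P2, N, prod(cfg$pool_dim) * C1)

  # leaky on pooled maps
  dpooled <- .leaky_bwd_cpp(cache$pooled, dl1, slope)

  # maxpool backward: route each pooled gradient to its argmax position
  da1_vec <- numeric(cache$a1_len)
  da1_vec[cache$pool_arg] <- dpooled # argmax positions are unique
  da1_maps <- array(da1_vec, c(cfg$conv1_dim[1], cfg$conv1_dim[2], C1, N))

  # SELU backward -> conv1
  da1 <- maps_to_mat(da1_maps)
  dz1 <- .selu_bwd_cpp(cache$z1, da1, sc[1], sc[2])
  dim(dz1) <- dim(da1)
  g_conv1_W <- crossprod(cache$cols1, dz1)
  g_conv1_b <- colSums(dz1)

  list(conv1_W = g_conv1_W, conv1_b = g_conv1_b,
       conv2_W = g_conv2_W, conv2_b = g_conv2_b,
       dense1_W = g_dense1_W, dense1_b = g_dense1_b,
       dense2_W = g_dense2_W, dense2_b = g_dense2_b,
       dense3_W = g_dense3_W, dense3_b = g_dense3_b)
}

#' Training configuration for the ratio CNN
#'
#' Defaults follow the full-scale protocol: Adam with learning rate 1e-4,
#' mean-absolute-error loss, 500 epochs, batches of 30 shuffled plots, 4:1
#' train:test and 4:1 train:validation splits, 4 training steps and 5
#' validation steps per epoch. Setting \code{steps_per_epoch} or
#' \code{validation_steps} to \code{NULL} uses full passes over the split
#' instead of the caps. Fresh Gaussian noise (\code{input_noise_sd}) is added
#' to every training batch so each presented signal is unique.
#'
#' @param learning_rate Adam learning rate.
#' @param epochs Training epochs.
#' @param batch_size Batch size.
#' @param steps_per_epoch,validation_steps Per-epoch step caps or \code{NULL}.
#' @param test_fraction,validation_fraction Held-out fractions (both 1/5).
#' @param input_noise_sd SD of the input-side Gaussian noise (standardized
#'   current units).
#' @param adam_beta1,adam_beta2,adam_eps Adam moment parameters.
#' @return An object of class \code{training_config}.
#' @export
training_config <- function(learning_rate = 1e-4, epochs = 500,
                            batch_size = 30, steps_per_epoch = 4,
                            validation_steps = 5, test_fraction = 0.2,
                            validation_fraction = 0.2, input_noise_sd = 0.05,
                            adam_beta1 = 0.9, adam_beta2 = 0.999,
                            adam_eps = 1e-7) {
  stop_if(learning_rate <= 0 || epochs < 1 || batch_size < 1,
          "learning rate, epochs and batch size must be positive")
  stop_if(test_fraction <= 0 || test_fraction >= 1 ||
            validation_fraction <= 0 || validation_fraction >= 1,
          "split fractions must lie in (0, 1)")
  structure(as.list(environment()), class = "training_config")
}

#' Train the ratio-regression CNN
#'
#' Splits the mixture set 4:1 into a training pool and a held-out test set,
#' then 4:1 again into train and validation, and minimises the mean absolute
#' error with Adam over shuffled batches. Gaussian noise is drawn fresh for
#' every training batch and added to the inputs. The per-epoch history
#' records the training MAE and validation RMSE. Training is deterministic
#' given the seed (single-threaded BLAS assumed).
#'
#' @param dataset A \code{mixture_set} from [generate_training_set()].
#' @param config A [cnn_config()]; its \code{input_dim} must match the set.
#' @param tconf A [training_config()].
#' @param seed Integer seed covering initialisation, splits, shuffling and
#'   input noise.
#' @param verbose Print a line every 10 epochs.
#' @return List with \code{model} (trained \code{ratio_model}),
#'   \code{history} (data.frame epoch/train_mae/val_rmse), and the index
#'   vectors \code{train}, \code{validation}, \code{test}.
#' @export
train_cnn <- function(dataset, config = cnn_config(), tconf = training_config(),
                      seed = 1, verbose = FALSE) {
  stopifnot(inherits(dataset, "mixture_set"),
            inherits(config, "cnn_config"),
            inherits(tconf, "training_config"))
  n <- length(dataset$ratio)
  stop_if(n < 2 * tconf$batch_size, "dataset too small for the configured batches")
  stop_if(!all(dataset$dims == config$input_dim),
          "dataset plot dimensions do not match the CNN input shape")

  model <- build_cnn(config, seed = child_seed(seed, 1))
  splits <- with_seed(child_seed(seed, 2), {
    perm <- sample.int(n)
    n_test <- max(1L, floor(n * tconf$test_fraction))
    test <- perm[seq_len(n_test)]
    rest <- perm[-seq_len(n_test)]
    n_val <- max(1L, floor(length(rest) * tconf$validation_fraction))
    list(validation = rest[seq_len(n_val)], train = rest[-seq_len(n_val)],
         test = test)
  })
  itr <- splits$train
  adam <- list(m = lapply(model$weights, function(x) x * 0),
               v = lapply(model$weights, function(x) x * 0), t = 0)
  lr <- tconf$learning_rate
  b1 <- tconf$adam_beta1; b2 <- tconf$adam_beta2; eps <- tconf$adam_eps
  steps_full <- max(1L, floor(length(itr) / tconf$batch_size))
  steps <- if (is.null(tconf$steps_per_epoch)) steps_full else
    min(tconf$steps_per_epoch, steps_full)
  n_val_eval <- if (is.null(tconf$validation_steps)) length(splits$validation)
  else min(length(splits$validation), tconf$validation_steps * tconf$batch_size)
  history <- data.frame(epoch = seq_len(tconf$epochs), train_mae = NA_real_,
                        val_rmse = NA_real_)

  with_seed(child_seed(seed, 3), {
    for (ep in seq_len(tconf$epochs)) {
      ord <- sample(itr)
      losses <- numeric(steps)
      for (st in seq_len(steps)) {
        take <- ord[((st - 1) * tconf$batch_size) %% length(ord) +
                      seq_len(tconf$batch_size)]
        take <- take[!is.na(take)]
        xb <- dataset$x[, , take, drop = FALSE]
        if (tconf$input_noise_sd > 0) {
          xb <- xb + array(rnorm(length(xb), 0, tconf$input_noise_sd), dim(xb))
        }
        yb <- dataset$ratio[take]
        fw <- cnn_forward(model, xb, keep = TRUE)
        resid <- fw$pred - yb
        losses[st] <- mean(abs(resid))
        dpred <- sign(resid) / length(resid) # MAE gradient
        grads <- cnn_backward(model, fw$cache, dpred)
        adam$t <- adam$t + 1
        corr1 <- 1 - b1^adam$t
        corr2 <- 1 - b2^adam$t
        for (nm in names(model$weights)) {
          g <- grads[[nm]]
          adam$m[[nm]] <- b1 * adam$m[[nm]] + (1 - b1) * g
          adam$v[[nm]] <- b2 * adam$v[[nm]] + (1 - b2) * g * g
          model$weights[[nm]] <- model$weights[[nm]] -
            lr * (adam$m[[nm]] / corr1) / (sqrt(adam$v[[nm]] / corr2) + eps)
        }
      }
      vidx <- splits$validation[seq_len(n_val_eval)]
      vp <- predict_ratio(model, dataset$x[, , vidx, drop = FALSE])
      history$train_mae[ep] <- mean(losses)
      history$val_rmse[ep] <- evaluate_rmse(vp, dataset$ratio[vidx])
      if (verbose && ep %% 10 == 0) {
        message(sprintf("epoch %d: train MAE %.4f, val RMSE %.4f",
                        ep, history$train_mae[ep], history$val_rmse[ep]))
      }
    }
  })
  model$trained <- TRUE
  list(model = model, history = history, train = splits$train,
       validation = splits$validation, test = splits$test)
}

#' Predict the serotonin:dopamine ratio of color plots
#'
#' Forward pass of a trained [build_cnn()] model. Accepts a single
#' standardized [color_plot()], a plain matrix, or a 3-D array of stacked
#' plots. Predictions are not clipped to \[0, 1\].
#'
#' @param model A \code{ratio_model}.
#' @param x Input plot(s); dimensions must match the model's input shape.
#' @param batch Internal prediction batch size.
#' @return Numeric vector of predicted ratios (1 = pure serotonin, 0 = pure
#'   dopamine).
#' @export
predict_ratio <- function(model, x, batch = 64) {
  stopifnot(inherits(model, "ratio_model"))
  if (inherits(x, "color_plot")) x <- x$current
  d <- dim(x)
  stop_if(!all(d[1:2] == model$config$input_dim),
          "plot shape does not match the model input shape")
  if (length(d) == 2) dim(x) <- c(d, 1L)
  N <- dim(x)[3]
  out <- numeric(N)
  for (s in seq(1, N, by = batch)) {
    take <- s:min(s + batch - 1, N)
    out[take] <- cnn_forward(model, x[, , take, drop = FALSE])$pred
  }
  out
}

#' Root-mean-square error between predictions and truth
#'
#' @param preds,truth Equal-length numeric vectors.
#' @return RMSE.
#' @export
evaluate_rmse <- function(preds, truth) {
  stop_if(length(preds) == 0, "empty prediction vector")
  stop_if(length(preds) != length(truth), "length mismatch")
  sqrt(mean((preds - truth)^2))
}

#' Least-squares slope of a predicted-ratio time course
#'
#' Ordinary least squares of ratio against time; used to quantify the
#' post-levodopa drift from serotonin-like (ratio 1) toward dopamine-like
#' (ratio 0) signals.
#'
#' @param preds data.frame with columns \code{time} (min) and \code{ratio},
#'   or a numeric ratio vector accompanied by \code{time}.
#' @param time Optional time vector when \code{preds} is numeric.
#' @return Slope in 1/min.
#' @export
ratio_timecourse_slope <- function(preds, time = NULL) {
  if (is.data.frame(preds)) {
    time <- preds$time
    ratio <- preds$ratio
  } else {
    ratio <- preds
  }
  stop_if(is.null(time) || length(ratio) < 3,
          "need at least 3 (time, ratio) points")
  coef(lm(ratio ~ time))[[2]]
}

#' Feature importance by input randomization
#'
#' Estimates which color-plot samples drive the ratio prediction: the model
#' is retrained \code{n_rep} times from different seeds; after each training,
#' every input block in turn is replaced by fresh \eqn{U(-1, 1)} noise across
#' an evaluation set, and the ratio of perturbed to baseline RMSE is recorded
#' for the block's pixels. Scores are averaged over repetitions and
#' normalised to a maximum of 1. Blockwise evaluation (default 4x4) keeps the
#' procedure tractable; \code{block = c(1, 1)} gives the per-sample variant.
#'
#' @param dataset A \code{mixture_set} used for training and evaluation.
#' @param train_fn Function \code{(dataset, seed) -> ratio_model} (or a list
#'   with a \code{model} element, as returned by [train_cnn()]).
#' @param n_rep Number of training repetitions (default 15).
#' @param block Block height and width in pixels.
#' @param n_eval Number of evaluation plots sampled per repetition.
#' @param seed Integer seed.
#' @return An \code{importance_map}: list with \code{importance} (matrix,
#'   max 1), \code{raw} (mean RMSE ratio before normalisation) and
#'   \code{n_rep}.
#' @export
feature_importance <- function(dataset, train_fn, n_rep = 15, block = c(4, 4),
                               n_eval = 100, seed = 1) {
  stopifnot(inherits(dataset, "mixture_set"))
  stop_if(n_rep < 1, "n_rep must be at least 1")
  d <- dataset$dims
  acc <- matrix(0, d[1], d[2])
  rstarts <- seq(1, d[1], by = block[1])
  cstarts <- seq(1, d[2], by = block[2])
  for (rep_i in seq_len(n_rep)) {
    srep <- child_seed(seed, rep_i)
    fit <- train_fn(dataset, srep)
    model <- if (inherits(fit, "ratio_model")) fit else fit$model
    ev <- with_seed(child_seed(srep, 1),
                    sample.int(length(dataset$ratio),
                               min(n_eval, length(dataset$ratio))))
    xe <- dataset$x[, , ev, drop = FALSE]
    ye <- dataset$ratio[ev]
    base <- evaluate_rmse(predict_ratio(model, xe), ye)
    with_seed(child_seed(srep, 2), {
      for (ri in rstarts) {
        rr <- ri:min(ri + block[1] - 1, d[1])
        for (ci in cstarts) {
          cc <- ci:min(ci + block[2] - 1, d[2])
          xp <- xe
          xp[rr, cc, ] <- runif(length(rr) * length(cc) * dim(xe)[3], -1, 1)
          pert <- evaluate_rmse(predict_ratio(model, xp), ye)
          acc[rr, cc] <- acc[rr, cc] + pert / base
        }
      }
    })
  }
  raw <- acc / n_rep
  structure(list(importance = raw / max(raw), raw = raw, n_rep = n_rep,
                 block = block),
            class = "importance_map")
}

#' @export
print.importance_map <- function(x, ...) {
  cat(sprintf("<importance_map> %d x %d, %d repetitions, block %dx%d\n",
              nrow(x$importance), ncol(x$importance), x$n_rep,
              x$block[1], x$block[2]))
  invisible(x)
}
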