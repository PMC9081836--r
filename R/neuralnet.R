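#' CNN-LSTM architecture description
#'
#' @param n_conv_layers number of Conv1D+ReLU blocks, one of 1-4.
#' @param n_filters filters per conv layer, one of 16/32/64.
#' @param kernel_size conv kernel width, one of 3/5/7.
#' @param lstm_units LSTM hidden units, one of 16/32/64.
#' @param batch_norm logical; batch normalization on the input, after each
#'   conv block and after the LSTM.
#' @param dropout_rate one of 0.01/0.1/0.2/0.3/0.4.
#' @param head_width output width: 1 (torque regression) or 4 (per-muscle
#'   activations, hybrid model).
#' @param head_activation `"linear"` (regression) or `"sigmoid"` (activations).
#' @return a validated `cnn_architecture` list.
#' @export
cnn_architecture <- function(n_conv_layers = 3, n_filters = 32,
                             kernel_size = 7, lstm_units = 64,
                             batch_norm = TRUE, dropout_rate = 0.1,
                             head_width = 1, head_activation = "linear") {
  chk <- function(v, set, nm)
    if (!v %in% set) stop(sprintf("invalid %s: %s", nm, v))
  chk(n_conv_layers, 1:4, "n_conv_layers")
  chk(n_filters, c(16, 32, 64), "n_filters")
  chk(kernel_size, c(3, 5, 7), "kernel_size")
  chk(lstm_units, c(16, 32, 64), "lstm_units")
  chk(dropout_rate, c(0.01, 0.1, 0.2, 0.3, 0.4), "dropout_rate")
  chk(head_width, c(1, 4), "head_width")
  chk(head_activation, c("linear", "sigmoid"), "head_activation")
  structure(list(n_conv_layers = n_conv_layers, n_filters = n_filters,
                 kernel_size = kernel_size, lstm_units = lstm_units,
                 batch_norm = isTRUE(batch_norm) || batch_norm == 1,
                 dropout_rate = dropout_rate, head_width = head_width,
                 head_activation = head_activation),
            class = "cnn_architecture")
}

#' The architecture selected by the study-scale search
#'
#' Three conv layers of 32 filters (kernel 7), a 64-unit LSTM, batch
#' normalization between layers and dropout 0.1.
#'
#' @param head_width,head_activation head configuration (see
#'   [cnn_architecture()]).
#' @return a `cnn_architecture`.
#' @export
optimized_architecture <- function(head_width = 1, head_activation = "linear")
  cnn_architecture(3, 32, 7, 64, TRUE, 0.1, head_width, head_activation)

#' Build a CNN-LSTM model
#'
#' Layer sequence: \[BN\] + n_conv x (Conv1D + ReLU + \[BN\]) + LSTM + \[BN\] +
#' Dropout + Dense head.  Weight initialization is Glorot-uniform, seeded.
#'
#' @param arch a [cnn_architecture()].
#' @param input_shape `c(window_len, n_channels)` (default `c(128, 4)`).
#' @param seed RNG seed for the weight initialization.
#' @return a model object consumed by [train_cnn()] / [predict_cnn()].
#' @export
build_model <- function(arch, input_shape = c(128, 4), seed = 1L) {
  stopifnot(inherits(arch, "cnn_architecture"))
  t_out <- input_shape[1] - arch$n_conv_layers * (arch$kernel_size - 1)
  if (t_out < 1) stop("window too short for the convolution stack")
  set.seed(seed)
  layers <- list()
  add <- function(l) layers[[length(layers) + 1L]] <<- l
  cin <- input_shape[2]
  if (arch$batch_norm) add(new_layer_bn(cin))
  for (i in seq_len(arch$n_conv_layers)) {
    add(new_layer_conv(cin, arch$kernel_size, arch$n_filters))
    add(new_layer_relu())
    if (arch$batch_norm) add(new_layer_bn(arch$n_filters))
    cin <- arch$n_filters
  }
  add(new_layer_lstm(cin, arch$lstm_units))
  if (arch$batch_norm) add(new_layer_bn(arch$lstm_units))
  add(new_layer_dropout(arch$dropout_rate))
  add(new_layer_dense(arch$lstm_units, arch$head_width, arch$head_activation))
  structure(list(layers = layers, arch = arch, input_shape = input_shape,
                 seed = seed), class = "cnn_model")
}

#' @export
print.cnn_model <- function(x, ...) {
  a <- x$arch
  cat(sprintf(
    "<cnn_model> %d conv x %d filters (k=%d) + LSTM %d, BN=%s, dropout %g, head %d (%s)\n",
    a$n_conv_layers, a$n_filters, a$kernel_size, a$lstm_units,
    a$batch_norm, a$dropout_rate, a$head_width, a$head_activation))
  cat(sprintf("  input %d x %d, %d parameters\n", x$input_shape[1],
              x$input_shape[2], sum(count_parameters(x$arch,
                                                     x$input_shape[2])$n_params)))
  invisible(x)
}

#' Per-layer trainable-parameter counts of an architecture
#'
#' Closed-form accounting: Conv1D `(C_in K + 1) F`, LSTM
#' `4((I + H) H + H)`, Dense `(I + 1) O`, BatchNorm `4 x features`
#' (2 trainable + 2 running moments, following common reporting practice).
#'
#' @param arch a [cnn_architecture()].
#' @param input_channels number of input channels (default 4).
#' @return data.frame with columns `layer`, `size`, `n_params`.
#' @export
count_parameters <- function(arch, input_channels = 4) {
  stopifnot(inherits(arch, "cnn_architecture"))
  rows <- list()
  add <- function(layer, size, n)
    rows[[length(rows) + 1L]] <<- data.frame(layer = layer, size = size,
                                             n_params = n)
  cin <- input_channels
  if (arch$batch_norm) add("batch_norm", cin, 4 * cin)
  for (i in seq_len(arch$n_conv_layers)) {
    add(sprintf("conv1d_%d", i), arch$n_filters,
        (cin * arch$kernel_size + 1) * arch$n_filters)
    cin <- arch$n_filters
    if (arch$batch_norm) add("batch_norm", cin, 4 * cin)
  }
  add("lstm", arch$lstm_units,
      4 * ((cin + arch$lstm_units) * arch$lstm_units + arch$lstm_units))
  if (arch$batch_norm)
    add("batch_norm", arch$lstm_units, 4 * arch$lstm_units)
  add("dropout", NA, 0)
  add("dense", arch$head_width, (arch$lstm_units + 1) * arch$head_width)
  do.call(rbind, rows)
}

#' Causal deployment delay of the windowed pipeline
#'
#' In a causal (real-time) deployment the estimator must wait for a full
#' window, produces outputs once per stride, and the causal variant of the
#' output filter adds one further output sample.
#'
#' @param window_ms window length (ms).
#' @param stride_ms stride (ms); also the output sampling period.
#' @param filter_samples output-filter delay in output samples.
#' @return total delay in ms.
#' @export
deployment_delay_ms <- function(window_ms = 128, stride_ms = 16,
                                filter_samples = 1)
  window_ms + stride_ms + filter_samples * stride_ms

#' Default training configuration
#'
#' @param lr Adam learning rate.
#' @param max_epochs epoch cap.
#' @param patience early-stopping patience (epochs without monitored-loss
#'   improvement).
#' @param batch_size minibatch size.
#' @param seed RNG seed (weights are seeded separately at build time).
#' @param verbose print per-epoch losses.
#' @return a list.
#' @export
training_config <- function(lr = 0.001, max_epochs = 100, patience = 5,
                            batch_size = 64, seed = 1L, verbose = FALSE)
  list(lr = lr, max_epochs = max_epochs, patience = patience,
       batch_size = batch_size, seed = seed, verbose = verbose)

# Eq-style loss and its gradient wrt predictions; the batch correlation is
# treated as a constant weight in the gradient.
loss_and_grad <- function(y, yhat) {
  n <- length(y)
  r <- suppressWarnings(cor(y, yhat))
  if (!is.finite(r) || r <= 0) r <- 1e-2
  list(loss = mean((y - yhat)^2) / r^2,
       grad = 2 * (yhat - y) / (n * r^2))
}

scale_targets <- function(model, y) {
  sc <- model$target_scale
  if (is.null(sc)) y else (y - sc$mu) / sc$sd
}

dataset_loss <- function(model, ds) {
  yhat <- as.numeric(nn_predict(model, ds$windows))
  loss_mse_over_r2(scale_targets(model, ds$targets), yhat)
}

#' Train a CNN-LSTM torque regressor
#'
#' Minibatch Adam on the correlation-weighted MSE, with early stopping on the
#' monitored loss (validation set if supplied, else training set) and
#' best-weight restoration.
#'
#' @param model a model from [build_model()] (head width 1, linear).
#' @param train a [windowed_dataset()] for training.
#' @param val optional [windowed_dataset()] for validation/monitoring.
#' @param cfg a [training_config()].
#' @return list with `model` (best weights), `history` (per-epoch losses),
#'   `stopped_early`, `best_epoch`.
#' @export
train_cnn <- function(model, train, val = NULL, cfg = training_config()) {
  stopifnot(inherits(train, "windowed_dataset"))
  nw <- n_windows(train)
  if (nw < 1) stop("empty training set")
  set.seed(cfg$seed)
  # targets are standardized internally (training dynamics); predictions are
  # mapped back to N.m by predict_cnn via the stored scale
  sdy <- sd(train$targets)
  model$target_scale <- list(mu = mean(train$targets),
                             sd = if (is.finite(sdy) && sdy > 0) sdy else 1)
  y_tr <- scale_targets(model, train$targets)
  state <- adam_init(model)
  best <- list(loss = Inf, params = get_params(model), epoch = 0L)
  history <- data.frame()
  wait <- 0L; stopped <- FALSE
  for (epoch in seq_len(cfg$max_epochs)) {
    idx <- sample(nw)
    ep_losses <- c()
    for (s in seq(1L, nw, by = cfg$batch_size)) {
      bi <- idx[s:min(s + cfg$batch_size - 1L, nw)]
      if (length(bi) < 2L) next
      Xb <- train$windows[bi, , , drop = FALSE]
      yb <- y_tr[bi]
      fw <- nn_forward(model, Xb, training = TRUE)
      model <- fw$model  # BN running-stat updates
      lg <- loss_and_grad(yb, as.numeric(fw$out))
      ep_losses <- c(ep_losses, lg$loss)
      grads <- nn_backward(model, fw$caches, matrix(lg$grad, ncol = 1))
      up <- adam_step(model, grads, state, lr = cfg$lr)
      model <- up$model; state <- up$state
    }
    monitor <- if (!is.null(val)) dataset_loss(model, val)
               else dataset_loss(model, train)
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = mean(ep_losses),
                                         monitor_loss = monitor))
    if (cfg$verbose)
      message(sprintf("epoch %3d  train %.5g  monitor %.5g", epoch,
                      mean(ep_losses), monitor))
    if (!is.finite(monitor)) stop("training diverged (non-finite loss)")
    if (monitor < best$loss - 1e-12) {
      best <- list(loss = monitor, params = get_params(model), epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$patience) { stopped <- TRUE; break }
    }
  }
  list(model = set_params(model, best$params), history = history,
       stopped_early = stopped, best_epoch = best$epoch)
}

#' Predict torque from windowed envelopes
#'
#' One output per window at the stride rate, then 1 Hz zero-lag smoothing.
#'
#' @param model a trained regression model.
#' @param ds a [windowed_dataset()] (or a bare window array).
#' @param smooth apply [smooth_prediction()].
#' @return a [torque_series()] at the window (stride) rate.
#' @export
predict_cnn <- function(model, ds, smooth = TRUE) {
  windows <- if (inherits(ds, "windowed_dataset")) ds$windows else ds
  if (!identical(as.integer(dim(windows)[2:3]), as.integer(model$input_shape)))
    stop("window shape does not match the model input shape")
  fs_win <- if (inherits(ds, "windowed_dataset")) ds$fs / ds$stride else 62.5
  yhat <- as.numeric(nn_predict(model, windows))
  if (!is.null(model$target_scale))
    yhat <- yhat * model$target_scale$sd + model$target_scale$mu
  tq <- torque_series(yhat, fs_win)
  if (smooth) tq <- smooth_prediction(tq)
  tq
}

#' Architecture search space
#'
#' @return named list of grids over the tunable architecture fields
#'   (`batch_norm` encoded 0/1).
#' @export
cnn_search_space <- function()
  list(n_conv_layers = 1:4, n_filters = c(16, 32, 64),
       kernel_size = c(3, 5, 7), lstm_units = c(16, 32, 64),
       batch_norm = c(0, 1), dropout_rate = c(0.01, 0.1, 0.2, 0.3, 0.4))

#' Bayesian architecture search for the CNN-LSTM
#'
#' TPE search over [cnn_search_space()] minimizing the validation loss of a
#' model trained under `cfg` at each trial.
#'
#' @param train,val [windowed_dataset()] objects.
#' @param space search space (default [cnn_search_space()]).
#' @param n_iter number of search trials (200 at study scale).
#' @param seed RNG seed.
#' @param cfg [training_config()] used for the inner trainings.
#' @return list with `arch` (best [cnn_architecture()]), `best_value`,
#'   `trace`, `history`, `seed`.
#' @export
hyperparameter_search <- function(train, val, space = cnn_search_space(),
                                  n_iter = 200, seed = 1L,
                                  cfg = training_config()) {
  if (n_windows(train) < 1 || n_windows(val) < 1) stop("empty train/val data")
  shape <- dim(train$windows)[2:3]
  objective <- function(p) {
    arch <- cnn_architecture(
      n_conv_layers = if (is.null(p$n_conv_layers)) 3 else p$n_conv_layers,
      n_filters = if (is.null(p$n_filters)) 32 else p$n_filters,
      kernel_size = if (is.null(p$kernel_size)) 7 else p$kernel_size,
      lstm_units = if (is.null(p$lstm_units)) 64 else p$lstm_units,
      batch_norm = if (is.null(p$batch_norm)) TRUE else p$batch_norm == 1,
      dropout_rate = if (is.null(p$dropout_rate)) 0.1 else p$dropout_rate)
    mdl <- build_model(arch, input_shape = shape, seed = seed)
    fit <- train_cnn(mdl, train, val, cfg)
    dataset_loss(fit$model, val)
  }
  res <- tpe_optimize(space, objective, n_iter = n_iter, seed = seed)
  bp <- res$best_params
  arch <- cnn_architecture(
    n_conv_layers = if (is.null(bp$n_conv_layers)) 3 else bp$n_conv_layers,
    n_filters = if (is.null(bp$n_filters)) 32 else bp$n_filters,
    kernel_size = if (is.null(bp$kernel_size)) 7 else bp$kernel_size,
    lstm_units = if (is.null(bp$lstm_units)) 64 else bp$lstm_units,
    batch_norm = if (is.null(bp$batch_norm)) TRUE else bp$batch_norm == 1,
    dropout_rate = if (is.null(bp$dropout_rate)) 0.1 else bp$dropout_rate)
  list(arch = arch, best_value = res$best_value, trace = res$trace,
       history = res$history, seed = seed)
}
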