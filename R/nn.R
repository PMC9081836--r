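# Minimal CNN-LSTM engine: Conv1D / BatchNorm / ReLU / LSTM / Dropout / Dense
# with backpropagation and Adam, implemented as vectorized matrix algebra.
# Tensors are arrays [batch, time, channels]; after the LSTM, matrices
# [batch, features].  No deep-learning framework is involved: the networks
# here are small enough (tens of thousands of weights) that BLAS-backed R is
# adequate, and a self-contained implementation keeps training byte-
# reproducible under a seed.

glorot_init <- function(fan_in, fan_out, dims) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(runif(prod(dims), -lim, lim), dims)
}

new_layer_conv <- function(cin, k, f) {
  list(type = "conv", k = k, cin = cin, f = f,
       W = glorot_init(cin * k, f, c(cin * k, f)), b = numeric(f))
}
new_layer_bn <- function(nfeat) {
  list(type = "bn", gamma = rep(1, nfeat), beta = numeric(nfeat),
       run_mean = numeric(nfeat), run_var = rep(1, nfeat),
       momentum = 0.9, initialized = FALSE, eps = 1e-5)
}
new_layer_relu <- function() list(type = "relu")
new_layer_lstm <- function(cin, units) {
  b <- numeric(4 * units)
  b[(units + 1):(2 * units)] <- 1  # forget-gate bias
  list(type = "lstm", cin = cin, units = units,
       Wx = glorot_init(cin, 4 * units, c(cin, 4 * units)),
       Wh = glorot_init(units, 4 * units, c(units, 4 * units)), b = b)
}
new_layer_dropout <- function(rate) list(type = "dropout", rate = rate)
new_layer_dense <- function(cin, out, activation = "linear") {
  list(type = "dense", cin = cin, out = out, activation = activation,
       W = glorot_init(cin, out, c(cin, out)), b = numeric(out))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- per-layer forward/backward ------------------------------------------

conv_fwd <- function(ly, X) {
  list(out = conv1d_fwd_cpp(X, ly$W, ly$b), cache = list(X = X))
}
conv_bwd <- function(ly, dY, cache) {
  r <- conv1d_bwd_cpp(cache$X, ly$W, dY)
  list(dX = r$dX, grads = list(W = r$dW, b = as.numeric(r$db)))
}

as_feature_matrix <- function(X) {
  d <- dim(X)
  if (length(d) == 3L) matrix(X, d[1] * d[2], d[3]) else X
}

bn_fwd <- function(ly, X, training) {
  d <- dim(X)
  M <- as_feature_matrix(X)
  n <- nrow(M)
  if (training) {
    mu <- colMeans(M)
    cen <- M - rep(mu, each = n)
    v <- colMeans(cen^2)
  } else {
    mu <- ly$run_mean; v <- ly$run_var
    cen <- M - rep(mu, each = n)
  }
  invstd <- 1 / sqrt(v + ly$eps)
  xhat <- cen * rep(invstd, each = n)
  Y <- xhat * rep(ly$gamma, each = n) + rep(ly$beta, each = n)
  upd <- NULL
  if (training) {
    # running stats start at the first batch's statistics, then EMA
    if (!isTRUE(ly$initialized))
      upd <- list(run_mean = mu, run_var = v, initialized = TRUE)
    else
      upd <- list(run_mean = ly$momentum * ly$run_mean + (1 - ly$momentum) * mu,
                  run_var = ly$momentum * ly$run_var + (1 - ly$momentum) * v,
                  initialized = TRUE)
  }
  out <- if (length(d) == 3L) array(Y, d) else Y
  list(out = out,
       cache = list(xhat = xhat, invstd = invstd, dimX = d,
                    training = training),
       state_update = upd)
}
bn_bwd <- function(ly, dY, cache) {
  d <- cache$dimX
  dM <- as_feature_matrix(dY)
  n <- nrow(dM)
  dgamma <- colSums(dM * cache$xhat)
  dbeta <- colSums(dM)
  if (cache$training) {
    # batch statistics depend on the inputs
    t1 <- dM - rep(dbeta / n, each = n)
    t2 <- cache$xhat * rep(dgamma / n, each = n)
    dXm <- (t1 - t2) * rep(ly$gamma * cache$invstd, each = n)
  } else {
    dXm <- dM * rep(ly$gamma * cache$invstd, each = n)
  }
  dX <- if (length(d) == 3L) array(dXm, d) else dXm
  list(dX = dX, grads = list(gamma = dgamma, beta = dbeta))
}

relu_fwd <- function(ly, X) list(out = pmax(X, 0), cache = list(mask = X > 0))
relu_bwd <- function(ly, dY, cache) list(dX = dY * cache$mask, grads = NULL)

lstm_fwd <- function(ly, X) {
  r <- lstm_fwd_cpp(X, ly$Wx, ly$Wh, ly$b)
  list(out = r$h, cache = list(X = X, I = r$I, Fg = r$Fg, G = r$G, O = r$O,
                               Cs = r$Cs, Hs = r$Hs))
}
lstm_bwd <- function(ly, dh, cache) {
  r <- lstm_bwd_cpp(cache$X, ly$Wx, ly$Wh, cache$I, cache$Fg, cache$G,
                    cache$O, cache$Cs, cache$Hs, dh)
  list(dX = r$dX, grads = list(Wx = r$dWx, Wh = r$dWh, b = as.numeric(r$db)))
}

dropout_fwd <- function(ly, X, training) {
  if (!training || ly$rate <= 0)
    return(list(out = X, cache = list(mask = NULL)))
  mask <- array(runif(length(X)) >= ly$rate, dim(X))
  list(out = X * mask / (1 - ly$rate), cache = list(mask = mask))
}
dropout_bwd <- function(ly, dY, cache) {
  if (is.null(cache$mask)) return(list(dX = dY, grads = NULL))
  list(dX = dY * cache$mask / (1 - ly$rate), grads = NULL)
}

dense_fwd <- function(ly, X) {
  Z <- sweep(X %*% ly$W, 2, ly$b, "+")
  out <- switch(ly$activation, linear = Z, sigmoid = sigmoid(Z),
                stop("unknown head activation"))
  list(out = out, cache = list(X = X, out = out))
}
dense_bwd <- function(ly, dY, cache) {
  dZ <- if (ly$activation == "sigmoid") dY * cache$out * (1 - cache$out) else dY
  list(dX = tcrossprod(dZ, ly$W),
       grads = list(W = crossprod(cache$X, dZ), b = colSums(dZ)))
}

# ---- model-level forward/backward ----------------------------------------

nn_forward <- function(model, X, training = FALSE) {
  caches <- vector("list", length(model$layers))
  for (li in seq_along(model$layers)) {
    ly <- model$layers[[li]]
    r <- switch(ly$type,
      conv = conv_fwd(ly, X),
      bn = bn_fwd(ly, X, training),
      relu = relu_fwd(ly, X),
      lstm = lstm_fwd(ly, X),
      dropout = dropout_fwd(ly, X, training),
      dense = dense_fwd(ly, X))
    X <- r$out
    caches[[li]] <- r$cache
    if (training && ly$type == "bn" && !is.null(r$state_update)) {
      model$layers[[li]]$run_mean <- r$state_update$run_mean
      model$layers[[li]]$run_var <- r$state_update$run_var
      model$layers[[li]]$initialized <- r$state_update$initialized
    }
  }
  list(out = X, caches = caches, model = model)
}

nn_backward <- function(model, caches, dout) {
  grads <- vector("list", length(model$layers))
  for (li in rev(seq_along(model$layers))) {
    ly <- model$layers[[li]]
    r <- switch(ly$type,
      conv = conv_bwd(ly, dout, caches[[li]]),
      bn = bn_bwd(ly, dout, caches[[li]]),
      relu = relu_bwd(ly, dout, caches[[li]]),
      lstm = lstm_bwd(ly, dout, caches[[li]]),
      dropout = dropout_bwd(ly, dout, caches[[li]]),
      dense = dense_bwd(ly, dout, caches[[li]]))
    dout <- r$dX
    grads[li] <- list(r$grads)  # keep NULL entries without shrinking the list
  }
  grads
}


# run_mean/run_var are not trainable but are snapshotted with the weights so
# best-epoch restoration is consistent
PARAM_NAMES <- c("W", "b", "Wx", "Wh", "gamma", "beta", "run_mean", "run_var")

get_params <- function(model)
  lapply(model$layers, function(ly) ly[intersect(PARAM_NAMES, names(ly))])

set_params <- function(model, params) {
  for (li in seq_along(params))
    for (nm in names(params[[li]]))
      model$layers[[li]][[nm]] <- params[[li]][[nm]]
  model
}

adam_init <- function(model) {
  z <- lapply(get_params(model), function(p) lapply(p, function(x) x * 0))
  list(m = z, v = z, t = 0L)
}

adam_step <- function(model, grads, state, lr = 0.001,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t; corr2 <- 1 - beta2^state$t
  for (li in seq_along(grads)) {
    g <- grads[[li]]
    if (is.null(g)) next
    for (nm in names(g)) {
      state$m[[li]][[nm]] <- beta1 * state$m[[li]][[nm]] + (1 - beta1) * g[[nm]]
      state$v[[li]][[nm]] <- beta2 * state$v[[li]][[nm]] + (1 - beta2) * g[[nm]]^2
      mh <- state$m[[li]][[nm]] / corr1
      vh <- state$v[[li]][[nm]] / corr2
      model$layers[[li]][[nm]] <- model$layers[[li]][[nm]] - lr * mh / (sqrt(vh) + eps)
    }
  }
  list(model = model, state = state)
}

# batched inference (no dropout, BN running stats)
nn_predict <- function(model, windows, batch_size = 256L) {
  nw <- dim(windows)[1]
  out <- NULL
  for (s in seq(1L, nw, by = batch_size)) {
    e <- min(s + batch_size - 1L, nw)
    y <- nn_forward(model, windows[s:e, , , drop = FALSE], training = FALSE)$out
    out <- rbind(out, y)
  }
  out
}
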