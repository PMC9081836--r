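#' Default hybrid-model parameters
#'
#' Only the strength coefficient `c_str` and tendon slack coefficient
#' `c_slack` are calibrated in the hybrid model; all other Hill constants are
#' taken from the geometry table.
#'
#' @param muscles muscle labels.
#' @return named list per muscle with `c_str`, `c_slack`.
#' @export
default_hybrid_params <- function(muscles = MUSCLES)
  setNames(lapply(muscles, function(m) list(c_str = 1.0, c_slack = 1.0)),
           muscles)

#' Hybrid calibration search space (c_str, c_slack per muscle)
#' @param muscles muscle labels.
#' @return named list of grids, 8 dimensions for four muscles.
#' @export
hybrid_search_space <- function(muscles = MUSCLES) {
  out <- list()
  for (m in muscles) {
    out[[paste0(m, ".c_str")]] <- seq(0.5, 1.5, by = 0.05)
    out[[paste0(m, ".c_slack")]] <- seq(0.85, 1.15, by = 0.05)
  }
  out
}

# Rigid-tendon fiber kinematics per window: with the tendon fixed at its
# slack length, fiber length follows from the MTU length and constant-
# thickness pennation in closed form:
#   (lm_abs)^2 = (l_mt - l_slack)^2 + (l_opt0 sin a0)^2
# Velocities are successive-window differences of normalized fiber length.
hybrid_kinematics <- function(theta, geom, hp, stride_s) {
  muscles <- names(geom)
  nw <- length(theta)
  lm <- matrix(0, nw, length(muscles)); vm <- lm; ca <- lm; rr <- lm
  for (j in seq_along(muscles)) {
    m <- muscles[j]; g <- geom[[m]]
    lmt <- mtu_length(theta, m, geom)
    lsl <- hp[[m]]$c_slack * g$lslack
    proj <- pmax(lmt - lsl, 0.25 * g$lopt0)
    h <- g$lopt0 * sin(g$penn0)
    lm_abs <- sqrt(proj^2 + h^2)
    ca[, j] <- proj / lm_abs
    lm[, j] <- pmin(pmax(lm_abs / g$lopt0, 0.3), 1.8)
    vm[, j] <- c(0, diff(lm[, j])) / stride_s
    rr[, j] <- moment_arm(theta, m, geom)
  }
  list(lm = lm, vm = vm, cos_a = ca, rarm = rr, muscles = muscles)
}

#' Simplified (passive-free) muscle fiber force
#'
#' `F_m = Fmax0 (a f_v f_a + d_m vhat) cos(alpha)`: the contraction model of
#' the hybrid estimator, with the passive-force term removed so that zero
#' activation at rest yields zero force at any fiber length.
#'
#' @param a activation in \[0,1\].
#' @param lm normalized fiber length.
#' @param v normalized fiber velocity (l_opt/s).
#' @param fmax maximal isometric force (N, already strength-scaled).
#' @param cos_a pennation cosine.
#' @return fiber force (N).
#' @export
simplified_muscle_force <- function(a, lm, v, fmax, cos_a) {
  fmax * (a * force_velocity(v) * active_force_length(lm, a) +
          HILL$dm * v / HILL$vmax) * cos_a
}

# torque per window and its partial derivative wrt each activation
hybrid_torque <- function(act, kin, geom, hp, with_grad = FALSE) {
  muscles <- kin$muscles
  nw <- nrow(act)
  torque <- numeric(nw)
  grad <- if (with_grad) matrix(0, nw, length(muscles)) else NULL
  for (j in seq_along(muscles)) {
    g <- geom[[muscles[j]]]
    fmax <- hp[[muscles[j]]]$c_str * g$fmax0
    a <- act[, j]; lm <- kin$lm[, j]; v <- kin$vm[, j]
    fv <- force_velocity(v)
    fa <- active_force_length(lm, a)
    fm <- fmax * (a * fv * fa + HILL$dm * v / HILL$vmax) * kin$cos_a[, j]
    torque <- torque + fm * kin$rarm[, j]
    if (with_grad) {
      # d fa / d a through the activation-shifted optimum
      lopt_a <- HILL$lambda_a * (1 - a) + 1
      dfa_da <- fa * (2 * (lm - lopt_a) / HILL$gamma_fl) * (-HILL$lambda_a)
      grad[, j] <- fmax * fv * (fa + a * dfa_da) * kin$cos_a[, j] * kin$rarm[, j]
    }
  }
  list(torque = torque, grad = grad)
}

#' Per-muscle activations from the hybrid CNN
#'
#' @param model a trained 4-output sigmoid-head model.
#' @param ds a [windowed_dataset()] (or window array).
#' @return matrix `[n_windows, 4]` of activations in (0,1).
#' @export
activation_cnn <- function(model, ds) {
  windows <- if (inherits(ds, "windowed_dataset")) ds$windows else ds
  if (!identical(as.integer(dim(windows)[2:3]), as.integer(model$input_shape)))
    stop("window shape does not match the model input shape")
  act <- nn_predict(model, windows)
  colnames(act) <- MUSCLES[seq_len(ncol(act))]
  act
}

#' Hybrid torque prediction
#'
#' CNN activations drive the simplified contraction model with rigid-tendon
#' fiber kinematics from window-mean knee angles; per-window torques are
#' smoothed at 1 Hz.
#'
#' @param model trained activation CNN (4-output sigmoid head).
#' @param ds a [windowed_dataset()] carrying window-mean angles.
#' @param geom an `mtu_geometry`.
#' @param hp hybrid parameters (see [default_hybrid_params()]).
#' @param smooth apply output smoothing.
#' @return a [torque_series()] at the window rate.
#' @export
predict_hybrid <- function(model, ds, geom = load_geometry(),
                           hp = default_hybrid_params(), smooth = TRUE) {
  stopifnot(inherits(ds, "windowed_dataset"), !is.null(ds$angle))
  stride_s <- ds$stride / ds$fs
  kin <- hybrid_kinematics(ds$angle, geom, hp, stride_s)
  act <- activation_cnn(model, ds)
  tq <- torque_series(hybrid_torque(act, kin, geom, hp)$torque, ds$fs / ds$stride)
  if (smooth) tq <- smooth_prediction(tq)
  tq
}

hybrid_stage_loss <- function(act, ds, geom, hp) {
  stride_s <- ds$stride / ds$fs
  kin <- hybrid_kinematics(ds$angle, geom, hp, stride_s)
  loss_mse_over_r2(ds$targets, hybrid_torque(act, kin, geom, hp)$torque)
}

calibrate_hybrid_nms <- function(act, ds, geom, n_iter, seed) {
  muscles <- names(geom)
  space <- hybrid_search_space(muscles)
  obj <- function(p) {
    hp <- flat_to_params(unlist(p), muscles)
    hybrid_stage_loss(act, ds, geom, hp)
  }
  res <- tpe_optimize(space, obj, n_iter = n_iter, seed = seed)
  list(hp = flat_to_params(unlist(res$best_params), muscles),
       best_value = res$best_value)
}

train_hybrid_cnn_stage <- function(model, ds, geom, hp, n_epochs, cfg) {
  stride_s <- ds$stride / ds$fs
  kin <- hybrid_kinematics(ds$angle, geom, hp, stride_s)
  nw <- n_windows(ds)
  state <- adam_init(model)
  losses <- c()
  for (epoch in seq_len(n_epochs)) {
    idx <- sample(nw)
    ep <- c()
    for (s in seq(1L, nw, by = cfg$batch_size)) {
      bi <- idx[s:min(s + cfg$batch_size - 1L, nw)]
      if (length(bi) < 2L) next
      fw <- nn_forward(model, ds$windows[bi, , , drop = FALSE], training = TRUE)
      model <- fw$model
      kb <- list(lm = kin$lm[bi, , drop = FALSE], vm = kin$vm[bi, , drop = FALSE],
                 cos_a = kin$cos_a[bi, , drop = FALSE],
                 rarm = kin$rarm[bi, , drop = FALSE], muscles = kin$muscles)
      ht <- hybrid_torque(fw$out, kb, geom, hp, with_grad = TRUE)
      lg <- loss_and_grad(ds$targets[bi], ht$torque)
      if (!is.finite(lg$loss)) stop("hybrid CNN stage diverged (non-finite loss)")
      ep <- c(ep, lg$loss)
      dact <- ht$grad * lg$grad  # chain rule through the muscle layer
      grads <- nn_backward(model, fw$caches, dact)
      up <- adam_step(model, grads, state, lr = cfg$lr)
      model <- up$model; state <- up$state
    }
    losses <- c(losses, mean(ep))
  }
  list(model = model, losses = losses)
}

#' Train the hybrid estimator (alternating schedule)
#'
#' Stage order: (1) muscle-model calibration with window-mean SREs standing in
#' for activations (no activation dynamics); (2) CNN trained on the
#' end-to-end torque loss with muscle parameters frozen; (3) muscle-model
#' recalibration on the CNN activations; (4) CNN again; (5) final
#' muscle-model calibration; (6) final CNN training.  The torque-loss
#' gradient reaches the CNN through the closed-form simplified contraction
#' model (rigid-tendon fiber kinematics), so the muscle layer is exactly
#' differentiable in the activations.
#'
#' @param ds training [windowed_dataset()] (with window-mean angles).
#' @param geom an `mtu_geometry`.
#' @param arch CNN architecture (default: the optimized backbone with a
#'   4-wide sigmoid head).
#' @param schedule list with `nms_iters` (default 500) and `cnn_epochs`
#'   (default 10) per stage.
#' @param seed RNG seed.
#' @param cfg [training_config()] for the CNN stages.
#' @return list with `model`, `hp`, `stage_log` (data.frame with the stage
#'   name, the stage's own objective value `stage_loss`, and a like-for-like
#'   end-to-end `eval_loss` after the stage), `seed`.
#' @export
train_hybrid <- function(ds, geom = load_geometry(),
                         arch = optimized_architecture(4, "sigmoid"),
                         schedule = list(nms_iters = 500, cnn_epochs = 10),
                         seed = 1L, cfg = training_config(seed = seed)) {
  stopifnot(inherits(ds, "windowed_dataset"), !is.null(ds$angle))
  stopifnot(identical(arch$head_activation, "sigmoid"), arch$head_width == 4)
  model <- build_model(arch, input_shape = dim(ds$windows)[2:3], seed = seed)
  set.seed(seed)
  log <- data.frame()
  # stage_loss: the stage's own objective value; eval_loss: a like-for-like
  # end-to-end loss (current activation source -> torque vs reference)
  note <- function(stage, loss, act_src, hp_now)
    log <<- rbind(log, data.frame(stage = stage, stage_loss = loss,
                                  eval_loss = hybrid_stage_loss(act_src, ds,
                                                                geom, hp_now)))

  # stage 1: calibrate on raw window-mean SREs as activation stand-ins
  sre_act <- apply(ds$windows, c(1, 3), mean)
  sre_act <- pmin(pmax(sre_act, 0), 1)
  st1 <- calibrate_hybrid_nms(sre_act, ds, geom, schedule$nms_iters, seed)
  hp <- st1$hp
  note("nms_sre", st1$best_value, sre_act, hp)

  # stage 2: CNN on torque loss, hp frozen
  st2 <- train_hybrid_cnn_stage(model, ds, geom, hp, schedule$cnn_epochs, cfg)
  model <- st2$model
  note("cnn_1", tail(st2$losses, 1), activation_cnn(model, ds), hp)

  # stage 3: recalibrate on CNN activations
  act <- activation_cnn(model, ds)
  st3 <- calibrate_hybrid_nms(act, ds, geom, schedule$nms_iters, seed + 1L)
  hp <- st3$hp
  note("nms_cnn", st3$best_value, act, hp)

  # stage 4: CNN again
  st4 <- train_hybrid_cnn_stage(model, ds, geom, hp, schedule$cnn_epochs, cfg)
  model <- st4$model
  note("cnn_2", tail(st4$losses, 1), activation_cnn(model, ds), hp)

  # stages 5-6: final calibration and final CNN pass
  act <- activation_cnn(model, ds)
  st5 <- calibrate_hybrid_nms(act, ds, geom, schedule$nms_iters, seed + 2L)
  hp <- st5$hp
  note("nms_final", st5$best_value, act, hp)
  st6 <- train_hybrid_cnn_stage(model, ds, geom, hp, schedule$cnn_epochs, cfg)
  model <- st6$model
  note("cnn_final", tail(st6$losses, 1), activation_cnn(model, ds), hp)

  list(model = model, hp = hp, stage_log = log, seed = seed)
}
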