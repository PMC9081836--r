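geom <- load_geometry()

test_that("the simplified contraction model drops the passive term", {
  # zero activation, static: zero force even on a stretched fiber
  expect_equal(simplified_muscle_force(0, 1.5, 0, 1000, 1), 0)
  # all scaling factors at unity: force equals fmax
  expect_equal(simplified_muscle_force(1, 1, 0, 1200, 1), 1200)
  # never exceeds the full model at matched states (passive term >= 0)
  set.seed(6)
  for (k in 1:50) {
    a <- runif(1); lm <- runif(1, 0.6, 1.6); v <- runif(1, -5, 5)
    fmax <- 1000; ca <- runif(1, 0.9, 1)
    full <- fmax * (a * force_velocity(v) * active_force_length(lm, a) +
                    passive_force_length(lm) + 0.1 * v / 10) * ca
    expect_lte(simplified_muscle_force(a, lm, v, fmax, ca), full + 1e-9)
  }
})

test_that("the activation CNN emits four bounded activations per window", {
  arch <- cnn_architecture(1, 16, 3, 16, FALSE, 0.01, 4, "sigmoid")
  mdl <- build_model(arch, input_shape = c(32, 4), seed = 3)
  X <- array(rnorm(7 * 32 * 4), c(7, 32, 4))
  act <- activation_cnn(mdl, X)
  expect_equal(dim(act), c(7, 4))
  expect_true(all(act > 0 & act < 1))
  # feedforward determinism: constant windows give constant activations
  Xc <- array(0.5, c(3, 32, 4))
  ac <- activation_cnn(mdl, Xc)
  expect_equal(ac[1, ], ac[2, ], tolerance = 1e-12)
  expect_error(activation_cnn(mdl, array(0, c(3, 64, 4))), "shape")
})

test_that("hybrid torque respects sign convention and bounds", {
  nw <- 40
  theta <- seq(0.2, 1.4, length.out = nw)
  kin <- myotorque:::hybrid_kinematics(theta, geom, default_hybrid_params(),
                                       stride_s = 0.016)
  ext <- cbind(rep(0.6, nw), rep(0.6, nw), rep(0, nw), rep(0, nw))
  tq_ext <- myotorque:::hybrid_torque(ext, kin, geom, default_hybrid_params())
  expect_true(all(tq_ext$torque > 0))

  bound <- sum(vapply(names(geom), function(m)
    1.5 * geom[[m]]$fmax0 *
      max(abs(moment_arm(seq(-0.1, 2.1, 0.01), m, geom))) * 1.4, 0))
  every <- cbind(rep(1, nw), rep(1, nw), rep(1, nw), rep(1, nw))
  tq_all <- myotorque:::hybrid_torque(every, kin, geom, default_hybrid_params())
  expect_true(all(abs(tq_all$torque) <= bound))
})

test_that("a silent activation CNN yields near-zero torque", {
  tr <- small_trial()
  fs <- 1000; n <- 2000
  static_sre <- envelope_series(matrix(0.05, n, 4), fs, normalized = TRUE)
  static_kin <- kinematic_series(rep(0.9, n), fs)
  static_tq <- torque_series(rep(0, n), fs)
  ds_static <- window_signals(static_sre, static_tq, kin = static_kin)
  arch <- cnn_architecture(1, 16, 3, 16, FALSE, 0.01, 4, "sigmoid")
  mdl <- build_model(arch, input_shape = c(128, 4), seed = 3)
  nl <- length(mdl$layers)
  mdl$layers[[nl]]$W[] <- 0
  mdl$layers[[nl]]$b[] <- -30  # sigmoid(-30) ~ 0
  tq <- predict_hybrid(mdl, ds_static, geom, default_hybrid_params())
  expect_lt(max(abs(tq$torque)), 0.5)
  # on a moving trial only the small velocity-damping term survives
  ds_move <- window_signals(tr$sre, tr$torque, kin = tr$kin)
  tq_m <- predict_hybrid(mdl, ds_move, geom, default_hybrid_params())
  expect_lt(max(abs(tq_m$torque)), 2)
})

test_that("feeding true activations through the hybrid forward path matches the generator", {
  bench <- small_benchmark()
  tr <- bench$days[["1"]][[2]]
  ds <- window_signals(tr$sre, tr$torque, kin = tr$kin)
  # window-mean true activations stand in for the CNN output
  nw <- n_windows(ds)
  starts <- (seq_len(nw) - 1) * ds$stride + 1
  act <- t(vapply(starts, function(s)
    colMeans(tr$activations[s:(s + ds$window_len - 1), ]), numeric(4)))
  kin <- myotorque:::hybrid_kinematics(ds$angle, bench$geom,
                                       default_hybrid_params(), 0.016)
  tq <- torque_series(
    myotorque:::hybrid_torque(act, kin, bench$geom,
                              default_hybrid_params())$torque, 62.5)
  tq <- smooth_prediction(tq)
  err <- nrmse(ds$targets, tq$torque, max(tr$torque$torque),
               min(tr$torque$torque))
  # the structural gap of the simplified model (no passive force, rigid
  # tendon, window-mean kinematics) against the elastic-tendon generator
  expect_lt(err, 6)
})

test_that("alternating training logs its schedule and improves end to end", {
  bench <- small_benchmark()
  ds <- window_trials(bench$days[["1"]][1:3])
  arch <- cnn_architecture(1, 16, 3, 16, TRUE, 0.01, 4, "sigmoid")
  fit <- train_hybrid(ds, bench$geom, arch = arch,
                      schedule = list(nms_iters = 40, cnn_epochs = 2),
                      seed = 5, cfg = training_config(lr = 0.01, seed = 5))
  expect_equal(fit$stage_log$stage,
               c("nms_sre", "cnn_1", "nms_cnn", "cnn_2", "nms_final",
                 "cnn_final"))
  expect_true(all(is.finite(fit$stage_log$eval_loss)))
  expect_true(all(fit$stage_log$eval_loss >= 0))
  for (m in names(fit$hp)) {
    expect_true(fit$hp[[m]]$c_str >= 0.5 && fit$hp[[m]]$c_str <= 1.5)
    expect_true(fit$hp[[m]]$c_slack >= 0.85 && fit$hp[[m]]$c_slack <= 1.15)
  }
  # prediction runs end to end on an unseen trial
  tr <- bench$days[["1"]][[5]]
  ds5 <- window_signals(tr$sre, tr$torque, kin = tr$kin)
  tq <- predict_hybrid(fit$model, ds5, bench$geom, fit$hp)
  expect_equal(length(tq$torque), n_windows(ds5))
})
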