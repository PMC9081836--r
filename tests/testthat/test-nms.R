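geom <- load_geometry()

test_that("activation transfer has exact endpoints and a linear limit", {
  expect_equal(activation_transfer(0, -2), 0)
  expect_equal(activation_transfer(1, -2), 1)
  expect_equal(activation_transfer(0.5, -2), (exp(-1) - 1) / (exp(-2) - 1),
               tolerance = 1e-12)
  # linear limit: a - u ~ A u(1-u)/2, so the gap at A = -0.01 is <= |A|/8
  u <- seq(0, 1, 0.05)
  expect_lt(max(abs(activation_transfer(u, -0.01) - u)), 0.01 / 8 + 1e-6)
  expect_true(all(diff(activation_transfer(u, -2.5)) > 0))
})

test_that("activation dynamics settle to the drive and start at the right slope", {
  expect_equal(neural_activation(rep(0, 100), 20, 30, 1), rep(0, 100))
  u <- neural_activation(rep(0.6, 2000), 20, 30, 1)
  expect_true(all(diff(u) >= -1e-15))  # monotone rise
  expect_lt(abs(u[300] - 0.6), 1e-4)   # steady within 10 tau_act
  # first exponential-Euler step from u=0 with emg=1: tau = 0.5 * 20 ms
  expect_equal(neural_activation(rep(1, 5), 20, 30, 1)[1], 1 - exp(-1 / 10),
               tolerance = 1e-12)
  expect_error(neural_activation(c(0.1, NaN), 20, 30, 1), "finite")
})

test_that("step-decay trajectory converges to the fine-step reference", {
  emg <- c(rep(1, 200), rep(0, 400))
  u1 <- neural_activation(emg, 20, 30, 1)
  ref <- neural_activation(rep(emg, each = 100), 20, 30, 0.01)
  ref_at <- ref[seq(100, 100 * length(emg), by = 100)]
  err1 <- max(abs(u1 - ref_at))
  expect_lt(err1, 0.02)
  # first-order convergence: a 10x finer step shrinks the error ~10x
  u01 <- neural_activation(rep(emg, each = 10), 20, 30, 0.1)
  err01 <- max(abs(u01[seq(10, 10 * length(emg), by = 10)] - ref_at))
  expect_lt(err01, err1 / 5)
})

test_that("activation chain maps [0,1] into [0,1]", {
  set.seed(3)
  for (k in 1:5) {
    emg <- pmin(pmax(butter_zl(abs(rnorm(3000, 0, 0.5)), 4, 1000), 0), 1.5)
    u <- neural_activation(emg, runif(1, 10, 80), runif(1, 10, 80), 1)
    a <- activation_transfer(u, runif(1, -3, -0.01))
    expect_true(all(u >= 0 & u <= 1))
    expect_true(all(a >= 0 & a <= 1))
  }
})

test_that("Hill curves hit their anchor points", {
  # active force-length: peak 1 at the activation-adjusted optimum
  expect_equal(active_force_length(1, 1), 1)
  expect_equal(active_force_length(1.15, 0), 1)
  expect_equal(active_force_length(0.15 * 0.5 + 1, 0.5), 1)
  # passive: zero at optimum, 1 at 60% strain, monotone between
  expect_equal(passive_force_length(1), 0)
  expect_equal(passive_force_length(1.6), 1)
  fp <- passive_force_length(seq(1, 1.6, 0.01))
  expect_true(all(diff(fp) > 0))
  expect_true(passive_force_length(1.3) > 0 && passive_force_length(1.3) < 1)
  # force-velocity: isometric 1, zero at -vmax, eccentric plateau
  expect_equal(force_velocity(0), 1)
  expect_equal(force_velocity(-10), 0)
  expect_gt(force_velocity(5), 1.35)
  expect_true(all(diff(force_velocity(seq(-10, 2, 0.1))) > 0))
  # tendon: slack -> 0, normalization point at 4% strain
  expect_equal(tendon_force_norm(-0.01), 0)
  expect_equal(tendon_force_norm(0), 0)
  expect_equal(tendon_force_norm(0.04), 1, tolerance = 1e-12)
})

test_that("tendon strain arithmetic composes as l_t = l_mt - l_m cos(alpha)", {
  lm_abs <- 0.09; alpha <- 0.1; lslack <- 0.3
  lmt <- lslack * 1.04 + lm_abs * cos(alpha)
  # built to hit 4% strain exactly -> force = fmax
  expect_equal(tendon_force(lmt, lm_abs, alpha, lslack, fmax = 1200), 1200,
               tolerance = 1e-9)
})

test_that("fiber-length solver finds the rest equilibrium exactly", {
  g <- geom$RF
  p <- list(fmax = g$fmax0, lopt = g$lopt0, lslack = g$lslack,
            penn0 = g$penn0, dm = 0.1)
  lmt0 <- g$lslack + g$lopt0 * cos(g$penn0)
  s <- solve_fiber_length(lmt0, a = 0, p)
  expect_equal(s$lm, 1, tolerance = 1e-6)
  expect_lt(abs(s$residual), 1e-3 * g$fmax0)
  expect_lt(abs(s$fm), 1e-3 * g$fmax0)
  # full activation, same stiff-tendon configuration: force near c_str*Fmax0
  s1 <- solve_fiber_length(lmt0, a = 1, p)
  expect_equal(s1$fm, g$fmax0, tolerance = 0.1)
})

test_that("solver equals a dense-grid argmin of the equilibrium residual", {
  set.seed(42)
  g <- geom$VL
  p <- list(fmax = g$fmax0, lopt = g$lopt0, lslack = g$lslack,
            penn0 = g$penn0, dm = 0.1)
  grid <- seq(0.3, 1.8, length.out = 100001)
  residual <- function(lm, a, lmt) {
    ca <- myotorque:::pennation_cos(lm, p$penn0)
    ft <- tendon_force(lmt, lm * p$lopt, acos(ca), p$lslack, p$fmax)
    fm <- p$fmax * (a * force_velocity(0) * active_force_length(lm, a) +
                    passive_force_length(lm)) * ca
    abs(ft - fm)
  }
  for (k in 1:20) {
    a <- runif(1)
    lmt <- runif(1, p$lslack + 0.5 * p$lopt, p$lslack + 1.5 * p$lopt)
    lm_grid <- grid[which.min(residual(grid, a, lmt))]
    lm_solver <- solve_fiber_length(lmt, a, p)$lm
    expect_equal(lm_solver, lm_grid, tolerance = 1e-4)
  }
})

test_that("forward run keeps the equilibrium residual small everywhere", {
  tr <- small_trial()
  out <- myotorque:::nms_forward(tr$activations, tr$kin, geom,
                                 default_nms_params())
  expect_lt(out$max_rel_residual, 1e-3)
  expect_equal(out$n_flagged, 0)
})

test_that("torque prediction respects sign convention and physiological bounds", {
  fs <- 1000; n <- 2000
  static <- kinematic_series(rep(0.8, n), fs)
  zero_sre <- envelope_series(matrix(0, n, 4), fs, normalized = TRUE)
  tq0 <- predict_torque_nms(zero_sre, static, geom)
  expect_lt(max(abs(tq0$torque)), 0.5)

  ext_only <- envelope_series(cbind(RF = rep(0.4, n), VL = rep(0.4, n),
                                    BF = rep(0, n), ST = rep(0, n)),
                              fs, normalized = TRUE)
  tq_ext <- predict_torque_nms(ext_only, static, geom)
  expect_true(all(tq_ext$torque[500:1500] > 0))

  th <- seq(-0.1, 2.1, length.out = 200)
  bound <- sum(vapply(names(geom), function(m)
    1.5 * geom[[m]]$fmax0 * max(abs(moment_arm(th, m, geom))) * 1.4, 0))
  tr <- small_trial()
  pred <- predict_torque_nms(tr$sre, tr$kin, geom, default_nms_params())
  expect_true(all(abs(pred$torque) <= bound))
})

test_that("forward model is deterministic", {
  tr <- small_trial()
  p1 <- predict_torque_nms(tr$sre, tr$kin, geom, default_nms_params())
  p2 <- predict_torque_nms(tr$sre, tr$kin, geom, default_nms_params())
  expect_identical(p1$torque, p2$torque)
})

test_that("calibration guards, bookkeeping and sanity hold on a small search", {
  bench <- small_benchmark()
  trials <- bench$days[["1"]][1:3]
  flat <- torque_series(rep(1, length(trials[[1]]$torque$torque)),
                        trials[[1]]$torque$fs)
  bad <- list(list(sre = trials[[1]]$sre, kin = trials[[1]]$kin, torque = flat))
  expect_error(calibrate_nms(bad, geom, n_iter = 5, seed = 1), "degenerate")

  # data generated away from the default parameter set: calibration should
  # land below the default-parameter loss
  truth <- default_nms_params()
  truth$RF$c_str <- 1.35; truth$VL$c_str <- 0.7
  truth$BF$A <- -2.5; truth$ST$tau_act <- 60
  shifted <- generate_benchmark(protocol_spec(n_trials = 3, extra_cycles = 1),
                                days = 1, seed = 77, true_params = truth)
  strials <- shifted$days[["1"]]
  cal <- calibrate_nms(strials, geom, n_iter = 80, seed = 5, decimation = 8)
  expect_true(all(diff(cal$trace) <= 0))        # best-so-far non-increasing
  expect_equal(cal$best_value, min(cal$history$loss))
  # best parameters respect the search bounds
  for (m in names(cal$params)) {
    expect_true(cal$params[[m]]$c_str >= 0.5 && cal$params[[m]]$c_str <= 1.5)
    expect_true(cal$params[[m]]$A >= -3 && cal$params[[m]]$A <= -0.01)
    expect_true(cal$params[[m]]$tau_act >= 10 && cal$params[[m]]$tau_act <= 80)
  }
  muscles <- names(geom)
  dec <- lapply(strials, myotorque:::decimate_trial, q = 8)
  default_loss <- myotorque:::nms_training_loss(
    unlist(lapply(muscles, function(m)
      setNames(default_nms_params()[[m]],
               paste(m, names(default_nms_params()[[m]]), sep = ".")))),
    dec, geom, muscles)
  expect_lt(cal$best_value, default_loss)
})
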