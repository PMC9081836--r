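spec <- protocol_spec(n_trials = 2, extra_cycles = 1)
geom <- load_geometry()

test_that("kinematics are seeded, bounded and follow the routine", {
  k1 <- generate_kinematics(spec, seed = 21)
  k2 <- generate_kinematics(spec, seed = 21)
  expect_identical(k1$angle, k2$angle)
  expect_false(identical(k1$angle, generate_kinematics(spec, seed = 22)$angle))
  expect_true(all(k1$angle >= 0 & k1$angle <= 100 * pi / 180))
  # the routine reaches full extension and returns to ~90 degrees
  expect_lt(min(k1$angle), 0.02)
  expect_gt(max(k1$angle[1:500]), 80 * pi / 180)
  # the first extension sweep is monotone non-increasing
  ext_start <- which(diff(k1$angle) < -1e-6)[1]
  ext_end <- which(k1$angle < 0.01)[1]
  expect_true(all(diff(k1$angle[ext_start:ext_end]) <= 1e-12))
})

test_that("ground-truth activations follow the phase structure", {
  kin <- generate_kinematics(spec, seed = 31)
  act <- generate_activations(kin, seed = 32)
  expect_true(all(act >= 0 & act <= 1))
  expect_equal(colnames(act), c("RF", "VL", "BF", "ST"))
  # low tonic activation during the initial 90-degree hold
  hold <- seq_len(round(0.5 * kin$fs))
  expect_lt(max(act[hold, ]), 0.15)
  # quadriceps peak inside the extension movement, not during holds
  dtheta <- myotorque:::num_gradient(kin$angle, 1 / kin$fs)
  quad <- act[, "RF"] + act[, "VL"]
  expect_lt(abs(dtheta[which.max(quad)]), Inf)
  expect_gt(max(quad[dtheta < -0.3]), max(quad[hold]))
  # extensors dominate during extension, flexors during flexion
  expect_gt(mean((act[, "RF"] + act[, "VL"])[dtheta < -0.5]),
            mean((act[, "BF"] + act[, "ST"])[dtheta < -0.5]))
  expect_gt(mean((act[, "BF"] + act[, "ST"])[dtheta > 0.5]),
            mean((act[, "RF"] + act[, "VL"])[dtheta > 0.5]))
})

test_that("reference torque is quiet at rest and signed by muscle group", {
  fs <- 1000
  static <- kinematic_series(rep(0.8, 3000), fs)
  zero_act <- matrix(0.0, 3000, 4, dimnames = list(NULL, c("RF", "VL", "BF", "ST")))
  tq0 <- simulate_torque(static, zero_act, geom)
  expect_lt(max(abs(tq0$torque)), 0.5)

  ext_act <- zero_act; ext_act[, c("RF", "VL")] <- 0.5
  expect_gt(min(simulate_torque(static, ext_act, geom)$torque[500:2500]), 0)
  flx_act <- zero_act; flx_act[, c("BF", "ST")] <- 0.5
  expect_lt(max(simulate_torque(static, flx_act, geom)$torque[500:2500]), 0)
})

test_that("the NMS model at generating truth reproduces the reference torque", {
  tr <- small_trial()
  pred <- predict_torque_nms(tr$sre, tr$kin, small_benchmark()$geom,
                             small_benchmark()$true_params)
  err <- nrmse(tr$torque$torque, pred$torque,
               max(tr$torque$torque), min(tr$torque$torque))
  # residual is the injected envelope noise (SD 0.02, 6 Hz band) carried
  # through the activation chain; noise-free regeneration is exact
  expect_lt(err, 3)
  clean <- generate_benchmark(protocol_spec(n_trials = 1, extra_cycles = 1),
                              days = 1, seed = small_benchmark()$seed,
                              drift = day_drift(noise_sd = 0))
  tc <- clean$days[["1"]][[1]]
  pc <- predict_torque_nms(tc$sre, tc$kin, clean$geom, clean$true_params)
  expect_lt(nrmse(tc$torque$torque, pc$torque, max(tc$torque$torque),
                  min(tc$torque$torque)), 0.5)
})

test_that("envelope synthesis inverts the activation chain", {
  kin <- generate_kinematics(spec, seed = 41)
  act <- generate_activations(kin, seed = 42)
  clean <- day_drift(noise_sd = 0)
  env <- generate_emg_envelopes(act, drift = clean, day = 1, seed = 43)
  expect_true(all(env$values >= 0))
  p <- default_true_params()
  for (m in c("RF", "ST")) {
    u <- neural_activation(env$values[, m], p[[m]]$tau_act, p[[m]]$tau_deact, 1)
    a <- activation_transfer(u, p[[m]]$A)
    rel_rms <- sqrt(mean((a - act[, m])^2)) / sqrt(mean(act[, m]^2))
    expect_lt(rel_rms, 0.05)
  }
  # per-muscle gains act linearly on the envelope
  e1 <- generate_emg_envelopes(act, drift = clean, seed = 44,
                               gains = c(1, 1, 1, 1))
  e2 <- generate_emg_envelopes(act, drift = clean, seed = 44,
                               gains = c(2, 1, 1, 1))
  expect_equal(e2$values[, "RF"], 2 * e1$values[, "RF"], tolerance = 1e-12)
  expect_equal(e2$values[, "VL"], e1$values[, "VL"], tolerance = 1e-12)
})

test_that("raw-EMG carrier wrapping survives envelope extraction", {
  kin <- generate_kinematics(spec, seed = 51)
  act <- generate_activations(kin, seed = 52)
  env <- generate_emg_envelopes(act, drift = day_drift(noise_sd = 0), seed = 53)
  raw <- generate_raw_emg(env, seed = 54)
  expect_s3_class(raw, "raw_emg")
  expect_equal(raw$fs, 2000)
  sre <- compute_sre(raw)
  sync <- resample_and_sync(sre, kin)
  n <- nrow(sync$emg$values)
  mid <- round(0.1 * n):round(0.9 * n)
  ref <- approx(seq_along(env$values[, "VL"]) / env$fs, env$values[, "VL"],
                xout = mid / 1000)$y
  expect_gt(cor(sync$emg$values[mid, "VL"], ref), 0.95)
})

test_that("benchmark generation is reproducible and drift is day-gated", {
  b1 <- generate_benchmark(spec, days = c(1, 2), seed = 61)
  b2 <- generate_benchmark(spec, days = c(1, 2), seed = 61)
  expect_identical(b1$days[["1"]][[1]]$sre$values,
                   b2$days[["1"]][[1]]$sre$values)
  expect_identical(b1$days[["2"]][[2]]$torque$torque,
                   b2$days[["2"]][[2]]$torque$torque)
  # disabling drift leaves day-2 generation identical apart from sampling
  off <- day_drift(enabled = FALSE)
  b3 <- generate_benchmark(spec, days = 2, seed = 61, drift = off)
  b4 <- generate_benchmark(spec, days = 2, seed = 61, drift = off)
  expect_identical(b3$days[["2"]][[1]]$sre$values,
                   b4$days[["2"]][[1]]$sre$values)
  # with drift enabled, day-2 envelopes differ from the drift-free stream
  expect_false(identical(b1$days[["2"]][[1]]$sre$values,
                         b3$days[["2"]][[1]]$sre$values))
  # but the underlying kinematics/truth are the same stream
  expect_identical(b1$days[["2"]][[1]]$kin$angle, b3$days[["2"]][[1]]$kin$angle)
})
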