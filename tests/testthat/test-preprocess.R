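test_that("envelope extraction rejects DC, passes rectified amplitude", {
  fs <- 2000
  n <- 3 * fs
  zero <- raw_emg(matrix(0, n, 4), fs)
  expect_equal(max(abs(compute_sre(zero)$values)), 0)

  dc <- raw_emg(matrix(1, n, 4), fs)
  env_dc <- compute_sre(dc)$values
  mid <- (fs):(2 * fs)  # after settling
  expect_lt(max(env_dc[mid, ]), 1e-3)

  t <- (seq_len(n) - 1) / fs
  s50 <- raw_emg(matrix(sin(2 * pi * 50 * t), n, 4), fs)
  env <- compute_sre(s50)$values
  # analytic oracle: mean of |sin| = 2/pi, within 5% (high-pass shaves a bit)
  expect_equal(mean(env[mid, 1]), 2 / pi, tolerance = 0.05)
})

test_that("too-short signals for the envelope filters are rejected", {
  fs <- 2000
  short <- raw_emg(matrix(rnorm(200 * 4), 200, 4), fs)
  expect_error(compute_sre(short), "shorter")
})

test_that("MVC normalization scales by the smoothed MVC peak", {
  fs <- 1000
  t <- (seq_len(3 * fs) - 1) / fs
  burst <- exp(-((t - 1.5) / 0.5)^2)  # smooth 1-peak effort
  env <- envelope_series(outer(burst, c(1, 2, 0.5, 1)), fs)
  smoothed_max <- function(x) {
    w <- round(0.5 * fs)
    max(stats::filter(x, rep(1 / w, w), sides = 2), na.rm = TRUE)
  }
  self_norm <- normalize_by_mvc(env, env)
  # a trial identical to the MVC trial has smoothed peak 1 on every channel
  expect_equal(unname(apply(self_norm$values, 2, smoothed_max)), rep(1, 4),
               tolerance = 1e-9)

  half <- envelope_series(0.5 * env$values, fs)
  expect_equal(unname(apply(normalize_by_mvc(half, env)$values, 2, smoothed_max)),
               rep(0.5, 4), tolerance = 1e-9)

  expect_error(normalize_by_mvc(env, envelope_series(matrix(0, 3 * fs, 4), fs)),
               "positive")
})

test_that("resampling aligns EMG and kinematics on a 1 kHz clock", {
  emg <- envelope_series(matrix(0.4, 2000, 4), fs = 2000)
  kin <- kinematic_series(rep(0.5, 240), fs = 240)
  out <- resample_and_sync(emg, kin)
  expect_equal(out$emg$fs, 1000)
  expect_equal(out$kin$fs, 1000)
  expect_equal(nrow(out$emg$values), length(out$kin$angle))
  # common support [0, 239/240] at 1 kHz -> floor(0.99583/1e-3)+1 samples
  expect_equal(length(out$kin$angle), floor((239 / 240) * 1000) + 1)
  expect_equal(unique(as.numeric(out$emg$values)), 0.4)
  expect_equal(unique(out$kin$angle), 0.5)

  # linear ramp survives interpolation to 1e-6
  ramp <- kinematic_series(seq(0, 1, length.out = 240), fs = 240)
  out2 <- resample_and_sync(emg, ramp)
  tt <- seq(0, 239 / 240, by = 1e-3)
  expect_equal(out2$kin$angle, tt / (239 / 240), tolerance = 1e-6)

  late <- kinematic_series(rep(0.5, 240), fs = 240)
  expect_error(resample_and_sync(emg, late, t0_kin = 10), "overlap")
})

test_that("windowing counts, targets and boundary cases follow the contract", {
  fs <- 1000
  env <- envelope_series(matrix(0.1, 1000, 4), fs)
  tq <- torque_series(rep(3.5, 1000), fs)
  ds <- window_signals(env, tq)
  expect_equal(n_windows(ds), 55)  # floor((1000-128)/16)+1
  expect_equal(ds$targets, rep(3.5, 55))

  one <- window_signals(envelope_series(matrix(0, 128, 4), fs),
                        torque_series(rnorm(128), fs))
  expect_equal(n_windows(one), 1)

  expect_error(window_signals(envelope_series(matrix(0, 100, 4), fs),
                              torque_series(rnorm(100), fs)), "shorter")
})

test_that("window targets conserve mass over the covered span", {
  fs <- 1000
  n <- 1000
  env <- envelope_series(matrix(0, n, 4), fs)
  # constant torque: sum(targets) * stride = c * covered length, exactly
  ds_c <- window_signals(env, torque_series(rep(2, n), fs))
  expect_identical(sum(ds_c$targets) * 16, 2 * n_windows(ds_c) * 16)
  # linear torque: window means are midpoint values, so the stride-cell
  # integral around the window centers matches exactly
  a <- 1.5; b <- 0.02
  tq <- torque_series(a + b * (seq_len(n) - 1), fs)
  ds_l <- window_signals(env, tq)
  centers <- (seq_len(n_windows(ds_l)) - 1) * 16 + (0 + 127) / 2
  expect_equal(sum(ds_l$targets) * 16, sum(a + b * centers) * 16,
               tolerance = 1e-12)
})

test_that("prediction smoothing is zero-lag with unit DC gain", {
  fs <- 62.5
  const <- torque_series(rep(7, 500), fs)
  expect_equal(smooth_prediction(const)$torque, rep(7, 500), tolerance = 1e-9)

  t <- (seq_len(2000) - 1) / fs
  s10 <- torque_series(sin(2 * pi * 10 * t), fs)
  out <- smooth_prediction(s10)$torque
  expect_lt(max(abs(out[200:1800])), 0.01)  # > 99% attenuation at 10x cutoff

  expect_equal(smooth_prediction(torque_series(rep(0, 500), fs))$torque,
               rep(0, 500))
})

test_that("forward-backward filtering has zero group delay", {
  fs <- 1000
  t <- (seq_len(4000) - 1) / fs
  x <- exp(-((t - 2) / 0.3)^2)  # band-limited bump
  y <- butter_zl(x, 6, fs)
  cc <- stats::ccf(y, x, lag.max = 50, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("preprocessing is deterministic", {
  set.seed(1)
  x <- matrix(abs(rnorm(4000 * 4)), 4000, 4)
  r1 <- compute_sre(raw_emg(x, 2000))
  r2 <- compute_sre(raw_emg(x, 2000))
  expect_identical(r1$values, r2$values)
})
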