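# Seeded generator of the non-weight-bearing stool protocol: smooth knee
# trajectories, physiologically patterned ground-truth activations, reference
# torque from the full forward NMS model at known parameters, and noisy EMG
# envelopes obtained by inverting the activation chain, with optional
# day-to-day drift (electrode gain, MVC error, timing).

#' Protocol description for the synthetic stool routine
#'
#' One trial: hold at ~90 deg knee flexion, extend fully, hold, flex back to
#' 90 deg, then `extra_cycles` further extension/flexion cycles.  Phase
#' durations are jittered per trial (log-normal cadence jitter).
#'
#' @param n_trials trials per day (default 40).
#' @param hold_s nominal hold duration (s).
#' @param move_s nominal extension/flexion movement duration (s).
#' @param extra_cycles additional flexion/extension cycles per trial.
#' @param jitter_sd log-normal SD of the cadence jitter.
#' @param peak_flexion_deg flexed knee angle (deg).
#' @param fs sampling rate (Hz).
#' @return a `protocol_spec` list.
#' @export
protocol_spec <- function(n_trials = 40, hold_s = 1.0, move_s = 1.2,
                          extra_cycles = 2, jitter_sd = 0.05,
                          peak_flexion_deg = 90, fs = 1000) {
  stopifnot(peak_flexion_deg > 0, peak_flexion_deg <= 100)
  structure(list(n_trials = n_trials, hold_s = hold_s, move_s = move_s,
                 extra_cycles = extra_cycles, jitter_sd = jitter_sd,
                 peak_flexion_deg = peak_flexion_deg, fs = fs),
            class = "protocol_spec")
}

#' Day-to-day drift description
#'
#' Emulates between-day differences in electrode placement and MVC
#' normalization: per-muscle multiplicative envelope gain (log-normal),
#' per-muscle MVC-reference error multiplier (log-normal), additive envelope
#' noise, and a global timing offset between EMG and kinematics.
#'
#' @param sigma_gain log-SD of the per-muscle envelope gain (default 0.15).
#' @param sigma_mvc log-SD of the MVC-reference error (default 0.05).
#' @param noise_sd additive Gaussian envelope noise SD (default 0.02),
#'   applied on every day.
#' @param timing_sd_ms SD of the EMG-kinematics timing offset (ms).
#' @param enabled drift multipliers applied on days > 1 (noise is always on).
#' @return a `day_drift` list.
#' @export
day_drift <- function(sigma_gain = 0.15, sigma_mvc = 0.05, noise_sd = 0.02,
                      timing_sd_ms = 10, enabled = TRUE)
  structure(list(sigma_gain = sigma_gain, sigma_mvc = sigma_mvc,
                 noise_sd = noise_sd, timing_sd_ms = timing_sd_ms,
                 enabled = enabled), class = "day_drift")

# quintic minimum-jerk ramp on [0,1]
min_jerk <- function(s) s^3 * (10 - 15 * s + 6 * s^2)

#' Generate one trial's knee-angle trajectory
#'
#' @param spec a [protocol_spec()].
#' @param seed RNG seed (per trial).
#' @return a [kinematic_series()] (rad, 0 = full extension).
#' @export
generate_kinematics <- function(spec, seed = 1L) {
  set.seed(seed)
  peak <- spec$peak_flexion_deg * pi / 180
  segs <- list(c(peak, peak, spec$hold_s),       # hold flexed
               c(peak, 0, spec$move_s),          # extend
               c(0, 0, 0.5 * spec$hold_s),       # hold extended
               c(0, peak, spec$move_s))          # flex back
  for (k in seq_len(spec$extra_cycles)) {
    segs <- c(segs, list(c(peak, 0, spec$move_s), c(0, 0, 0.25 * spec$hold_s),
                         c(0, peak, spec$move_s), c(peak, peak, 0.25 * spec$hold_s)))
  }
  angle <- c()
  for (sg in segs) {
    dur <- sg[3] * exp(rnorm(1, 0, spec$jitter_sd))
    n <- max(2L, round(dur * spec$fs))
    s <- min_jerk(seq(0, 1, length.out = n))
    angle <- c(angle, sg[1] + (sg[2] - sg[1]) * s)
  }
  angle <- pmin(pmax(angle, 0), 100 * pi / 180)
  kinematic_series(angle, spec$fs)
}

num_gradient <- function(x, dt) {
  n <- length(x)
  g <- numeric(n)
  g[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  g[1] <- (x[2] - x[1]) / dt
  g[n] <- (x[n] - x[n - 1]) / dt
  g
}

#' Generate ground-truth muscle activations for a trial
#'
#' Extensors (RF, VL) are driven by extension velocity and by the
#' gravitational demand of supporting the raised shank (maximal near full
#' extension, zero with the shank vertical at 90 deg); flexors (BF, ST) by
#' flexion velocity.  A 0.02 cocontraction floor is always present and
#' activations are smoothed and clamped to \[0,1\].
#'
#' @param kin a [kinematic_series()].
#' @param seed RNG seed (per-trial effort variability).
#' @return numeric matrix `[N, 4]`, columns RF, VL, BF, ST.
#' @export
generate_activations <- function(kin, seed = 1L) {
  set.seed(seed)
  theta <- kin$angle
  dtheta <- num_gradient(theta, 1 / kin$fs)
  vref <- 1.5  # rad/s, typical peak movement speed of the routine
  flex_frac <- pmin(pmax(dtheta, 0) / vref, 1)
  # extensors support the raised shank against gravity but relax while the
  # knee is actively flexed (gravity lowers the shank)
  grav <- 0.30 * pmax(cos(theta), 0) * (1 - 0.8 * flex_frac)
  ext_v <- 0.50 * pmin(pmax(-dtheta, 0) / vref, 1.2)
  flx_v <- 0.75 * pmin(flex_frac, 1.2)  # brisk active flexion recruits the
                                        # hamstrings close to maximally
  effort <- exp(rnorm(4, 0, 0.08))  # per-muscle per-trial effort variation
  # distinct recruitment shapes per muscle (phasic vs tonic, angle-weighted)
  # so no two muscles are driven by proportional commands
  theta_n <- theta / max(theta)
  act <- cbind(RF = effort[1] * (0.35 * grav + 1.00 * ext_v),
               VL = effort[2] * (1.25 * grav + 0.30 * ext_v),
               BF = effort[3] * flx_v * (1.25 - 0.75 * theta_n),
               ST = effort[4] * flx_v * (0.45 + 0.95 * theta_n))
  act <- apply(act, 2, function(x) butter_zl(x, 2, kin$fs))
  act <- pmin(pmax(act, 0.02), 1)
  colnames(act) <- MUSCLES
  act
}

#' Default generating-truth NMS parameters
#'
#' All calibration coefficients at mid-range; used both as the generator's
#' truth and as the target of the parameter-recovery experiments.
#'
#' @return per-muscle parameter list (same shape as [default_nms_params()]).
#' @export
default_true_params <- function() default_nms_params()

#' Reference torque by forward simulation at known parameters
#'
#' Runs the full NMS contraction dynamics (elastic tendon, passive force)
#' on the true activations and smooths at 1 Hz: this is the reference torque
#' every model is trained against.
#'
#' @param kin a [kinematic_series()].
#' @param act activation matrix `[N, 4]`.
#' @param geom an `mtu_geometry`.
#' @param true_params generating parameters.
#' @return a [torque_series()].
#' @export
simulate_torque <- function(kin, act, geom = load_geometry(),
                            true_params = default_true_params())
  nms_forward(act, kin, geom, true_params, smooth = TRUE)$torque

# inverse of the activation chain: a -> u (closed form), then u -> envelope
# by inverting the exponential-Euler step of the activation ODE exactly:
# u[k] = e + (u[k-1] - e) exp(-dt/tau(u[k-1], e)) solved for e, with the
# activation/deactivation branch fixed by the sign of the step.
invert_activation <- function(act, A, tau_act, tau_deact, fs) {
  u <- log(1 + act * (exp(A) - 1)) / A
  n <- length(u)
  dt_ms <- 1000 / fs
  up <- u[-n]; un <- u[-1]
  aa <- exp(-dt_ms / (tau_act * (0.5 + 1.5 * up)))
  ad <- exp(-dt_ms / (tau_deact / (0.5 + 1.5 * up)))
  e_act <- (un - up * aa) / (1 - aa)
  e_de <- (un - up * ad) / (1 - ad)
  e <- c(u[1], ifelse(un > up, e_act, e_de))
  pmax(e, 0)
}

#' Synthesize noisy MVC-normalized EMG envelopes from true activations
#'
#' Envelope = per-muscle gain x MVC-error x inverse activation chain, plus
#' additive Gaussian noise, clipped at zero, optionally time-shifted
#' (drift timing offset).  On day 1 (or with drift disabled) all multipliers
#' are 1 and the offset 0.
#'
#' @param act activation matrix `[N, 4]`.
#' @param params generating activation parameters (per muscle `A`, `tau_act`,
#'   `tau_deact`).
#' @param drift a [day_drift()].
#' @param day day label (drift multipliers apply for day > 1).
#' @param fs sampling rate (Hz).
#' @param seed RNG seed.
#' @param gains optional fixed per-muscle gain vector (normally the day-level
#'   multipliers from [sample_day_drift()]).
#' @param mvc optional fixed per-muscle MVC-error multipliers.
#' @param shift optional timing offset in samples.
#' @return a normalized [envelope_series()].
#' @export
generate_emg_envelopes <- function(act, params = default_true_params(),
                                   drift = day_drift(), day = 1, fs = 1000,
                                   seed = 1L, gains = NULL, mvc = NULL,
                                   shift = NULL) {
  stopifnot(all(act >= 0 & act <= 1))
  set.seed(seed)
  m <- ncol(act)
  apply_drift <- drift$enabled && day > 1
  if (is.null(gains))
    gains <- if (apply_drift) exp(rnorm(m, 0, drift$sigma_gain)) else rep(1, m)
  if (is.null(mvc))
    mvc <- if (apply_drift) exp(rnorm(m, 0, drift$sigma_mvc)) else rep(1, m)
  if (is.null(shift))
    shift <- if (apply_drift) round(rnorm(1, 0, drift$timing_sd_ms) * fs / 1000) else 0L
  env <- matrix(0, nrow(act), m)
  for (j in seq_len(m)) {
    p <- params[[colnames(act)[j]]]
    e <- invert_activation(act[, j], p$A, p$tau_act, p$tau_deact, fs)
    env[, j] <- gains[j] * mvc[j] * e
  }
  if (shift != 0L) {
    n <- nrow(env)
    if (shift > 0)
      env <- rbind(env[rep(1L, shift), , drop = FALSE],
                   env[1:(n - shift), , drop = FALSE])
    else
      env <- rbind(env[(1 - shift):n, , drop = FALSE],
                   env[rep(n, -shift), , drop = FALSE])
  }
  if (drift$noise_sd > 0) {
    # envelope noise is band-limited like the envelope itself (6 Hz), scaled
    # to the requested SD after filtering
    noise <- apply(matrix(rnorm(length(env)), nrow(env)), 2, function(x) {
      nf <- butter_zl(x, 6, fs)
      nf / sd(nf) * drift$noise_sd
    })
    env <- env + noise
  }
  env <- pmax(env, 0)
  colnames(env) <- colnames(act)
  envelope_series(env, fs, normalized = TRUE)
}

#' Wrap an envelope into a synthetic raw-EMG carrier
#'
#' Amplitude-modulates band-limited (20-450 Hz) Gaussian noise at 2 kHz by
#' the envelope, for exercising the raw-EMG preprocessing chain.
#'
#' @param env an [envelope_series()] (values taken as modulation in mV).
#' @param fs_out carrier sampling rate (Hz, default 2000).
#' @param seed RNG seed.
#' @return a [raw_emg()] at `fs_out`.
#' @export
generate_raw_emg <- function(env, fs_out = 2000, seed = 1L) {
  set.seed(seed)
  n_in <- nrow(env$values)
  t_in <- (seq_len(n_in) - 1L) / env$fs
  n_out <- floor(t_in[n_in] * fs_out) + 1L
  t_out <- (seq_len(n_out) - 1L) / fs_out
  bp <- signal::butter(2, c(20, 450) / (fs_out / 2), type = "pass")
  samples <- sapply(seq_len(ncol(env$values)), function(j) {
    e <- approx(t_in, env$values[, j], xout = t_out)$y
    carrier <- filtfilt_zl(bp$b, bp$a, rnorm(n_out))
    carrier <- carrier / sd(carrier)
    e * carrier / (2 / pi)  # so the rectified-mean envelope matches e
  })
  colnames(samples) <- colnames(env$values)
  raw_emg(samples, fs_out)
}

trial_seed <- function(seed, day, trial) {
  (seed * 1009L + day * 131L + trial * 7L) %% 2147483563L
}

#' Sample the day-level drift multipliers
#'
#' Electrode-placement gain and MVC-reference error are properties of a
#' measurement session: they are drawn once per day and shared by all of that
#' day's trials.  Day 1 (or disabled drift) gives identity multipliers.
#'
#' @param drift a [day_drift()].
#' @param day day label.
#' @param seed benchmark master seed.
#' @return list with `gains`, `mvc` (length-4 multipliers) and `shift`
#'   (samples at 1 kHz).
#' @export
sample_day_drift <- function(drift, day, seed) {
  if (!drift$enabled || day <= 1)
    return(list(gains = rep(1, 4), mvc = rep(1, 4), shift = 0L))
  set.seed((seed * 2003L + day * 17L) %% 2147483563L)
  list(gains = exp(rnorm(4, 0, drift$sigma_gain)),
       mvc = exp(rnorm(4, 0, drift$sigma_mvc)),
       shift = as.integer(round(rnorm(1, 0, drift$timing_sd_ms))))
}

#' Generate the full multi-day synthetic benchmark
#'
#' For each requested day, generates `n_trials` trials of the stool routine:
#' kinematics, true activations, reference torque (forward NMS at
#' `true_params`), and drifted noisy envelopes.  All randomness flows from
#' the master seed; day 1 carries no drift multipliers.
#'
#' @param spec a [protocol_spec()].
#' @param days integer vector of day labels (default `c(1, 2, 3, 7)`).
#' @param seed master seed.
#' @param drift a [day_drift()].
#' @param geom an `mtu_geometry`.
#' @param true_params generating parameters.
#' @return a `synthetic_benchmark`: list with `days` (named list of trial
#'   lists; each trial has `sre`, `kin`, `torque`, `activations`), `geom`,
#'   `true_params`, `spec`, `drift`, `seed`.
#' @export
generate_benchmark <- function(spec = protocol_spec(), days = c(1, 2, 3, 7),
                               seed = 1L, drift = day_drift(),
                               geom = load_geometry(),
                               true_params = default_true_params()) {
  out <- list()
  for (d in days) {
    dd <- sample_day_drift(drift, d, seed)
    trials <- vector("list", spec$n_trials)
    for (i in seq_len(spec$n_trials)) {
      ts <- trial_seed(seed, d, i)
      kin <- generate_kinematics(spec, ts)
      act <- generate_activations(kin, ts + 1L)
      tq <- simulate_torque(kin, act, geom, true_params)
      env <- generate_emg_envelopes(act, true_params, drift, day = d,
                                    fs = spec$fs, seed = ts + 2L,
                                    gains = dd$gains, mvc = dd$mvc,
                                    shift = dd$shift)
      trials[[i]] <- list(sre = env, kin = kin, torque = tq,
                          activations = act)
    }
    out[[as.character(d)]] <- trials
  }
  structure(list(days = out, geom = geom, true_params = true_params,
                 spec = spec, drift = drift, seed = seed),
            class = "synthetic_benchmark")
}

#' @export
print.synthetic_benchmark <- function(x, ...) {
  cat(sprintf("<synthetic_benchmark> days %s, %d trials/day, seed %d\n",
              paste(names(x$days), collapse = ","), x$spec$n_trials, x$seed))
  invisible(x)
}
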