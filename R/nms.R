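#' Default per-muscle NMS parameters
#'
#' Calibratable parameters at their mid-range defaults: activation and
#' deactivation time constants (ms), transfer shape factor `A`, and the three
#' scaling coefficients applied to the geometry table's Hill constants
#' (`c_str` on maximal isometric force, `c_slack` on tendon slack length,
#' `c_opt0` on optimal fiber length).
#'
#' @param muscles character vector of muscle labels.
#' @return named list per muscle of parameter lists.
#' @export
default_nms_params <- function(muscles = MUSCLES) {
  one <- list(tau_act = 30, tau_deact = 40, A = -1.5,
              c_str = 1.0, c_slack = 1.0, c_opt0 = 1.0)
  setNames(lapply(muscles, function(m) one), muscles)
}

#' Calibration search space of the NMS model
#'
#' The discrete per-muscle grids searched by the calibration routine:
#' `tau_act`, `tau_deact` 10-80 ms (step 0.1), `A` -3 to -0.01 (step 0.001),
#' `c_str` 0.5-1.5 (step 0.05), `c_slack` and `c_opt0` 0.85-1.15 (step 0.05).
#'
#' @param muscles character vector of muscle labels.
#' @return named list of numeric grids (`<muscle>.<param>`), 24 dimensions
#'   for the default four muscles.
#' @export
nms_search_space <- function(muscles = MUSCLES) {
  grids <- list(tau_act = seq(10, 80, by = 0.1),
                tau_deact = seq(10, 80, by = 0.1),
                A = seq(-3, -0.01, by = 0.001),
                c_str = seq(0.5, 1.5, by = 0.05),
                c_slack = seq(0.85, 1.15, by = 0.05),
                c_opt0 = seq(0.85, 1.15, by = 0.05))
  out <- list()
  for (m in muscles)
    for (p in names(grids))
      out[[paste(m, p, sep = ".")]] <- grids[[p]]
  out
}

flat_to_params <- function(flat, muscles = MUSCLES) {
  out <- list()
  for (m in muscles) {
    pref <- paste0(m, ".")
    keys <- names(flat)[startsWith(names(flat), pref)]
    out[[m]] <- setNames(lapply(flat[keys], identity),
                         sub(pref, "", keys, fixed = TRUE))
  }
  out
}

# scaled Hill constants for the forward solver
scaled_constants <- function(geom, params, muscles = MUSCLES) {
  list(fmax = vapply(muscles, function(m) params[[m]]$c_str * geom[[m]]$fmax0, 0),
       lopt = vapply(muscles, function(m) params[[m]]$c_opt0 * geom[[m]]$lopt0, 0),
       lslack = vapply(muscles, function(m) params[[m]]$c_slack * geom[[m]]$lslack, 0),
       penn0 = vapply(muscles, function(m) geom[[m]]$penn0, 0),
       dm = rep(HILL$dm, length(muscles)))
}

#' Forward NMS torque prediction from muscle activations
#'
#' Runs the contraction dynamics (tendon-fiber equilibrium per sample) and
#' joint mechanics for given per-muscle activation series; used both by
#' [predict_torque_nms()] and by the synthetic generator and hybrid model.
#'
#' @param act numeric matrix `[N, 4]` of muscle activations in \[0,1\].
#' @param kin a [kinematic_series()] aligned with `act`.
#' @param geom an `mtu_geometry`.
#' @param params per-muscle parameter list (see [default_nms_params()]).
#' @param smooth apply the 1 Hz zero-lag output smoothing.
#' @return list with `torque` (a [torque_series()]), `lm`, `fm`,
#'   `max_rel_residual`, `n_flagged`.
#' @export
nms_forward <- function(act, kin, geom, params, smooth = TRUE) {
  muscles <- names(geom)
  n <- length(kin$angle)
  stopifnot(nrow(act) == n)
  lmt <- sapply(muscles, function(m) mtu_length(kin$angle, m, geom))
  rarm <- sapply(muscles, function(m) moment_arm(kin$angle, m, geom))
  sc <- scaled_constants(geom, params, muscles)
  out <- nms_forward_cpp(act, lmt, rarm, sc$fmax, sc$lopt, sc$lslack,
                         sc$penn0, sc$dm, 1 / kin$fs)
  tq <- torque_series(out$torque, kin$fs)
  if (smooth) tq <- smooth_prediction(tq)
  list(torque = tq, lm = out$lm, fm = out$fm,
       max_rel_residual = out$max_rel_residual, n_flagged = out$n_flagged)
}

#' EMG-driven NMS torque prediction
#'
#' Full chain: envelope -> neural activation ODE -> nonlinear transfer ->
#' contraction dynamics with tendon equilibrium -> torque synthesis ->
#' 1 Hz zero-lag smoothing.
#'
#' @param sre MVC-normalized [envelope_series()] (columns RF, VL, BF, ST).
#' @param kin aligned [kinematic_series()].
#' @param geom an `mtu_geometry`.
#' @param params per-muscle parameters (see [default_nms_params()]).
#' @param smooth apply output smoothing (default TRUE).
#' @return a [torque_series()].
#' @export
predict_torque_nms <- function(sre, kin, geom = load_geometry(),
                               params = default_nms_params(), smooth = TRUE) {
  stopifnot(inherits(sre, "envelope_series"), inherits(kin, "kinematic_series"))
  if (nrow(sre$values) != length(kin$angle))
    stop("envelope and kinematics must be aligned (equal length)")
  muscles <- names(geom)
  dt_ms <- 1000 / sre$fs
  act <- sapply(muscles, function(m) {
    p <- params[[m]]
    u <- neural_activation(sre$values[, m], p$tau_act, p$tau_deact, dt_ms)
    activation_transfer(u, p$A)
  })
  nms_forward(act, kin, geom, params, smooth = smooth)$torque
}

decimate_trial <- function(trial, q) {
  if (q <= 1L) return(trial)
  idx <- seq(1L, nrow(trial$sre$values), by = q)
  fs <- trial$sre$fs / q
  list(sre = envelope_series(trial$sre$values[idx, , drop = FALSE], fs,
                             normalized = trial$sre$normalized),
       kin = kinematic_series(trial$kin$angle[idx], fs),
       torque = torque_series(trial$torque$torque[idx], fs))
}

nms_training_loss <- function(flat, trials, geom, muscles) {
  params <- flat_to_params(flat, muscles)
  y <- c(); yhat <- c()
  for (tr in trials) {
    pred <- predict_torque_nms(tr$sre, tr$kin, geom, params)
    y <- c(y, tr$torque$torque)
    yhat <- c(yhat, pred$torque)
  }
  loss_mse_over_r2(y, yhat)
}

#' Calibrate the NMS model on training trials
#'
#' Bayesian (TPE) search over the 24-dimensional discrete space of
#' [nms_search_space()], minimizing the correlation-weighted MSE
#' ([loss_mse_over_r2()]) of the smoothed torque prediction against the
#' reference over all training trials.
#'
#' @param trials list of trials, each a list with `sre` (normalized
#'   [envelope_series()]), `kin` ([kinematic_series()]) and `torque`
#'   (reference [torque_series()]), all aligned.
#' @param geom an `mtu_geometry`.
#' @param n_iter number of optimization trials (2000 at study scale).
#' @param seed RNG seed; recorded in the result.
#' @param decimation integer subsampling factor applied to the signals during
#'   calibration only (forward-model speed; 1 = none, default 2; larger
#'   factors bias the activation-dynamics integration noticeably).
#' @return a `calibration_result`: list with `params` (per-muscle), `flat`,
#'   `best_value`, `trace` (best-so-far loss), `history`, `seed`.
#' @export
calibrate_nms <- function(trials, geom = load_geometry(), n_iter = 2000,
                          seed = 1L, decimation = 2L) {
  stopifnot(length(trials) >= 1)
  rng <- range(unlist(lapply(trials, function(tr) range(tr$torque$torque))))
  if (diff(rng) <= 0) stop("degenerate torque reference (constant)")
  muscles <- names(geom)
  cal_trials <- lapply(trials, decimate_trial, q = as.integer(decimation))
  space <- nms_search_space(muscles)
  res <- tpe_optimize(space,
                      function(p) nms_training_loss(p, cal_trials, geom, muscles),
                      n_iter = n_iter, seed = seed, n_candidates = 48L)
  structure(list(params = flat_to_params(unlist(res$best_params), muscles),
                 flat = unlist(res$best_params),
                 best_value = res$best_value, trace = res$trace,
                 history = res$history, seed = seed),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> %d trials, best loss %.4g, seed %d\n",
              nrow(x$history), x$best_value, x$seed))
  invisible(x)
}

#' Serialize calibrated NMS parameters to JSON
#'
#' @param result a `calibration_result` from [calibrate_nms()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_nms_params <- function(result, path) {
  jsonlite::write_json(list(params = result$params, seed = result$seed,
                            best_value = result$best_value,
                            trace = result$trace),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
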