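# File interfaces (plain CSV dialects) and the end-to-end pipeline driver
# behind the command-line entry point (inst/cli/myotorque.R).

#' Read / write the delimited time-series dialects
#'
#' EMG: columns `time_s, RF, VL, BF, ST`; kinematics: `time_s,
#' knee_angle_deg`; torque: `time_s, torque_Nm`.  Header row mandatory,
#' UTF-8, `.` decimal separator.  Angles are degrees at the file boundary and
#' radians internally.
#'
#' @param path file path.
#' @param x object to write.
#' @return the parsed object, or (for writers) `path` invisibly.
#' @name timeseries_io
NULL

infer_fs <- function(time_s) {
  dt <- diff(time_s)
  round(1 / stats::median(dt))
}

#' @rdname timeseries_io
#' @export
read_emg_csv <- function(path) {
  d <- read.csv(path)
  stopifnot(all(c("time_s", MUSCLES) %in% names(d)))
  envelope_series(as.matrix(d[MUSCLES]), fs = infer_fs(d$time_s))
}

#' @rdname timeseries_io
#' @export
write_emg_csv <- function(x, path) {
  t <- (seq_len(nrow(x$values)) - 1L) / x$fs
  write.csv(data.frame(time_s = t, x$values), path, row.names = FALSE)
  invisible(path)
}

#' @rdname timeseries_io
#' @export
read_kinematics_csv <- function(path) {
  d <- read.csv(path)
  stopifnot(all(c("time_s", "knee_angle_deg") %in% names(d)))
  kinematic_series(d$knee_angle_deg * pi / 180, fs = infer_fs(d$time_s))
}

#' @rdname timeseries_io
#' @export
write_kinematics_csv <- function(x, path) {
  t <- (seq_len(length(x$angle)) - 1L) / x$fs
  write.csv(data.frame(time_s = t, knee_angle_deg = x$angle * 180 / pi),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname timeseries_io
#' @export
read_torque_csv <- function(path) {
  d <- read.csv(path)
  stopifnot(all(c("time_s", "torque_Nm") %in% names(d)))
  torque_series(d$torque_Nm, fs = infer_fs(d$time_s))
}

#' @rdname timeseries_io
#' @export
write_torque_csv <- function(x, path) {
  t <- (seq_len(length(x$torque)) - 1L) / x$fs
  write.csv(data.frame(time_s = t, torque_Nm = x$torque), path,
            row.names = FALSE)
  invisible(path)
}

#' Write a synthetic benchmark to a directory of CSV trials
#'
#' Creates `day<g>/trial<i>_{emg,kin,torque}.csv` plus `truth.json` with the
#' generating parameters and seed.
#'
#' @param bench a `synthetic_benchmark`.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(bench, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (d in names(bench$days)) {
    dd <- file.path(dir, paste0("day", d))
    dir.create(dd, showWarnings = FALSE)
    for (i in seq_along(bench$days[[d]])) {
      tr <- bench$days[[d]][[i]]
      write_emg_csv(tr$sre, file.path(dd, sprintf("trial%02d_emg.csv", i)))
      write_kinematics_csv(tr$kin, file.path(dd, sprintf("trial%02d_kin.csv", i)))
      write_torque_csv(tr$torque, file.path(dd, sprintf("trial%02d_torque.csv", i)))
    }
  }
  jsonlite::write_json(list(true_params = bench$true_params,
                            seed = bench$seed,
                            n_trials = bench$spec$n_trials),
                       file.path(dir, "truth.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Run the end-to-end workflow on a synthetic benchmark
#'
#' simulate -> split -> train/calibrate the selected models -> multi-day
#' evaluation, writing a per-trial NRMSE CSV and a JSON summary carrying the
#' seed and configuration for provenance.
#'
#' @param models character subset of `c("nms", "cnn", "hybrid")`.
#' @param out_dir output directory.
#' @param seed master seed.
#' @param n_trials trials per day.
#' @param days day labels.
#' @param nms_iters NMS calibration iterations.
#' @param cnn_epochs epoch cap for CNN training.
#' @param extra_cycles extension/flexion cycles per trial beyond the first.
#' @param verbose print progress.
#' @return the `evaluation_report`, invisibly.
#' @export
run_pipeline <- function(models = c("nms", "cnn", "hybrid"), out_dir = NULL,
                         seed = 1L, n_trials = 8, days = c(1, 2),
                         nms_iters = 500, cnn_epochs = 20,
                         extra_cycles = 1, verbose = TRUE) {
  models <- match.arg(models, c("nms", "cnn", "hybrid"), several.ok = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  say("generating benchmark (seed %d, %d trials/day)...", seed, n_trials)
  spec <- protocol_spec(n_trials = n_trials, extra_cycles = extra_cycles)
  bench <- generate_benchmark(spec, days = days, seed = seed)
  fit <- fit_models(bench, models = models, seed = seed,
                    nms_iters = nms_iters, cnn_epochs = cnn_epochs,
                    verbose = verbose)
  report <- evaluate_benchmark(bench, fit)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(report$per_trial, file.path(out_dir, "nrmse_per_trial.csv"),
              row.names = FALSE)
    jsonlite::write_json(list(summary = report$summary, seed = seed,
                              models = models, n_trials = n_trials,
                              days = days, nms_iters = nms_iters,
                              cnn_epochs = cnn_epochs,
                              version = as.character(utils::packageVersion("myotorque"))),
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}

#' Fit the selected models on day-1 training data of a benchmark
#'
#' Applies the fixed day-1 80/20 train/test split (and shuffled train/val
#' split within the pool), calibrates/trains each requested model, and
#' returns the fitted objects plus the split.
#'
#' @param bench a `synthetic_benchmark` (must contain day "1").
#' @param models character subset of `c("nms", "cnn", "hybrid")`.
#' @param seed RNG seed.
#' @param nms_iters calibration iterations for the NMS model.
#' @param cnn_epochs epoch cap for the CNN model.
#' @param nms_decimation signal subsampling during NMS calibration.
#' @param hybrid_schedule schedule passed to [train_hybrid()].
#' @param cnn_arch CNN backbone architecture (also used, with a 4-wide
#'   sigmoid head, for the hybrid model).
#' @param lr Adam learning rate for the CNN and hybrid stages.
#' @param verbose print progress.
#' @return list with `split` and per-model fits (`nms`, `cnn`, `hybrid`).
#' @export
fit_models <- function(bench, models = c("nms", "cnn", "hybrid"), seed = 1L,
                       nms_iters = 500, cnn_epochs = 20, nms_decimation = 2,
                       hybrid_schedule = list(nms_iters = 500, cnn_epochs = 10),
                       cnn_arch = optimized_architecture(), lr = 0.01,
                       verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  day1 <- bench$days[["1"]]
  split <- make_splits(length(day1), seed = seed)
  train_trials <- day1[split$train]
  val_trials <- day1[split$val]
  out <- list(split = split)
  if ("nms" %in% models) {
    say("calibrating NMS model (%d iterations)...", nms_iters)
    out$nms <- calibrate_nms(c(train_trials, val_trials), bench$geom,
                             n_iter = nms_iters, seed = seed,
                             decimation = nms_decimation)
  }
  if ("cnn" %in% models) {
    say("training CNN model (max %d epochs)...", cnn_epochs)
    tr_ds <- window_trials(train_trials)
    va_ds <- window_trials(val_trials)
    mdl <- build_model(cnn_arch, input_shape = dim(tr_ds$windows)[2:3],
                       seed = seed)
    out$cnn <- train_cnn(mdl, tr_ds, va_ds,
                         training_config(lr = lr, max_epochs = cnn_epochs,
                                         seed = seed))
  }
  if ("hybrid" %in% models) {
    say("training hybrid model (alternating schedule)...")
    tr_ds <- window_trials(c(train_trials, val_trials))
    h_arch <- cnn_architecture(cnn_arch$n_conv_layers, cnn_arch$n_filters,
                               cnn_arch$kernel_size, cnn_arch$lstm_units,
                               cnn_arch$batch_norm, cnn_arch$dropout_rate,
                               head_width = 4, head_activation = "sigmoid")
    out$hybrid <- train_hybrid(tr_ds, bench$geom, arch = h_arch,
                               schedule = hybrid_schedule, seed = seed,
                               cfg = training_config(lr = lr, seed = seed))
  }
  out
}

#' Concatenate trials into one windowed dataset
#'
#' Windows never cross trial boundaries.
#'
#' @param trials list of trials (`sre`, `kin`, `torque`).
#' @param window_len,stride windowing parameters (samples).
#' @return a [windowed_dataset()] with window-mean angles.
#' @export
window_trials <- function(trials, window_len = 128L, stride = 16L) {
  parts <- lapply(trials, function(tr)
    window_signals(tr$sre, tr$torque, window_len, stride, kin = tr$kin))
  win <- do.call(abind3, lapply(parts, function(p) p$windows))
  windowed_dataset(win, unlist(lapply(parts, `[[`, "targets")),
                   window_len, stride,
                   angle = unlist(lapply(parts, `[[`, "angle")),
                   fs = trials[[1]]$sre$fs)
}

abind3 <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1]])
  n <- sum(vapply(xs, function(x) dim(x)[1], 0L))
  out <- array(0, c(n, d[2], d[3]))
  at <- 0L
  for (x in xs) {
    out[(at + 1L):(at + dim(x)[1]), , ] <- x
    at <- at + dim(x)[1]
  }
  out
}

#' Evaluate fitted models over all days of a benchmark
#'
#' Day-1 evaluation uses only the held-out test trials; later days use all
#' trials.  All models are scored on the window grid (window-mean reference
#' torque) with a common per-leg normalization range.
#'
#' @param bench a `synthetic_benchmark`.
#' @param fit result of [fit_models()].
#' @return an `evaluation_report`.
#' @export
evaluate_benchmark <- function(bench, fit) {
  data_by_day <- list()
  for (d in names(bench$days)) {
    trials <- if (d == "1") bench$days[[d]][fit$split$test] else bench$days[[d]]
    data_by_day[[d]] <- lapply(trials, function(tr) {
      ds <- window_signals(tr$sre, tr$torque, kin = tr$kin)
      c(tr, list(ds = ds, torque_ref = ds$targets))
    })
  }
  fns <- list()
  if (!is.null(fit$nms))
    fns$nms <- function(tr) {
      pred <- predict_torque_nms(tr$sre, tr$kin, bench$geom, fit$nms$params)
      window_signals(tr$sre, pred, kin = tr$kin)$targets
    }
  if (!is.null(fit$cnn))
    fns$cnn <- function(tr) predict_cnn(fit$cnn$model, tr$ds)
  if (!is.null(fit$hybrid))
    fns$hybrid <- function(tr) predict_hybrid(fit$hybrid$model, tr$ds,
                                              bench$geom, fit$hybrid$hp)
  evaluate_multiday(fns, data_by_day)
}
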