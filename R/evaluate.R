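#' Correlation-weighted mean squared error
#'
#' `loss = mean((y - yhat)^2) / r^2` where `r` is the Pearson correlation of
#' reference and prediction; non-positive or undefined correlations are
#' replaced by 1e-2 before squaring, so anti-correlated predictions are
#' heavily penalized while the loss reduces to plain MSE at `r = 1`.
#'
#' @param y reference values (length >= 2).
#' @param yhat predicted values.
#' @return non-negative scalar loss.
#' @export
loss_mse_over_r2 <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) >= 2)
  r <- suppressWarnings(cor(y, yhat))
  if (!is.finite(r) || r <= 0) r <- 1e-2
  mean((y - yhat)^2) / r^2
}

#' Normalized root-mean-squared error in percent
#'
#' RMSE of the prediction divided by the reference range
#' (`y_max - y_min`, taken over all trials of one leg) times 100.
#'
#' @param y_ref reference torque values.
#' @param yhat predicted torque values.
#' @param y_max,y_min normalization range bounds (reference torque extrema
#'   over all trials of the leg).
#' @return NRMSE in percent.
#' @export
nrmse <- function(y_ref, yhat, y_max, y_min) {
  stopifnot(length(y_ref) == length(yhat))
  if (y_max <= y_min) stop("degenerate normalization range (y_max <= y_min)")
  sqrt(mean((yhat - y_ref)^2)) / (y_max - y_min) * 100
}

#' Train/validation/test partition of day-1 trials
#'
#' Day-1 trials are split 80/20 into a training pool and a held-out test set
#' by acquisition order (first 80% train pool, last 20% test); within the
#' pool a seeded shuffled 80/20 train/validation split is made.  Later-day
#' trials are entirely test data.
#'
#' @param n_trials number of day-1 trials (>= 5).
#' @param seed RNG seed for the shuffled train/validation split.
#' @return list with integer index vectors `train`, `val`, `test`.
#' @export
make_splits <- function(n_trials, seed = 1L) {
  if (n_trials < 5) stop("need at least 5 day-1 trials to split")
  n_pool <- floor(0.8 * n_trials)
  pool <- seq_len(n_pool)
  test <- setdiff(seq_len(n_trials), pool)
  set.seed(seed)
  shuffled <- sample(pool)
  n_train <- floor(0.8 * n_pool)
  list(train = sort(shuffled[seq_len(n_train)]),
       val = sort(shuffled[(n_train + 1L):n_pool]),
       test = test)
}

#' Per-trial NRMSE of a set of models over multiple days
#'
#' Applies each model's predict function to every trial of every day and
#' scores it against the reference torque with a per-leg normalization range
#' computed over the reference of all trials of all days.
#'
#' @param predict_fns named list of functions `f(trial) -> torque_series`
#'   (predictions on the trial's evaluation grid; see the model wrappers).
#' @param data_by_day named list (`"1"`, `"2"`, ...) of lists of trials; each
#'   trial must carry `torque_ref` (reference on the evaluation grid) or
#'   `torque` (a [torque_series()]).
#' @param leg leg label recorded in the report (default `"L1"`).
#' @return an `evaluation_report`: list with `per_trial` (data.frame
#'   `model,day,leg,trial,nrmse_pct`) and `summary` (mean/sd per model x day).
#' @export
evaluate_multiday <- function(predict_fns, data_by_day, leg = "L1") {
  all_ref <- unlist(lapply(data_by_day, function(day)
    lapply(day, function(tr) tr$torque$torque)))
  y_max <- max(all_ref); y_min <- min(all_ref)
  rows <- list()
  for (model in names(predict_fns)) {
    f <- predict_fns[[model]]
    for (day in names(data_by_day)) {
      trials <- data_by_day[[day]]
      for (i in seq_along(trials)) {
        tr <- trials[[i]]
        pred <- f(tr)
        ref <- if (!is.null(tr$torque_ref)) tr$torque_ref else tr$torque$torque
        yhat <- if (inherits(pred, "torque_series")) pred$torque else pred
        rows[[length(rows) + 1L]] <- data.frame(
          model = model, day = day, leg = leg, trial = i,
          nrmse_pct = nrmse(ref, yhat, y_max, y_min))
      }
    }
  }
  per_trial <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(per_trial, per_trial[c("model", "day")]),
    function(d) data.frame(model = d$model[1], day = d$day[1],
                           mean_nrmse = mean(d$nrmse_pct),
                           sd_nrmse = sd(d$nrmse_pct), n = nrow(d))))
  rownames(summ) <- NULL
  structure(list(per_trial = per_trial, summary = summ,
                 range = c(y_min, y_max)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Permutation test for a difference in mean NRMSE between two groups
#'
#' Two-sided test of the difference in means by random relabeling; a
#' self-contained descriptive alternative to mixed-model inference.
#'
#' @param x,y numeric vectors of per-trial NRMSE values.
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return list with `observed` difference (mean(x) - mean(y)) and `p_value`.
#' @export
permutation_test <- function(x, y, n_perm = 2000, seed = 1L) {
  set.seed(seed)
  obs <- mean(x) - mean(y)
  pooled <- c(x, y); nx <- length(x)
  perm <- replicate(n_perm, {
    idx <- sample(length(pooled), nx)
    mean(pooled[idx]) - mean(pooled[-idx])
  })
  list(observed = obs, p_value = mean(abs(perm) >= abs(obs)))
}
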