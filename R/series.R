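#' Time-series containers
#'
#' Lightweight S3 containers for the signals moving through the pipeline:
#' raw EMG, MVC-normalized envelopes, knee kinematics and knee torque.
#' All carry a sampling rate `fs` in Hz.
#'
#' @name series
NULL

MUSCLES <- c("RF", "VL", "BF", "ST")

#' Raw multi-channel EMG recording
#'
#' @param samples numeric matrix, one column per muscle (mV).
#' @param fs sampling rate in Hz (nominally 2000).
#' @param channels character vector of muscle labels.
#' @return an object of class `raw_emg`.
#' @export
raw_emg <- function(samples, fs = 2000, channels = MUSCLES) {
  samples <- as.matrix(samples)
  if (ncol(samples) != length(channels))
    stop("number of columns must match number of channel labels")
  if (!all(channels %in% MUSCLES) || length(channels) != 4L)
    stop("expected exactly the four channels RF, VL, BF, ST")
  if (fs <= 40) stop("sampling rate must exceed twice the 20 Hz high-pass cutoff")
  if (any(!is.finite(samples))) stop("non-finite EMG samples")
  colnames(samples) <- channels
  structure(list(samples = samples, fs = fs, channels = channels),
            class = "raw_emg")
}

#' MVC-normalized (or raw) smoothed rectified envelope
#'
#' @param values numeric matrix, one column per muscle (dimensionless once
#'   normalized by MVC).
#' @param fs sampling rate in Hz.
#' @param normalized logical, whether MVC normalization has been applied.
#' @return an object of class `envelope_series`.
#' @export
envelope_series <- function(values, fs, normalized = FALSE) {
  values <- as.matrix(values)
  if (any(!is.finite(values))) stop("non-finite envelope values")
  if (any(values < 0)) stop("envelope values must be non-negative")
  if (is.null(colnames(values))) colnames(values) <- MUSCLES[seq_len(ncol(values))]
  structure(list(values = values, fs = fs, normalized = normalized),
            class = "envelope_series")
}

#' Sagittal knee angle series
#'
#' Angle convention: radians, 0 = full extension, positive = flexion.
#'
#' @param angle numeric vector of knee flexion angles (rad).
#' @param fs sampling rate in Hz.
#' @return an object of class `kinematic_series`.
#' @export
kinematic_series <- function(angle, fs) {
  if (any(!is.finite(angle))) stop("non-finite knee angles")
  if (any(abs(angle) > pi)) stop("knee angle outside [-pi, pi]")
  structure(list(angle = as.numeric(angle), fs = fs), class = "kinematic_series")
}

#' Knee joint torque series (N·m, extension-positive)
#'
#' @param torque numeric vector (N·m).
#' @param fs sampling rate in Hz.
#' @return an object of class `torque_series`.
#' @export
torque_series <- function(torque, fs) {
  if (any(!is.finite(torque))) stop("non-finite torque values")
  structure(list(torque = as.numeric(torque), fs = fs), class = "torque_series")
}

#' @export
print.raw_emg <- function(x, ...) {
  cat(sprintf("<raw_emg> %d samples x %d channels @ %g Hz (%.2f s)\n",
              nrow(x$samples), ncol(x$samples), x$fs, nrow(x$samples) / x$fs))
  invisible(x)
}

#' @export
print.envelope_series <- function(x, ...) {
  cat(sprintf("<envelope_series%s> %d samples x %d channels @ %g Hz\n",
              if (x$normalized) ", MVC-normalized" else "",
              nrow(x$values), ncol(x$values), x$fs))
  invisible(x)
}

#' @export
print.kinematic_series <- function(x, ...) {
  cat(sprintf("<kinematic_series> %d samples @ %g Hz, angle %.1f-%.1f deg\n",
              length(x$angle), x$fs, min(x$angle) * 180 / pi,
              max(x$angle) * 180 / pi))
  invisible(x)
}

#' @export
print.torque_series <- function(x, ...) {
  cat(sprintf("<torque_series> %d samples @ %g Hz, %.1f to %.1f N.m\n",
              length(x$torque), x$fs, min(x$torque), max(x$torque)))
  invisible(x)
}

#' Windowed envelope dataset for the neural-network models
#'
#' @param windows numeric array `[n_windows, window_len, n_channels]`.
#' @param targets numeric vector of window-mean reference torques (N·m).
#' @param window_len,stride window length and hop, in samples.
#' @param angle optional vector of window-mean knee angles (rad), used by the
#'   hybrid model's geometry stage.
#' @param fs sampling rate of the underlying signals (Hz).
#' @return an object of class `windowed_dataset`.
#' @export
windowed_dataset <- function(windows, targets, window_len, stride,
                             angle = NULL, fs = 1000) {
  if (dim(windows)[1] != length(targets))
    stop("window count and target count differ")
  structure(list(windows = windows, targets = targets,
                 window_len = window_len, stride = stride,
                 angle = angle, fs = fs),
            class = "windowed_dataset")
}

#' @export
print.windowed_dataset <- function(x, ...) {
  d <- dim(x$windows)
  cat(sprintf("<windowed_dataset> %d windows of %d x %d (stride %d)\n",
              d[1], d[2], d[3], x$stride))
  invisible(x)
}

#' Number of windows in a windowed dataset
#' @param x a `windowed_dataset`.
#' @return integer window count.
#' @export
n_windows <- function(x) dim(x$windows)[1]
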