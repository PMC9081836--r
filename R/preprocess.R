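#' Smoothed rectified envelope (SRE) of raw EMG
#'
#' High-pass filters each channel at 20 Hz, full-wave rectifies, and low-pass
#' filters at 6 Hz.  All filters are zero-lag 2nd-order Butterworth
#' (forward-backward).  The output is un-normalized; see [normalize_by_mvc()].
#'
#' @param raw a [raw_emg()] object.
#' @return an [envelope_series()] at the input sampling rate.
#' @export
compute_sre <- function(raw) {
  stopifnot(inherits(raw, "raw_emg"))
  n <- nrow(raw$samples)
  if (n < min_filter_length(raw$fs))
    stop("signal shorter than 3x the 6 Hz filter settling length")
  hp <- butter_coefs(2, 20, raw$fs, "high")
  lp <- butter_coefs(2, 6, raw$fs, "low")
  env <- apply(raw$samples, 2, function(x) {
    e <- filtfilt_zl(lp$b, lp$a, abs(filtfilt_zl(hp$b, hp$a, x)))
    pmax(e, 0)
  })
  envelope_series(env, fs = raw$fs, normalized = FALSE)
}

# MVC reference per channel: peak of a 500 ms moving average of the MVC-trial
# envelope (robust to brief spikes; the plateau of a maximal effort).
mvc_reference <- function(mvc_sre) {
  w <- max(1L, as.integer(round(0.5 * mvc_sre$fs)))
  apply(mvc_sre$values, 2, function(x) {
    if (length(x) < w) return(max(x))
    ma <- stats::filter(x, rep(1 / w, w), sides = 2)
    max(ma, na.rm = TRUE)
  })
}

#' Normalize an envelope by MVC reference values
#'
#' The per-channel reference is the peak of a 500 ms moving average of the
#' MVC-trial envelope.
#'
#' @param sre an [envelope_series()] to normalize.
#' @param mvc_sre an [envelope_series()] from the MVC trial, same channels.
#' @return a normalized [envelope_series()] (values typically in \[0, ~1.2\]).
#' @export
normalize_by_mvc <- function(sre, mvc_sre) {
  stopifnot(inherits(sre, "envelope_series"), inherits(mvc_sre, "envelope_series"))
  if (ncol(sre$values) != ncol(mvc_sre$values))
    stop("channel sets differ between envelope and MVC trial")
  ref <- mvc_reference(mvc_sre)
  if (any(ref <= 0)) stop("MVC reference must be strictly positive")
  envelope_series(sweep(sre$values, 2, ref, "/"), fs = sre$fs, normalized = TRUE)
}

#' Resample an envelope and a kinematic series onto a shared 1 kHz clock
#'
#' Linear interpolation over the common time support of the two signals
#' (each assumed to start at t = 0 of its own clock unless offsets are given).
#'
#' @param emg an [envelope_series()] (e.g. at 2000 Hz).
#' @param kin a [kinematic_series()] (e.g. at 240 Hz).
#' @param fs_out target sampling rate (Hz, default 1000).
#' @param t0_emg,t0_kin start times of each recording on the shared clock (s).
#' @return list with elements `emg` and `kin`, both at `fs_out` and of equal
#'   length over the overlapping interval.
#' @export
resample_and_sync <- function(emg, kin, fs_out = 1000, t0_emg = 0, t0_kin = 0) {
  t_emg <- t0_emg + (seq_len(nrow(emg$values)) - 1L) / emg$fs
  t_kin <- t0_kin + (seq_len(length(kin$angle)) - 1L) / kin$fs
  lo <- max(t_emg[1], t_kin[1])
  hi <- min(t_emg[length(t_emg)], t_kin[length(t_kin)])
  if (hi <= lo) stop("EMG and kinematic recordings have no overlapping time support")
  tt <- seq(lo, hi, by = 1 / fs_out)
  vals <- apply(emg$values, 2, function(x) approx(t_emg, x, xout = tt)$y)
  ang <- approx(t_kin, kin$angle, xout = tt)$y
  list(emg = envelope_series(pmax(vals, 0), fs = fs_out,
                             normalized = emg$normalized),
       kin = kinematic_series(ang, fs = fs_out))
}

#' Window envelopes and reference torque for the neural-network models
#'
#' Cuts the multichannel envelope into overlapping frames and pairs each with
#' the arithmetic mean of the reference torque over the frame.  At 1 kHz the
#' defaults correspond to 128 ms windows with a 16 ms stride.
#'
#' @param sre an [envelope_series()].
#' @param torque a [torque_series()] aligned with `sre`.
#' @param window_len window length in samples (default 128).
#' @param stride hop in samples (default 16).
#' @param kin optional [kinematic_series()]; if given, window-mean angles are
#'   stored for the hybrid model.
#' @return a [windowed_dataset()].
#' @export
window_signals <- function(sre, torque, window_len = 128L, stride = 16L,
                           kin = NULL) {
  stopifnot(inherits(sre, "envelope_series"), inherits(torque, "torque_series"))
  n <- nrow(sre$values)
  if (length(torque$torque) != n)
    stop("envelope and torque must have equal length")
  if (n < window_len) stop("signal shorter than one window")
  nw <- (n - window_len) %/% stride + 1L
  starts <- (seq_len(nw) - 1L) * stride + 1L
  nc <- ncol(sre$values)
  win <- array(0, c(nw, window_len, nc))
  for (w in seq_len(nw))
    win[w, , ] <- sre$values[starts[w]:(starts[w] + window_len - 1L), ]
  tgt <- vapply(starts, function(s)
    mean(torque$torque[s:(s + window_len - 1L)]), numeric(1))
  ang <- NULL
  if (!is.null(kin))
    ang <- vapply(starts, function(s)
      mean(kin$angle[s:(s + window_len - 1L)]), numeric(1))
  windowed_dataset(win, tgt, window_len, stride, angle = ang, fs = sre$fs)
}

#' Smooth a predicted torque trace
#'
#' Zero-lag 2nd-order Butterworth low-pass at 1 Hz, applied to every model's
#' torque prediction before evaluation.
#'
#' @param torque a [torque_series()].
#' @param cutoff_hz cutoff frequency (Hz, default 1).
#' @return a smoothed [torque_series()] at the same rate.
#' @export
smooth_prediction <- function(torque, cutoff_hz = 1) {
  stopifnot(inherits(torque, "torque_series"))
  torque_series(butter_zl(torque$torque, cutoff_hz, torque$fs), torque$fs)
}
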