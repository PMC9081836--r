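# Zero-lag Butterworth filtering.
#
# "Zero-lag 2nd order" is read as forward-backward application of a 2nd-order
# Butterworth filter (effective 4th-order magnitude, zero phase), the standard
# biomechanics convention.  signal::filtfilt does no edge padding, so edges
# are handled here scipy-style: odd-reflection extension plus steady-state
# initial conditions for the direct-form-II-transposed filter.

# steady-state filter state for a unit-step input (zi scaled by x[1] on use)
iir_steady_state <- function(b, a) {
  b <- b / a[1]; a <- a / a[1]
  ns <- max(length(a), length(b)) - 1L
  bb <- c(b, rep(0, ns + 1L - length(b)))
  aa <- c(a, rep(0, ns + 1L - length(a)))
  g <- sum(bb) / sum(aa)  # DC gain
  zi <- numeric(ns)
  acc <- 0
  for (k in (ns + 1L):2L) {
    acc <- acc + bb[k] - aa[k] * g
    zi[k - 1L] <- acc
  }
  zi
}

apply_iir <- function(b, a, x, zi_template) {
  iir_df2t_cpp(b, a, x, zi_template * x[1])
}

#' Zero-lag (forward-backward) IIR filtering
#'
#' Applies the filter forward and backward so the net phase is zero; edges are
#' stabilized by odd-reflection padding and steady-state initial conditions.
#'
#' @param b,a filter numerator/denominator coefficients (e.g. from
#'   [signal::butter()]).
#' @param x numeric vector to filter.
#' @return filtered vector of the same length as `x`.
#' @export
filtfilt_zl <- function(b, a, x) {
  n <- length(x)
  npad <- 3L * max(length(a), length(b))
  if (n <= npad + 1L) stop("signal too short for stable zero-lag filtering")
  head_ext <- 2 * x[1] - x[(npad + 1L):2L]
  tail_ext <- 2 * x[n] - x[(n - 1L):(n - npad)]
  xe <- c(head_ext, x, tail_ext)
  zi <- iir_steady_state(b, a)
  y <- apply_iir(b, a, xe, zi)
  y <- rev(apply_iir(b, a, rev(y), zi))
  y[(npad + 1L):(npad + n)]
}

butter_coefs <- function(order, cutoff_hz, fs, type = "low") {
  wn <- cutoff_hz / (fs / 2)
  if (wn <= 0 || wn >= 1)
    stop("cutoff must lie strictly inside (0, fs/2)")
  bt <- signal::butter(order, wn, type = type)
  list(b = bt$b, a = bt$a)
}

#' Zero-lag Butterworth low/high-pass of a vector
#'
#' @param x numeric vector.
#' @param cutoff_hz cutoff frequency (Hz).
#' @param fs sampling rate (Hz).
#' @param order filter order applied in each direction (default 2).
#' @param type `"low"` or `"high"`.
#' @return filtered vector.
#' @export
butter_zl <- function(x, cutoff_hz, fs, order = 2, type = "low") {
  co <- butter_coefs(order, cutoff_hz, fs, type)
  filtfilt_zl(co$b, co$a, x)
}

# minimum signal length accepted by the envelope filters: three times the
# settling span of the slowest (6 Hz low-pass) filter's impulse response
min_filter_length <- function(fs, slowest_cutoff_hz = 6) {
  3L * as.integer(ceiling(fs / slowest_cutoff_hz))
}
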