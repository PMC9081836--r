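#' Muscle-tendon geometry of the knee
#'
#' Surrogate for a scaled musculoskeletal-model extraction: per muscle, MTU
#' length is a cubic polynomial of knee flexion angle and the moment arm is
#' its analytic angle-derivative (virtual-work consistency).  Knee flexion
#' angle is in radians, 0 = full extension; torque is extension-positive, so
#' extensor moment arms are positive and flexor moment arms negative.
#'
#' @param path optional path to a JSON constants table overriding the
#'   packaged defaults (same schema as
#'   `system.file("extdata/geometry_default.json", package = "myotorque")`).
#' @return an object of class `mtu_geometry`: a named list per muscle with
#'   elements `fmax0`, `lopt0`, `lslack`, `penn0`, `sign`, `lmt_poly`.
#' @export
load_geometry <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "geometry_default.json", package = "myotorque")
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  g <- lapply(cfg$muscles, function(m)
    list(fmax0 = m$fmax0_N, lopt0 = m$lopt0_m, lslack = m$lslack_m,
         penn0 = m$penn0_rad, sign = m$sign, lmt_poly = as.numeric(m$lmt_poly)))
  structure(g, class = "mtu_geometry", version = cfg$version)
}

THETA_RANGE <- c(-0.2, 2.2)  # admissible knee flexion range (rad)

check_theta <- function(theta) {
  if (any(theta < THETA_RANGE[1] - 1e-12 | theta > THETA_RANGE[2] + 1e-12))
    stop("knee angle outside the modelled range [-0.2, 2.2] rad")
}

poly_eval <- function(coefs, x) {
  # Horner, coefs = a0..a3
  y <- rep(coefs[length(coefs)], length(x))
  for (k in (length(coefs) - 1L):1L) y <- y * x + coefs[k]
  y
}

poly_deriv_eval <- function(coefs, x) {
  d <- coefs[-1] * seq_len(length(coefs) - 1L)
  poly_eval(d, x)
}

#' MTU length at a knee angle
#'
#' @param theta knee flexion angle(s), rad.
#' @param muscle one of `"RF"`, `"VL"`, `"BF"`, `"ST"`.
#' @param geom an `mtu_geometry` (default: packaged table).
#' @return MTU length(s) in metres.
#' @export
mtu_length <- function(theta, muscle, geom = load_geometry()) {
  check_theta(theta)
  poly_eval(geom[[muscle]]$lmt_poly, theta)
}

#' Signed knee moment arm at a knee angle
#'
#' Equal to the analytic angle-derivative of MTU length, so that
#' `torque = sum_j F_j * moment_arm_j` is extension-positive: positive for
#' the extensors (RF, VL, whose MTU lengthens with flexion) and negative for
#' the flexors (BF, ST).
#'
#' @inheritParams mtu_length
#' @return signed moment arm(s) in metres.
#' @export
moment_arm <- function(theta, muscle, geom = load_geometry()) {
  check_theta(theta)
  poly_deriv_eval(geom[[muscle]]$lmt_poly, theta)
}

#' @export
print.mtu_geometry <- function(x, ...) {
  cat(sprintf("<mtu_geometry v%s> muscles: %s\n",
              attr(x, "version"), paste(names(x), collapse = ", ")))
  invisible(x)
}
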