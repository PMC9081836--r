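# Hill-type muscle curves, Thelen-style parameterization.  These R versions
# are the readable reference; the forward simulation in src/ implements the
# same formulas and a test holds the two in agreement.

HILL <- list(
  gamma_fl = 0.45,    # active force-length shape
  lambda_a = 0.15,    # activation-dependent shift of the optimal length
  kpe      = 4,       # passive exponential shape factor
  eps0m    = 0.6,     # passive muscle strain at normalized force 1
  vmax     = 10,      # maximal shortening velocity (l_opt/s)
  af       = 0.25,    # force-velocity curvature
  flen     = 1.4,     # eccentric force plateau
  eps_toe  = 0.01516, # tendon toe-region strain limit
  f_toe    = 0.33,    # normalized tendon force at the toe limit
  eps_t0   = 0.04,    # tendon strain at normalized force 1
  k_toe    = 3,
  dm       = 0.1      # fiber damping (velocity normalized by vmax)
)

#' Nonlinear EMG-to-activation transfer
#'
#' `a = (exp(A u) - 1) / (exp(A) - 1)` with shape factor `A < 0`; maps
#' neural activation u in \[0,1\] to muscle activation a in \[0,1\] with
#' endpoints preserved, approaching the identity as `A -> 0`.
#'
#' @param u neural activation in \[0,1\].
#' @param A shape factor in \[-3, -0.01\].
#' @return muscle activation in \[0,1\].
#' @export
activation_transfer <- function(u, A) {
  stopifnot(A < 0)
  (exp(A * u) - 1) / (exp(A) - 1)
}

#' Neural activation dynamics
#'
#' First-order ODE `du/dt = (emg - u)/tau(u, emg)` where the time constant
#' switches between activation (`emg > u`) and deactivation, both scaled by
#' the activation level: `tau_act (0.5 + 1.5 u)` vs `tau_deact/(0.5 + 1.5 u)`.
#' Integrated by exponential Euler; output clamped to \[0,1\].
#'
#' @param emg numeric vector, envelope of one muscle in \[0, ~1.5\].
#' @param tau_act,tau_deact activation/deactivation time constants (ms).
#' @param dt_ms integration step (ms; must match the envelope rate).
#' @param u0 initial condition.
#' @return numeric vector `u` of the same length.
#' @export
neural_activation <- function(emg, tau_act, tau_deact, dt_ms = 1, u0 = 0) {
  if (any(!is.finite(emg))) stop("non-finite envelope input")
  stopifnot(tau_act > 0, tau_deact > 0, dt_ms > 0)
  activation_ode_cpp(emg, tau_act, tau_deact, dt_ms, u0)
}

#' Active force-length curve
#'
#' Gaussian about an activation-adjusted optimum:
#' `f_a = exp(-(l_m - l_opt(a))^2 / gamma)` with
#' `l_opt(a) = lambda (1 - a) + 1` (the optimum shifts to longer lengths at
#' low activation).
#'
#' @param lm normalized fiber length.
#' @param a muscle activation in \[0,1\].
#' @return dimensionless force scaling, peak 1.
#' @export
active_force_length <- function(lm, a) {
  lopt_a <- HILL$lambda_a * (1 - a) + 1
  exp(-(lm - lopt_a)^2 / HILL$gamma_fl)
}

#' Passive force-length curve
#'
#' Exponential toe: `f_p = (exp(kpe (l_m - 1)/eps0m) - 1)/(exp(kpe) - 1)`,
#' clamped to 0 below the optimal length; reaches 1 at 60% fiber strain.
#'
#' @param lm normalized fiber length.
#' @return dimensionless passive force.
#' @export
passive_force_length <- function(lm) {
  out <- (exp(HILL$kpe * (lm - 1) / HILL$eps0m) - 1) / (exp(HILL$kpe) - 1)
  pmax(out, 0)
}

#' Force-velocity curve
#'
#' Hyperbolic concentric limb reaching 0 at `-vmax` shortening, 1 at
#' isometric, with an eccentric plateau at 1.4.
#'
#' @param v normalized fiber velocity (l_opt/s; negative = shortening).
#' @return dimensionless force scaling.
#' @export
force_velocity <- function(v) {
  vmax <- HILL$vmax; af <- HILL$af; flen <- HILL$flen
  conc <- ifelse(v <= -vmax, 0, (vmax + v) / (vmax - v / af))
  cc <- vmax * (flen - 1)
  ecc <- (flen * v * (2 + 2 / af) + cc) / (v * (2 + 2 / af) + cc)
  ifelse(v <= 0, conc, ecc)
}

#' Normalized tendon force-strain curve
#'
#' Exponential toe region up to strain 0.01516, then linear, normalized so
#' the force equals 1 at 4% strain; zero for slack (non-positive strain).
#'
#' @param eps tendon strain `(l_t - l_slack)/l_slack`.
#' @return normalized tendon force (multiples of maximal isometric force).
#' @export
tendon_force_norm <- function(eps) {
  k_lin <- (1 - HILL$f_toe) / (HILL$eps_t0 - HILL$eps_toe)
  toe <- HILL$f_toe / (exp(HILL$k_toe) - 1) *
    (exp(HILL$k_toe * eps / HILL$eps_toe) - 1)
  out <- ifelse(eps < HILL$eps_toe, toe, HILL$f_toe + k_lin * (eps - HILL$eps_toe))
  ifelse(eps <= 0, 0, out)
}

#' Tendon force from MTU and fiber geometry
#'
#' Tendon length is `l_t = l_mt - l_m_abs cos(alpha)`; strain follows from the
#' slack length and the force from the normalized tendon curve scaled by
#' `fmax`.
#'
#' @param lmt MTU length (m).
#' @param lm_abs absolute fiber length (m).
#' @param alpha pennation angle (rad).
#' @param lslack tendon slack length (m).
#' @param fmax maximal isometric force (N) used to scale the curve.
#' @return tendon force (N, non-negative).
#' @export
tendon_force <- function(lmt, lm_abs, alpha, lslack, fmax = 1) {
  lt <- lmt - lm_abs * cos(alpha)
  eps <- (lt - lslack) / lslack
  fmax * tendon_force_norm(eps)
}

# constant-thickness pennation: sin(alpha(lm)) = sin(alpha0)/lm, clamp at 84 deg
pennation_cos <- function(lm, penn0) {
  s <- pmin(pmax(sin(penn0) / lm, 0), sin(84 * pi / 180))
  sqrt(1 - s^2)
}

#' Solve the tendon-fiber equilibrium for normalized fiber length
#'
#' Finds `l_m` in \[0.3, 1.8\] with `|F_t - F_m| -> 0` where the fiber force
#' includes active, passive and damping terms.  If the residual changes sign
#' in the bounds a bisection root is returned; otherwise the boundary with the
#' smaller residual is returned and flagged.
#'
#' @param lmt MTU length (m).
#' @param a muscle activation in \[0,1\].
#' @param params list with `fmax` (N, already strength-scaled), `lopt` (m,
#'   already scaled), `lslack` (m, already scaled), `penn0` (rad), `dm`.
#' @param v normalized fiber velocity (l_opt/s, default 0: static).
#' @param lm_init warm-start guess (previous sample's solution).
#' @return list with `lm`, `residual` (N), `fm` (N), `flagged`.
#' @export
solve_fiber_length <- function(lmt, a, params, v = 0, lm_init = 1) {
  solve_fiber_cpp(lmt, a, v, params$fmax, params$lopt, params$lslack,
                  params$penn0, params$dm, lm_init)
}
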