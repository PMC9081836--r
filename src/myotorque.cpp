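#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// IIR filtering (direct form II transposed) with caller-supplied initial
// state, used by the R-level zero-lag filtfilt wrapper.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector iir_df2t_cpp(NumericVector b, NumericVector a, NumericVector x,
                           NumericVector zi) {
  int n = x.size();
  int nb = b.size(), na = a.size();
  int ns = std::max(nb, na) - 1;
  std::vector<double> bb(ns + 1, 0.0), aa(ns + 1, 0.0), z(ns + 1, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i] / a[0];
  for (int i = 0; i < na; ++i) aa[i] = a[i] / a[0];
  for (int i = 0; i < ns && i < zi.size(); ++i) z[i] = zi[i];
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = bb[0] * xi + z[0];
    for (int k = 0; k < ns; ++k)
      z[k] = bb[k + 1] * xi - aa[k + 1] * yi + (k + 1 < ns ? z[k + 1] : 0.0);
    y[i] = yi;
  }
  return y;
}

// ---------------------------------------------------------------------------
// Activation dynamics: first-order ODE with activation-dependent time
// constant, integrated by exponential Euler.  Time constants in ms, dt in ms.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector activation_ode_cpp(NumericVector emg, double tau_act,
                                 double tau_deact, double dt, double u0) {
  int n = emg.size();
  NumericVector u(n);
  double uc = u0;
  for (int i = 0; i < n; ++i) {
    double e = emg[i];
    double tau = (e > uc) ? tau_act * (0.5 + 1.5 * uc)
                          : tau_deact / (0.5 + 1.5 * uc);
    uc = e + (uc - e) * std::exp(-dt / tau);
    if (uc < 0.0) uc = 0.0;
    if (uc > 1.0) uc = 1.0;
    u[i] = uc;
  }
  return u;
}

// ---------------------------------------------------------------------------
// Hill-type curve primitives (must mirror the R reference implementations in
// R/hill.R; a test asserts the forward solver satisfies the R-side curves).
// ---------------------------------------------------------------------------

static const double GAMMA_FL = 0.45;   // active force-length shape
static const double LAMBDA_A = 0.15;   // activation shift of the optimum
static const double KPE      = 4.0;    // passive exponential shape
static const double EPS0M    = 0.6;    // passive strain at normalized force 1
static const double VMAX     = 10.0;   // max shortening velocity (l_opt/s)
static const double AF       = 0.25;   // force-velocity curvature
static const double FLEN     = 1.4;    // eccentric plateau
static const double EPS_TOE  = 0.01516; // tendon toe strain
static const double FTOE     = 0.33;   // normalized tendon force at toe
static const double EPS_T0   = 0.04;   // tendon strain at normalized force 1
static const double KTOE     = 3.0;
static const double SIN84    = 0.99452189536827333692;

static inline double fl_active(double lm, double a) {
  double lopt_a = LAMBDA_A * (1.0 - a) + 1.0;
  double d = lm - lopt_a;
  return std::exp(-d * d / GAMMA_FL);
}

static inline double fl_passive(double lm) {
  if (lm <= 1.0) return 0.0;
  return (std::exp(KPE * (lm - 1.0) / EPS0M) - 1.0) / (std::exp(KPE) - 1.0);
}

static inline double fv_curve(double v) {
  // v: normalized fiber velocity in l_opt/s (negative = shortening)
  if (v <= -VMAX) return 0.0;
  if (v <= 0.0) return (VMAX + v) / (VMAX - v / AF);
  double c = VMAX * (FLEN - 1.0);
  double num = FLEN * v * (2.0 + 2.0 / AF) + c;
  double den = v * (2.0 + 2.0 / AF) + c;
  return num / den;
}

static inline double ft_curve(double eps) {
  if (eps <= 0.0) return 0.0;
  if (eps < EPS_TOE)
    return FTOE / (std::exp(KTOE) - 1.0) * (std::exp(KTOE * eps / EPS_TOE) - 1.0);
  double klin = (1.0 - FTOE) / (EPS_T0 - EPS_TOE);
  return FTOE + klin * (eps - EPS_TOE);
}

// constant-thickness pennation: sin(alpha) = sin(alpha0)/lm, clamped at 84 deg
static inline double cos_penn(double lm, double sin_a0) {
  double s = sin_a0 / lm;
  if (s > SIN84) s = SIN84;
  if (s < 0.0) s = 0.0;
  return std::sqrt(1.0 - s * s);
}

// [[Rcpp::export]]
NumericVector hill_curves_cpp(double lm, double a, double v, double eps) {
  return NumericVector::create(fl_active(lm, a), fl_passive(lm),
                               fv_curve(v), ft_curve(eps));
}

// ---------------------------------------------------------------------------
// Tendon-fiber equilibrium: root of g(lm) = Ft(lm) - Fm(lm) in lm in
// [0.3, 1.8] (normalized by the scaled optimal fiber length).
// ---------------------------------------------------------------------------

struct MusclePar {
  double fmax;    // c_str * F_max0
  double lopt;    // c_opt0 * l_opt0 (m)
  double lslack;  // c_slack * l_slack (m)
  double sin_a0;  // sin of pennation at optimum
  double dm;      // damping coefficient
};

static inline double equil_res(double lm, double a, double v, double lmt,
                               const MusclePar& p) {
  double ca = cos_penn(lm, p.sin_a0);
  double lt = lmt - lm * p.lopt * ca;
  double eps = (lt - p.lslack) / p.lslack;
  double ft = p.fmax * ft_curve(eps);
  double fm = p.fmax * (a * fv_curve(v) * fl_active(lm, a) + fl_passive(lm) +
                        p.dm * v / VMAX) * ca;
  return ft - fm;
}

static const double LM_LO = 0.3, LM_HI = 1.8;

// bisection on a bracket known to change sign
static double bisect(double lo, double hi, double glo, double a, double v,
                     double lmt, const MusclePar& p) {
  // 1e-7 on lm keeps the force residual orders below the 1e-3*Fmax contract
  for (int it = 0; it < 60; ++it) {
    double mid = 0.5 * (lo + hi);
    double gm = equil_res(mid, a, v, lmt, p);
    if ((gm > 0.0) == (glo > 0.0)) { lo = mid; glo = gm; } else { hi = mid; }
    if (hi - lo < 1e-7) break;
  }
  return 0.5 * (lo + hi);
}

// [[Rcpp::export]]
List solve_fiber_cpp(double lmt, double a, double v, double fmax, double lopt,
                     double lslack, double penn0, double dm, double lm_init) {
  MusclePar p{fmax, lopt, lslack, std::sin(penn0), dm};
  double glo = equil_res(LM_LO, a, v, lmt, p);
  double ghi = equil_res(LM_HI, a, v, lmt, p);
  bool flagged = false;
  double lm;
  if ((glo > 0.0) != (ghi > 0.0)) {
    // warm bracket around the initial guess when it already straddles the root
    double wlo = std::max(LM_LO, lm_init - 0.08);
    double whi = std::min(LM_HI, lm_init + 0.08);
    double gwlo = equil_res(wlo, a, v, lmt, p);
    double gwhi = equil_res(whi, a, v, lmt, p);
    if ((gwlo > 0.0) != (gwhi > 0.0))
      lm = bisect(wlo, whi, gwlo, a, v, lmt, p);
    else
      lm = bisect(LM_LO, LM_HI, glo, a, v, lmt, p);
  } else {
    lm = (std::fabs(glo) < std::fabs(ghi)) ? LM_LO : LM_HI;
    flagged = true;
  }
  double res = equil_res(lm, a, v, lmt, p);
  double ca = cos_penn(lm, p.sin_a0);
  double fm = p.fmax * (a * fv_curve(v) * fl_active(lm, a) + fl_passive(lm) +
                        p.dm * v / VMAX) * ca;
  return List::create(_["lm"] = lm, _["residual"] = res, _["fm"] = fm,
                      _["flagged"] = flagged);
}

// ---------------------------------------------------------------------------
// Full forward contraction run over a trial: per-sample equilibrium solve for
// each muscle with lagged, low-pass-filtered fiber velocity, then torque
// synthesis  tau = sum_j Fm_j * r_j  (r signed, extension-positive).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List nms_forward_cpp(NumericMatrix act,   // N x M muscle activation a(t)
                     NumericMatrix lmt,   // N x M MTU length (m)
                     NumericMatrix rarm,  // N x M signed moment arm (m)
                     NumericVector fmax, NumericVector lopt,
                     NumericVector lslack, NumericVector penn0,
                     NumericVector dm, double dt_s) {
  int n = act.nrow(), m = act.ncol();
  NumericVector torque(n);
  NumericMatrix lm_out(n, m), fm_out(n, m);
  double max_rel_res = 0.0;
  int n_flagged = 0;
  // velocity smoothing: one-pole low pass at 6 Hz on the backward difference
  double alpha = dt_s / (dt_s + 1.0 / (2.0 * M_PI * 6.0));
  for (int j = 0; j < m; ++j) {
    MusclePar p{fmax[j], lopt[j], lslack[j], std::sin(penn0[j]), dm[j]};
    double lm_prev = 1.0, v_f = 0.0;
    for (int i = 0; i < n; ++i) {
      double a = act(i, j);
      double v = v_f;  // lagged filtered velocity estimate (l_opt/s)
      double lmt_i = lmt(i, j);
      double glo = equil_res(LM_LO, a, v, lmt_i, p);
      double ghi = equil_res(LM_HI, a, v, lmt_i, p);
      double lm;
      if ((glo > 0.0) != (ghi > 0.0)) {
        double wlo = std::max(LM_LO, lm_prev - 0.05);
        double whi = std::min(LM_HI, lm_prev + 0.05);
        double gwlo = equil_res(wlo, a, v, lmt_i, p);
        double gwhi = equil_res(whi, a, v, lmt_i, p);
        if ((gwlo > 0.0) != (gwhi > 0.0))
          lm = bisect(wlo, whi, gwlo, a, v, lmt_i, p);
        else
          lm = bisect(LM_LO, LM_HI, glo, a, v, lmt_i, p);
      } else {
        lm = (std::fabs(glo) < std::fabs(ghi)) ? LM_LO : LM_HI;
        ++n_flagged;
      }
      double res = std::fabs(equil_res(lm, a, v, lmt_i, p)) / p.fmax;
      if (res > max_rel_res) max_rel_res = res;
      double ca = cos_penn(lm, p.sin_a0);
      double fm = p.fmax * (a * fv_curve(v) * fl_active(lm, a) +
                            fl_passive(lm) + p.dm * v / VMAX) * ca;
      lm_out(i, j) = lm;
      fm_out(i, j) = fm;
      torque[i] += fm * rarm(i, j);
      if (i > 0) {
        double v_raw = (lm - lm_prev) / dt_s;
        v_f += alpha * (v_raw - v_f);
      }
      lm_prev = lm;
    }
  }
  return List::create(_["torque"] = torque, _["lm"] = lm_out,
                      _["fm"] = fm_out, _["max_rel_residual"] = max_rel_res,
                      _["n_flagged"] = n_flagged);
}
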