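// Per-sample tendon-muscle equilibrium along a sampled trajectory.
//
// For each sample the tendon force F_t(xi) must balance the fascicle force
// F_mt projected on the tendon line of action.  Given the musculotendon
// length l_mt and activation a, the single unknown is the tendon length l_t:
// the fascicle geometry follows from the constant-thickness pennation
// assumption (l_m sin(phi) = l_m0 sin(phi0)), which gives the closed form
//   w   = l_mt - l_t            (projection of the fascicle on the tendon)
//   l_m = sqrt(w^2 + h^2),  h = l_m0 sin(phi0)
// so the residual g(l_t) = F_t - F_mt is a scalar root problem, bracketed
// by construction (g <= 0 at the slack end, g >= 0 at l_t = l_mt where the
// fascicle projection vanishes) and solved by bisection.  Fascicle velocity
// uses the backward difference against the previous solved sample, so the
// solve is sequential; this loop is the hot path of model calibration.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Pars {
  double ltsk, Fmax, lmo0, phi0, lambda, vmax;
  double fl_width, fv_shape, fv_ecc_max, fp_exp, fp_width;
  double tendon_scale;
};

inline double f_length(double lt, const Pars& p) {
  const double d = lt - 1.0;
  return std::exp(-d * d / p.fl_width);
}

inline double f_velocity(double vt, const Pars& p) {
  if (vt <= -1.0) return 0.0;
  if (vt <= 0.0) return (1.0 + vt) / (1.0 - vt / p.fv_shape);
  // eccentric branch: exponential rise to the plateau, slope-matched at 0
  const double kecc = (p.fv_ecc_max - 1.0) * p.fv_shape / (p.fv_shape + 1.0);
  return p.fv_ecc_max - (p.fv_ecc_max - 1.0) * std::exp(-vt / kecc);
}

inline double f_passive(double lt, const Pars& p) {
  if (lt <= 1.0) return 0.0;
  return (std::exp(p.fp_exp * (lt - 1.0) / p.fp_width) - 1.0) /
         (std::exp(p.fp_exp) - 1.0);
}

inline double tendon_force(double xi, const Pars& p) {
  double f;
  if (xi <= 0.0) f = 0.0;
  else if (xi < 0.0127) f = 1480.3 * p.Fmax * xi * xi;
  else f = (37.5 * xi - 0.2375) * p.Fmax;
  return p.tendon_scale * f;
}

struct MuscleEval {
  double lm, phi, vm, Fmt;
};

inline MuscleEval muscle_at(double lt, double lmt, double a, double lm_prev,
                            bool have_prev, double dt, const Pars& p) {
  MuscleEval e;
  const double lm0 = p.lmo0 * (p.lambda * (1.0 - a) + 1.0);
  const double h = lm0 * std::sin(p.phi0);
  double w = lmt - lt;
  if (w < 0.0) w = 0.0;
  e.lm = std::sqrt(w * w + h * h);
  e.phi = std::atan2(h, w);
  e.vm = have_prev ? (e.lm - lm_prev) / dt : 0.0;
  const double cphi = (e.lm > 0.0) ? w / e.lm : 0.0;
  e.Fmt = p.Fmax *
          (f_length(e.lm / lm0, p) * f_velocity(e.vm / p.vmax, p) * a +
           f_passive(e.lm / lm0, p)) *
          cphi;
  return e;
}

} // namespace

// [[Rcpp::export(name = ".muscle_forward_cpp")]]
NumericMatrix muscle_forward_cpp(NumericVector lmt, NumericVector a,
                                 double dt, NumericVector pars) {
  const int n = lmt.size();
  if (a.size() != n) stop("lmt and a must have equal length");
  Pars p;
  p.ltsk = pars["ltsk"];
  p.Fmax = pars["Fmax"];
  p.lmo0 = pars["lmo0"];
  p.phi0 = pars["phi0"];
  p.lambda = pars["lambda"];
  p.vmax = pars["vmax"];
  p.fl_width = pars["fl_width"];
  p.fv_shape = pars["fv_shape"];
  p.fv_ecc_max = pars["fv_ecc_max"];
  p.fp_exp = pars["fp_exp"];
  p.fp_width = pars["fp_width"];
  p.tendon_scale = pars["tendon_scale"];

  NumericMatrix out(n, 7);
  colnames(out) = CharacterVector::create("l_t", "xi", "l_m", "phi", "v_m",
                                          "F_mt", "resid");
  double lm_prev = 0.0;
  bool have_prev = false;
  const double ftol = 1e-9 * p.Fmax;

  for (int k = 0; k < n; ++k) {
    const double L = lmt[k];
    const double ak = a[k];
    double lt;
    MuscleEval e;

    // slack candidate: tendon exactly at (or below) slack length
    const double lt_slack = std::min(p.ltsk, L);
    e = muscle_at(lt_slack, L, ak, lm_prev, have_prev, dt, p);
    if (e.Fmt <= ftol) {
      lt = lt_slack; // both sides effectively zero
    } else {
      double lo = std::min(0.9 * p.ltsk, L);
      double hi = L;
      for (int it = 0; it < 100; ++it) {
        const double mid = 0.5 * (lo + hi);
        const MuscleEval em = muscle_at(mid, L, ak, lm_prev, have_prev, dt, p);
        const double xi = (mid - p.ltsk) / p.ltsk;
        const double g = tendon_force(xi, p) - em.Fmt;
        if (g > 0.0) hi = mid; else lo = mid;
        if (hi - lo < 1e-14) break;
      }
      lt = 0.5 * (lo + hi);
      e = muscle_at(lt, L, ak, lm_prev, have_prev, dt, p);
    }

    const double xi = (lt - p.ltsk) / p.ltsk;
    out(k, 0) = lt;
    out(k, 1) = xi;
    out(k, 2) = e.lm;
    out(k, 3) = e.phi;
    out(k, 4) = e.vm;
    out(k, 5) = e.Fmt;
    out(k, 6) = tendon_force(xi, p) - e.Fmt;
    lm_prev = e.lm;
    have_prev = true;
  }
  return out;
}
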