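#include <Rcpp.h>
using namespace Rcpp;

// Right-hand side of the coupled SWA / Process S system.
// Time unit is one scoring epoch (ts = 4 s); all rates are per ts.
// The build-up term rc*swa*(s/sU)*(1 - swa/s) is expanded to
// rc*swa*(s - swa)/sU, which avoids the division by s and is
// identical for s != 0.
static inline void rhs(double swa, double s, double wt, double remt,
                       double rc, double fcR, double fcW, double swaL,
                       double gc, double rs, double sU,
                       double &dswa, double &ds) {
  double build = rc * swa * (s - swa) / sU * (1.0 - wt) * (1.0 - remt);
  dswa = build - fcR * (swa - swaL) * remt - fcW * (swa - swaL) * wt;
  ds = -gc * swa + (sU - s) * rs;
}

// Fixed-step classical RK4 over one recording. Triggers are held
// piecewise constant within each epoch, so the vector field is smooth
// on every substep and RK4 at dt = 1/substeps ts is ample. The per-ts
// output is the trapezoid average of the dense solution over the
// epoch, matching the convention of averaging all solver points that
// fall within one 4-s epoch.
// [[Rcpp::export(name = ".simulate_core")]]
List simulate_core(IntegerVector wt, IntegerVector remt,
                   double rc, double fcR, double fcW, double swaL,
                   double gc, double rs, double sU,
                   double swa0, double s0, int substeps) {
  const int n = wt.size();
  if (remt.size() != n) stop("wt and remt must have equal length");
  if (substeps < 1) stop("substeps must be >= 1");
  NumericVector swa_out(n), s_out(n), swa_end(n), s_end(n);
  const double dt = 1.0 / substeps;
  double swa = swa0, s = s0;
  double k1s, k1S, k2s, k2S, k3s, k3S, k4s, k4S;
  for (int i = 0; i < n; ++i) {
    const double w = wt[i], r = remt[i];
    double acc_swa = 0.5 * swa, acc_s = 0.5 * s;
    for (int j = 0; j < substeps; ++j) {
      rhs(swa, s, w, r, rc, fcR, fcW, swaL, gc, rs, sU, k1s, k1S);
      rhs(swa + 0.5 * dt * k1s, s + 0.5 * dt * k1S, w, r,
          rc, fcR, fcW, swaL, gc, rs, sU, k2s, k2S);
      rhs(swa + 0.5 * dt * k2s, s + 0.5 * dt * k2S, w, r,
          rc, fcR, fcW, swaL, gc, rs, sU, k3s, k3S);
      rhs(swa + dt * k3s, s + dt * k3S, w, r,
          rc, fcR, fcW, swaL, gc, rs, sU, k4s, k4S);
      swa += dt / 6.0 * (k1s + 2.0 * k2s + 2.0 * k3s + k4s);
      s += dt / 6.0 * (k1S + 2.0 * k2S + 2.0 * k3S + k4S);
      const double wgt = (j == substeps - 1) ? 0.5 : 1.0;
      acc_swa += wgt * swa;
      acc_s += wgt * s;
    }
    if (!std::isfinite(swa) || !std::isfinite(s))
      stop("non-finite model state at epoch %d", i + 1);
    swa_out[i] = acc_swa * dt;
    s_out[i] = acc_s * dt;
    swa_end[i] = swa;
    s_end[i] = s;
  }
  return List::create(_["swa_sim"] = swa_out, _["s_sim"] = s_out,
                      _["swa_end"] = swa_end, _["s_end"] = s_end,
                      _["n_steps"] = n * substeps);
}
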