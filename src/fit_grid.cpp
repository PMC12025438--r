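#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Grid evaluation of the pooled PFS/OS mean-squared error of the cohort
// projection u(t) = u(t-1)(1 - p(t) - gamma), v(t) = v(t-1)(1 - delta) +
// u(t-1) p(t), p(t) = min(alpha (1+beta)^(t-1), 1 - gamma).  PFS = u,
// OS = u + v.  Returns the minimizer; ties broken by smallest |beta|, then
// alpha, gamma, delta.  Points with alpha + gamma > 1 at t = 1 are skipped
// as infeasible; clamping later in the horizon is allowed and flagged.
// [[Rcpp::export]]
List fit_grid_cpp(NumericVector av, NumericVector bv, NumericVector gv,
                  NumericVector dv, NumericVector pfs, NumericVector os,
                  double w1, double w2) {
  const int T = pfs.size();
  const int nA = av.size(), nB = bv.size(), nG = gv.size(), nD = dv.size();
  double best_mse = R_PosInf;
  double ba = NA_REAL, bb = NA_REAL, bg = NA_REAL, bd = NA_REAL;
  bool best_clamped = false;
  long n_eval = 0;

  std::vector<double> qpow(T), u(T), inflow(T);

  for (int ib = 0; ib < nB; ++ib) {
    const double b = bv[ib];
    qpow[0] = 1.0;
    for (int t = 1; t < T; ++t) qpow[t] = qpow[t - 1] * (1.0 + b);
    for (int ia = 0; ia < nA; ++ia) {
      const double a = av[ia];
      for (int ig = 0; ig < nG; ++ig) {
        const double g = gv[ig];
        if (a + g > 1.0 + 1e-12) continue;  // infeasible at t = 1
        const double cap = 1.0 - g;
        bool clamped = false;
        double up = 1.0, sse_pfs = 0.0;
        for (int t = 0; t < T; ++t) {
          double p = a * qpow[t];
          if (p > cap) { p = cap; clamped = true; }
          inflow[t] = up * p;
          up = up * (1.0 - p - g);
          u[t] = up;
          const double dp = up - pfs[t];
          sse_pfs += dp * dp;
        }
        const double base = w1 * sse_pfs / T;
        for (int id = 0; id < nD; ++id) {
          const double d = dv[id];
          double v = 0.0, sse_os = 0.0;
          const double keep = 1.0 - d;
          for (int t = 0; t < T; ++t) {
            v = v * keep + inflow[t];
            const double e = u[t] + v - os[t];
            sse_os += e * e;
          }
          const double mse = base + w2 * sse_os / T;
          ++n_eval;
          bool better = mse < best_mse;
          if (!better && mse == best_mse) {
            // deterministic tie-break: |beta|, alpha, gamma, delta
            if (std::abs(b) < std::abs(bb)) better = true;
            else if (std::abs(b) == std::abs(bb)) {
              if (a < ba) better = true;
              else if (a == ba) {
                if (g < bg) better = true;
                else if (g == bg && d < bd) better = true;
              }
            }
          }
          if (better) {
            best_mse = mse; ba = a; bb = b; bg = g; bd = d;
            best_clamped = clamped;
          }
        }
      }
    }
  }
  return List::create(
    _["alpha"] = ba, _["beta"] = bb, _["gamma"] = bg, _["delta"] = bd,
    _["mse"] = best_mse, _["clamped"] = best_clamped,
    _["n_evaluated"] = (double)n_eval);
}
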