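#include <Rcpp.h>
using namespace Rcpp;

// State codes (1-based from R): 1 nmCSPC, 2 mCSPC_low, 3 mCSPC_high,
// 4 nmCRPC, 5 mCRPC_L1, 6 mCRPC_L2, 7 progressed_mCRPC; death is implicit.
//
// Monthly cycle: the patient occupies one state for the whole month and
// accrues that month's (discounted) life-years, utility and cost; the
// competing progression / pre-progression death draw happens at month end
// (no half-cycle correction).  One uniform draw resolves the competing
// events: [0, p) progression, [p, p + gamma) death, rest stay.  Progression
// from nmCSPC consumes one extra uniform for the nmCRPC branch and, if not
// taken, one more for the low/high-risk mCSPC split.  Each time a
// suspension phase starts, one beta variate is drawn for its length.
// Patients are simulated sequentially from R's RNG stream, so a fixed seed
// gives a bit-identical cohort.
// [[Rcpp::export]]
List simulate_cohort_cpp(int n, int horizon, int start,
                         NumericVector alpha, NumericVector beta,
                         NumericVector gamma_, double delta_prog,
                         bool has_l2, double p_low, double p_nmcrpc,
                         NumericVector cost_on, NumericVector cost_off,
                         double cost_susp,
                         NumericVector util_on, NumericVector util_off,
                         NumericVector util_susp,
                         IntegerVector chemo_cycles,
                         LogicalVector intermittent,
                         double susp_a, double susp_b, double susp_scale,
                         int active_len,
                         double eol_monthly, int eol_max_months,
                         NumericVector disc, bool keep_paths) {
  NumericVector qaly(n), ly(n), cost(n);
  IntegerVector death_month(n);  // 0 = alive at horizon
  IntegerMatrix occ(7, horizon); // occupancy counts per state and month
  IntegerMatrix state_months(n, 7); // per-patient months spent in each state
  IntegerMatrix path_state, path_tis, path_phase;
  if (keep_paths) {
    path_state = IntegerMatrix(n, horizon);
    path_tis = IntegerMatrix(n, horizon);
    path_phase = IntegerMatrix(n, horizon);
  }

  for (int i = 0; i < n; ++i) {
    int s = start - 1;   // 0-based internal state
    int tis = 0;
    int phase = 0;       // 0 active, 1 suspended
    int phase_left = intermittent[s] ? active_len : 0;
    double q = 0.0, l = 0.0, c = 0.0;
    int dm = 0;

    for (int m = 1; m <= horizon; ++m) {
      ++tis;
      const double df = disc[m - 1];
      const bool susp = intermittent[s] && phase == 1;
      const bool on_chemo = !susp && chemo_cycles[s] > 0 &&
                            tis <= chemo_cycles[s];
      c += df * (susp ? cost_susp : (on_chemo ? cost_on[s] : cost_off[s]));
      q += df * (susp ? util_susp[s] : (on_chemo ? util_on[s] : util_off[s]));
      l += df / 12.0;
      occ(s, m - 1) += 1;
      state_months(i, s) += 1;
      if (keep_paths) {
        path_state(i, m - 1) = s + 1;
        path_tis(i, m - 1) = tis;
        path_phase(i, m - 1) =
          susp ? 1 : ((chemo_cycles[s] > 0 && !on_chemo) ? 2 : 0);
      }

      // event resolution at month end
      if (s == 6) {  // progressed mCRPC: death only
        if (unif_rand() < delta_prog) { dm = m; }
      } else {
        double p = alpha[s] * std::pow(1.0 + beta[s], tis - 1);
        const double cap = 1.0 - gamma_[s];
        if (p > cap) p = cap;
        const double u = unif_rand();
        if (u < p) {
          int ns;
          if (s == 0) {
            if (unif_rand() < p_nmcrpc) ns = 3;
            else ns = (unif_rand() < p_low) ? 1 : 2;
          } else if (s <= 3) ns = 4;
          else if (s == 4) ns = has_l2 ? 5 : 6;
          else ns = 6;
          s = ns; tis = 0; phase = 0;
          phase_left = intermittent[s] ? active_len : 0;
        } else if (u < p + gamma_[s]) {
          dm = m;
        } else if (intermittent[s]) {
          if (--phase_left <= 0) {
            if (phase == 0) {
              phase = 1;
              double len = std::floor(susp_scale *
                                      R::rbeta(susp_a, susp_b) + 0.5);
              phase_left = len < 1.0 ? 1 : (int)len;
            } else {
              phase = 0;
              phase_left = active_len;
            }
          }
        }
      }
      if (dm > 0) {
        // terminal-care costs for deaths in progressed mCRPC: the last
        // min(eol_max_months, months spent progressed) months of life
        if (s == 6) {
          int k = tis < eol_max_months ? tis : eol_max_months;
          for (int j = 0; j < k; ++j) c += eol_monthly * disc[m - 1 - j];
        }
        break;
      }
    }
    qaly[i] = q; ly[i] = l; cost[i] = c; death_month[i] = dm;
  }

  List out = List::create(
    _["qaly"] = qaly, _["ly"] = ly, _["cost"] = cost,
    _["death_month"] = death_month, _["occupancy"] = occ,
    _["state_months"] = state_months);
  if (keep_paths) {
    out["path_state"] = path_state;
    out["path_tis"] = path_tis;
    out["path_phase"] = path_phase;
  }
  return out;
}
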