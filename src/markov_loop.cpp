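#include <Rcpp.h>
using namespace Rcpp;

// Monthly accumulation loop of the cohort engine. The conditional-on-survival
// transition matrix is age-invariant; only the death probability (other-cause
// mortality times the state's hazard ratio) changes with age. Accrual happens
// in the start-of-cycle state; the death cost (if any) is added in the cycle
// of death. Returns cost, QALYs, undiscounted and discounted life-years.
// [[Rcpp::export]]
NumericVector markov_accumulate(NumericVector init, NumericMatrix cond,
                                NumericVector hr, NumericVector mort,
                                NumericVector inc, NumericVector uw,
                                NumericVector uplus, NumericVector base_cost,
                                NumericVector agew, NumericVector death_cost,
                                NumericVector disc, double cyc_frac) {
  const int S = init.size(), M = mort.size();
  std::vector<double> occ(init.begin(), init.end()), nxt(S);
  double cost = 0, qaly = 0, ly = 0, dly = 0;
  for (int m = 0; m < M; ++m) {
    double live = 0;
    for (int i = 0; i < S; ++i) live += occ[i];
    if (live < 1e-9) break;
    double c_m = live * base_cost[m], q_m = 0, d_m = 0;
    for (int i = 0; i < S; ++i) {
      c_m += occ[i] * inc[i];
      q_m += occ[i] * (agew[m] * uw[i] + uplus[i]);
    }
    c_m *= cyc_frac;
    q_m *= cyc_frac;
    for (int i = 0; i < S; ++i) {
      double pd = 1.0 - std::exp(-(mort[m] * hr[i] / 1e5) * cyc_frac);
      double de = occ[i] * pd;
      d_m += de;
      occ[i] -= de;
    }
    cost += (c_m + d_m * death_cost[m]) * disc[m];
    qaly += q_m * disc[m];
    ly += live * cyc_frac;
    dly += live * cyc_frac * disc[m];
    std::fill(nxt.begin(), nxt.end(), 0.0);
    for (int i = 0; i < S; ++i) {
      double oi = occ[i];
      if (oi <= 0) continue;
      for (int j = 0; j < S; ++j) nxt[j] += oi * cond(i, j);
    }
    std::copy(nxt.begin(), nxt.end(), occ.begin());
  }
  return NumericVector::create(cost, qaly, ly, dly);
}
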