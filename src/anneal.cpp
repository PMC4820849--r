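#include <Rcpp.h>
using namespace Rcpp;

// Simulated-annealing chain for the minimum-set problem.
//
// Objective: sum of selected costs + sum_f w[f] * shortfall_f, where
// shortfall_f = max(0, target[f] - representation_f). Proposals toggle a
// single candidate unit; Metropolis acceptance with geometric cooling
// (temp *= cooling each iteration). Uses R's RNG, so results are
// reproducible under set.seed() on the R side. Returns the best-objective
// state visited.
//
// A: features x units effective-amount matrix (all units)
// cand: 0-based indices of toggleable units (available, not locked)
// init: initial selection over all units (locked-in already TRUE)
// [[Rcpp::export(name = ".anneal_core")]]
LogicalVector anneal_core(NumericMatrix A, NumericVector cost,
                          IntegerVector cand, LogicalVector init,
                          NumericVector target, NumericVector w,
                          double temp, double cooling, int iterations) {
  const int nf = A.nrow();
  const int n = A.ncol();
  const int m = cand.size();

  // sparse per-column nonzeros: most units hold few features
  std::vector<std::vector<std::pair<int, double> > > nz(n);
  for (int j = 0; j < n; ++j)
    for (int f = 0; f < nf; ++f)
      if (A(f, j) != 0.0) nz[j].push_back(std::make_pair(f, A(f, j)));

  std::vector<int> sel(n);
  std::vector<double> rep(nf, 0.0);
  double cost_sel = 0.0;
  for (int j = 0; j < n; ++j) {
    sel[j] = init[j] ? 1 : 0;
    if (sel[j]) {
      cost_sel += cost[j];
      for (size_t k = 0; k < nz[j].size(); ++k)
        rep[nz[j][k].first] += nz[j][k].second;
    }
  }
  double pen = 0.0;
  for (int f = 0; f < nf; ++f) {
    double s = target[f] - rep[f];
    if (s > 0) pen += w[f] * s;
  }
  double obj = cost_sel + pen;

  std::vector<int> best_sel(sel);
  double best_obj = obj;

  if (m > 0) {
    for (int it = 0; it < iterations; ++it) {
      int j = cand[(int)(unif_rand() * m) % m];
      double sign = sel[j] ? -1.0 : 1.0;
      double delta = sign * cost[j];
      for (size_t k = 0; k < nz[j].size(); ++k) {
        int f = nz[j][k].first;
        double a = nz[j][k].second;
        double old_s = target[f] - rep[f];
        double new_s = old_s - sign * a;
        delta += w[f] * ((new_s > 0 ? new_s : 0) - (old_s > 0 ? old_s : 0));
      }
      if (delta <= 0 || (temp > 0 && unif_rand() < std::exp(-delta / temp))) {
        sel[j] = 1 - sel[j];
        for (size_t k = 0; k < nz[j].size(); ++k)
          rep[nz[j][k].first] += sign * nz[j][k].second;
        obj += delta;
        if (obj < best_obj) {
          best_obj = obj;
          best_sel = sel;
        }
      }
      temp *= cooling;
    }
  }

  LogicalVector out(n);
  for (int j = 0; j < n; ++j) out[j] = best_sel[j] == 1;
  return out;
}
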