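#include <Rcpp.h>
using namespace Rcpp;

// Exact stochastic simulation (Gillespie direct method) of a continuous-time
// Markov chain with generator Q (rows = from-states, off-diagonals >= 0).
// Uses R's RNG so results are reproducible under set.seed().

static int draw_next(const NumericMatrix& Q, int s, double total) {
  double u = R::runif(0.0, total);
  double acc = 0.0;
  int n = Q.ncol(), last = -1;
  for (int j = 0; j < n; ++j) {
    if (j == s) continue;
    double q = Q(s, j);
    if (q <= 0.0) continue;
    acc += q;
    last = j;
    if (u <= acc) return j;
  }
  return last; // guard against rounding at u ~= total
}

// [[Rcpp::export(name = ".ssaPathC")]]
List ssa_path(NumericMatrix Q, int start, double duration) {
  int s = start - 1;
  double t = 0.0;
  std::vector<int> states;
  std::vector<double> entry;
  states.push_back(s + 1);
  entry.push_back(0.0);
  for (;;) {
    double total = -Q(s, s);
    if (total <= 0.0) break;          // absorbing: dwell to end of window
    t += R::rexp(1.0 / total);
    if (t >= duration) break;
    s = draw_next(Q, s, total);
    states.push_back(s + 1);
    entry.push_back(t);
  }
  return List::create(_["states"] = wrap(states), _["entry"] = wrap(entry));
}

// First-passage times from `start` into the set `target` (1-based indices),
// n independent passages, each capped at tmax seconds (capped passages are
// returned as NA).
// [[Rcpp::export(name = ".ssaFirstPassageC")]]
NumericVector ssa_first_passage(NumericMatrix Q, int start,
                                IntegerVector target, int n, double tmax) {
  int ns = Q.nrow();
  std::vector<bool> is_target(ns, false);
  for (int k = 0; k < target.size(); ++k) is_target[target[k] - 1] = true;
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int s = start - 1;
    double t = 0.0;
    bool hit = false;
    while (t < tmax) {
      double total = -Q(s, s);
      if (total <= 0.0) break;        // stuck: never reaches target
      t += R::rexp(1.0 / total);
      if (t >= tmax) break;
      s = draw_next(Q, s, total);
      if (is_target[s]) { hit = true; break; }
    }
    out[i] = hit ? t : NA_REAL;
  }
  return out;
}
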