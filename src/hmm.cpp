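#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Two-state Gaussian hidden Markov model: scaled forward-backward
// (Baum-Welch) parameter estimation and Viterbi decoding, specialized to
// K = 2 states for speed on long (~1e5 frame) extension traces.

static inline double dnorm_(double x, double mu, double sd) {
  double z = (x - mu) / sd;
  return std::exp(-0.5 * z * z) / (sd * 2.5066282746310002);
}

// [[Rcpp::export(name = ".hmm2EmC")]]
List hmm2_em(NumericVector x, NumericVector mu0, NumericVector sd0,
             NumericMatrix A0, NumericVector pi0, int maxit, double tol) {
  int T = x.size();
  double mu[2] = {mu0[0], mu0[1]};
  double sd[2] = {sd0[0], sd0[1]};
  double A[2][2] = {{A0(0, 0), A0(0, 1)}, {A0(1, 0), A0(1, 1)}};
  double pi[2] = {pi0[0], pi0[1]};
  std::vector<double> a0(T), a1(T), b0(T), b1(T), c(T), g0(T), g1(T);
  double ll_old = R_NegInf, ll = R_NegInf;
  int it = 0;
  const double sd_floor = 1e-8;
  for (it = 0; it < maxit; ++it) {
    // forward with scaling
    double e0 = dnorm_(x[0], mu[0], sd[0]), e1 = dnorm_(x[0], mu[1], sd[1]);
    a0[0] = pi[0] * e0; a1[0] = pi[1] * e1;
    c[0] = a0[0] + a1[0];
    if (c[0] <= 0) c[0] = DBL_MIN;
    a0[0] /= c[0]; a1[0] /= c[0];
    for (int t = 1; t < T; ++t) {
      e0 = dnorm_(x[t], mu[0], sd[0]); e1 = dnorm_(x[t], mu[1], sd[1]);
      double p0 = (a0[t-1] * A[0][0] + a1[t-1] * A[1][0]) * e0;
      double p1 = (a0[t-1] * A[0][1] + a1[t-1] * A[1][1]) * e1;
      double s = p0 + p1;
      if (s <= 0) { s = DBL_MIN; p0 = DBL_MIN; }
      c[t] = s; a0[t] = p0 / s; a1[t] = p1 / s;
    }
    ll = 0.0;
    for (int t = 0; t < T; ++t) ll += std::log(c[t]);
    // backward
    b0[T-1] = 1.0; b1[T-1] = 1.0;
    for (int t = T - 2; t >= 0; --t) {
      e0 = dnorm_(x[t+1], mu[0], sd[0]); e1 = dnorm_(x[t+1], mu[1], sd[1]);
      b0[t] = (A[0][0] * e0 * b0[t+1] + A[0][1] * e1 * b1[t+1]) / c[t+1];
      b1[t] = (A[1][0] * e0 * b0[t+1] + A[1][1] * e1 * b1[t+1]) / c[t+1];
    }
    // posteriors and transition expectations
    double n00 = 0, n01 = 0, n10 = 0, n11 = 0;
    double s0 = 0, s1 = 0, m0 = 0, m1 = 0;
    for (int t = 0; t < T; ++t) {
      g0[t] = a0[t] * b0[t]; g1[t] = a1[t] * b1[t];
      double gs = g0[t] + g1[t];
      if (gs <= 0) gs = DBL_MIN;
      g0[t] /= gs; g1[t] /= gs;
      s0 += g0[t]; s1 += g1[t];
      m0 += g0[t] * x[t]; m1 += g1[t] * x[t];
    }
    for (int t = 0; t < T - 1; ++t) {
      e0 = dnorm_(x[t+1], mu[0], sd[0]); e1 = dnorm_(x[t+1], mu[1], sd[1]);
      double x00 = a0[t] * A[0][0] * e0 * b0[t+1] / c[t+1];
      double x01 = a0[t] * A[0][1] * e1 * b1[t+1] / c[t+1];
      double x10 = a1[t] * A[1][0] * e0 * b0[t+1] / c[t+1];
      double x11 = a1[t] * A[1][1] * e1 * b1[t+1] / c[t+1];
      double xs = x00 + x01 + x10 + x11;
      if (xs <= 0) continue;
      n00 += x00 / xs; n01 += x01 / xs; n10 += x10 / xs; n11 += x11 / xs;
    }
    // M-step
    pi[0] = g0[0]; pi[1] = g1[0];
    if (n00 + n01 > 0) { A[0][0] = n00 / (n00 + n01); A[0][1] = 1 - A[0][0]; }
    if (n10 + n11 > 0) { A[1][1] = n11 / (n10 + n11); A[1][0] = 1 - A[1][1]; }
    if (s0 > 0) mu[0] = m0 / s0;
    if (s1 > 0) mu[1] = m1 / s1;
    double v0 = 0, v1 = 0;
    for (int t = 0; t < T; ++t) {
      v0 += g0[t] * (x[t] - mu[0]) * (x[t] - mu[0]);
      v1 += g1[t] * (x[t] - mu[1]) * (x[t] - mu[1]);
    }
    sd[0] = s0 > 0 ? std::sqrt(v0 / s0) : sd[0];
    sd[1] = s1 > 0 ? std::sqrt(v1 / s1) : sd[1];
    if (sd[0] < sd_floor) sd[0] = sd_floor;
    if (sd[1] < sd_floor) sd[1] = sd_floor;
    if (it > 0 && std::fabs(ll - ll_old) < tol * (1.0 + std::fabs(ll))) break;
    ll_old = ll;
  }
  return List::create(
    _["mu"] = NumericVector::create(mu[0], mu[1]),
    _["sd"] = NumericVector::create(sd[0], sd[1]),
    _["A"] = NumericMatrix(2, 2,
        std::vector<double>{A[0][0], A[1][0], A[0][1], A[1][1]}.data()),
    _["pi"] = NumericVector::create(pi[0], pi[1]),
    _["logLik"] = ll, _["iter"] = it + 1);
}

// [[Rcpp::export(name = ".hmm2ViterbiC")]]
IntegerVector hmm2_viterbi(NumericVector x, NumericVector mu, NumericVector sd,
                           NumericMatrix A, NumericVector pi) {
  int T = x.size();
  const double tiny = 1e-300;
  double lA[2][2];
  for (int i = 0; i < 2; ++i)
    for (int j = 0; j < 2; ++j)
      lA[i][j] = std::log(A(i, j) + tiny);
  std::vector<double> d0(T), d1(T);
  std::vector<unsigned char> p0(T), p1(T);
  d0[0] = std::log(pi[0] + tiny) + std::log(dnorm_(x[0], mu[0], sd[0]) + tiny);
  d1[0] = std::log(pi[1] + tiny) + std::log(dnorm_(x[0], mu[1], sd[1]) + tiny);
  for (int t = 1; t < T; ++t) {
    double e0 = std::log(dnorm_(x[t], mu[0], sd[0]) + tiny);
    double e1 = std::log(dnorm_(x[t], mu[1], sd[1]) + tiny);
    double a = d0[t-1] + lA[0][0], b = d1[t-1] + lA[1][0];
    if (a >= b) { d0[t] = a + e0; p0[t] = 0; } else { d0[t] = b + e0; p0[t] = 1; }
    a = d0[t-1] + lA[0][1]; b = d1[t-1] + lA[1][1];
    if (a >= b) { d1[t] = a + e1; p1[t] = 0; } else { d1[t] = b + e1; p1[t] = 1; }
  }
  IntegerVector path(T);
  int s = d0[T-1] >= d1[T-1] ? 0 : 1;
  path[T-1] = s + 1;
  for (int t = T - 1; t > 0; --t) {
    s = s == 0 ? p0[t] : p1[t];
    path[t-1] = s + 1;
  }
  return path;
}
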