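// Breslow partial likelihood, score and observed information for
// time-varying covariates that are affine in time per subject:
//   x1_j(t) = a_j + s_j * t  (the trajectory), plus optional static
// columns (genotype dosage, covariates).  Subjects are pre-sorted by
// decreasing observed time so the risk set at the k-th (ascending)
// unique event time is a prefix.  Mirrors the R reference used in the
// tests.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
List cox_pl_cpp(NumericVector theta,
                NumericVector a, NumericVector s,
                NumericMatrix Xs,            // n x p_s static columns
                NumericVector ev_times,      // ascending unique event times
                IntegerVector n_at_risk,     // risk-prefix size per event time
                List ev_idx,                 // 1-based indices of events
                bool need_info) {
  const int n = a.size();
  const int p_s = Xs.ncol();
  const int p = 1 + p_s;
  const int D = ev_times.size();
  const double b = theta[0];

  std::vector<double> base(n);
  for (int i = 0; i < n; ++i) {
    double lp = b * a[i];
    for (int j = 0; j < p_s; ++j) lp += theta[1 + j] * Xs(i, j);
    base[i] = lp;
  }

  double ll = 0.0;
  NumericVector U(p);
  NumericMatrix I(p, p);
  std::vector<double> S1(p), S2(p * p);

  for (int k = 0; k < D; ++k) {
    const double e = ev_times[k];
    const int nr = n_at_risk[k];
    // max of eta over the risk set for overflow-safe exponentials
    double mx = -INFINITY;
    for (int i = 0; i < nr; ++i) {
      double eta = base[i] + b * s[i] * e;
      if (eta > mx) mx = eta;
    }
    double S0 = 0.0;
    std::fill(S1.begin(), S1.end(), 0.0);
    if (need_info) std::fill(S2.begin(), S2.end(), 0.0);
    std::vector<double> x(p);
    for (int i = 0; i < nr; ++i) {
      x[0] = a[i] + s[i] * e;
      for (int j = 0; j < p_s; ++j) x[1 + j] = Xs(i, j);
      double w = std::exp(base[i] + b * s[i] * e - mx);
      S0 += w;
      for (int j = 0; j < p; ++j) S1[j] += w * x[j];
      if (need_info) {
        for (int j = 0; j < p; ++j) {
          for (int l = 0; l <= j; ++l) S2[j * p + l] += w * x[j] * x[l];
        }
      }
    }
    IntegerVector dk = ev_idx[k];
    const int d = dk.size();
    for (int ii = 0; ii < d; ++ii) {
      int i = dk[ii] - 1;
      double traj = a[i] + s[i] * e;
      ll += base[i] + b * s[i] * e;
      U[0] += traj;
      for (int j = 0; j < p_s; ++j) U[1 + j] += Xs(i, j);
    }
    ll -= d * (std::log(S0) + mx);
    for (int j = 0; j < p; ++j) U[j] -= d * S1[j] / S0;
    if (need_info) {
      for (int j = 0; j < p; ++j) {
        for (int l = 0; l <= j; ++l) {
          double v = d * (S2[j * p + l] / S0 - (S1[j] / S0) * (S1[l] / S0));
          I(j, l) += v;
          if (l != j) I(l, j) += v;
        }
      }
    }
  }
  return List::create(Named("ll") = ll, Named("U") = U, Named("I") = I);
}
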