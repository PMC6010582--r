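// Compiled kernel for the joint-likelihood evaluation: per-subject
// posterior mode search (damped Newton on a strictly concave 2-D
// objective) and adaptive Gauss-Hermite quadrature of the random-effect
// integral.  Mirrors the vectorized R reference implementation
// (joint_loglik_prep_r); the two are cross-checked in the test suite.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// phi_k(w) = int_0^1 t^(k-1) exp(w t) dt, stable near w = 0
static inline double phi1(double w) {
  if (std::fabs(w) < 1e-12) return 1.0 + w / 2.0;
  return std::expm1(w) / w;
}
static inline double phi2(double w) {
  if (std::fabs(w) < 1e-4)
    return 0.5 + w / 3.0 + w * w / 8.0 + w * w * w / 30.0;
  return (w * std::exp(w) - std::expm1(w)) / (w * w);
}
static inline double phi3(double w) {
  if (std::fabs(w) < 1e-3)
    return 1.0 / 3.0 + w / 4.0 + w * w / 10.0 + w * w * w / 36.0;
  return (std::exp(w) * (w * w - 2.0 * w + 2.0) - 2.0) / (w * w * w);
}

struct SurvInt { double Q0, Q1, Q2; };

// weighted integrals of (1, s, s^2) exp(c s) over the three hazard pieces
static inline SurvInt surv_ints(double c, const double* t, const double* r) {
  SurvInt out = {0.0, 0.0, 0.0};
  double lo = 0.0;
  for (int k = 0; k < 3; ++k) {
    double hi = t[k];
    double d = hi - lo;
    if (d > 0.0) {
      double w = c * d;
      double e = r[k] * std::exp(c * lo) * d;
      double p1 = phi1(w), p2 = phi2(w), p3 = phi3(w);
      out.Q0 += e * p1;
      out.Q1 += e * (lo * p1 + d * p2);
      out.Q2 += e * (lo * lo * p1 + 2.0 * lo * d * p2 + d * d * p3);
    }
    lo = hi;
  }
  return out;
}

static inline double cum_Q0(double c, const double* t, const double* r) {
  double out = 0.0, lo = 0.0;
  for (int k = 0; k < 3; ++k) {
    double d = t[k] - lo;
    if (d > 0.0) out += r[k] * std::exp(c * lo) * d * phi1(c * d);
    lo = t[k];
  }
  return out;
}

// [[Rcpp::export]]
List joint_ll_cpp(NumericVector m, NumericVector St, NumericVector Stt,
                  NumericVector S_r, NumericVector S_rt, NumericVector S_rr,
                  NumericVector Tv, NumericVector delta,
                  NumericMatrix hi, NumericVector log_rate_T,
                  NumericVector cbase, NumericVector rates,
                  double beta, double sigma_e,
                  NumericVector mu, NumericMatrix P, double logdetSigma,
                  NumericVector qx1, NumericVector qx2, NumericVector qlogw,
                  NumericVector b0_init, NumericVector b1_init,
                  bool use_init) {
  const int n = m.size();
  const int Q = qx1.size();
  const double s2 = sigma_e * sigma_e;
  const double log2pis2 = std::log(2.0 * M_PI * s2);
  const double P11 = P(0, 0), P12 = P(0, 1), P22 = P(1, 1);
  const double mu0 = mu[0], mu1 = mu[1];
  const double prior_const = -std::log(2.0 * M_PI) - 0.5 * logdetSigma;
  const double r[3] = {rates[0], rates[1], rates[2]};
  const double SQRT2 = std::sqrt(2.0);

  NumericVector b0_out(n), b1_out(n);
  double ll = 0.0;
  std::vector<double> hq(Q);

  for (int i = 0; i < n; ++i) {
    const double mi = m[i], Sti = St[i], Stti = Stt[i];
    const double Sri = S_r[i], Srti = S_rt[i], Srri = S_rr[i];
    const double Ti = Tv[i], di = delta[i];
    const double cb = cbase[i], lrT = log_rate_T[i];
    const double t[3] = {hi(i, 0), hi(i, 1), hi(i, 2)};

    // complete-data log density at (b0, b1)
    auto h_fun = [&](double b0, double b1) -> double {
      double sse = Srri - 2.0 * (b0 * Sri + b1 * Srti) + b0 * b0 * mi +
                   2.0 * b0 * b1 * Sti + b1 * b1 * Stti;
      double loglong = -0.5 * mi * log2pis2 - sse / (2.0 * s2);
      double expo = beta * b0 + cb;
      if (expo > 700.0) expo = 700.0;
      double cum = std::exp(expo) * cum_Q0(beta * b1, t, r);
      double event = di * (lrT + beta * (b0 + b1 * Ti) + cb);
      double d0 = b0 - mu0, d1 = b1 - mu1;
      double prior = prior_const -
        0.5 * (P11 * d0 * d0 + 2.0 * P12 * d0 * d1 + P22 * d1 * d1);
      return loglong + event - cum + prior;
    };

    // starting point
    double b0, b1;
    if (use_init) {
      b0 = b0_init[i];
      b1 = b1_init[i];
    } else {
      double A11 = mi / s2 + P11, A12 = Sti / s2 + P12, A22 = Stti / s2 + P22;
      double r1 = Sri / s2 + P11 * mu0 + P12 * mu1;
      double r2 = Srti / s2 + P12 * mu0 + P22 * mu1;
      double det0 = A11 * A22 - A12 * A12;
      b0 = (A22 * r1 - A12 * r2) / det0;
      b1 = (A11 * r2 - A12 * r1) / det0;
    }
    double h = h_fun(b0, b1);
    if (!std::isfinite(h)) {  // bad warm start: fall back to Gaussian mode
      double A11 = mi / s2 + P11, A12 = Sti / s2 + P12, A22 = Stti / s2 + P22;
      double r1 = Sri / s2 + P11 * mu0 + P12 * mu1;
      double r2 = Srti / s2 + P12 * mu0 + P22 * mu1;
      double det0 = A11 * A22 - A12 * A12;
      b0 = (A22 * r1 - A12 * r2) / det0;
      b1 = (A11 * r2 - A12 * r1) / det0;
      h = h_fun(b0, b1);
      if (!std::isfinite(h)) return List::create(Named("ok") = false);
    }

    // damped Newton; one full step past tolerance leaves O(tol^2) error
    double H00 = 0, H01 = 0, H11 = 0;
    for (int it = 0; it < 100; ++it) {
      double expo = beta * b0 + cb;
      if (expo > 700.0) expo = 700.0;
      double E0 = std::exp(expo);
      SurvInt q = surv_ints(beta * b1, t, r);
      double g0 = (Sri - b0 * mi - b1 * Sti) / s2 + di * beta -
                  beta * E0 * q.Q0 - (P11 * (b0 - mu0) + P12 * (b1 - mu1));
      double g1 = (Srti - b0 * Sti - b1 * Stti) / s2 + di * beta * Ti -
                  beta * E0 * q.Q1 - (P12 * (b0 - mu0) + P22 * (b1 - mu1));
      H00 = -mi / s2 - beta * beta * E0 * q.Q0 - P11;
      H01 = -Sti / s2 - beta * beta * E0 * q.Q1 - P12;
      H11 = -Stti / s2 - beta * beta * E0 * q.Q2 - P22;
      double det = H00 * H11 - H01 * H01;
      double st0 = -(H11 * g0 - H01 * g1) / det;
      double st1 = -(-H01 * g0 + H00 * g1) / det;
      if (!std::isfinite(st0) || !std::isfinite(st1))
        return List::create(Named("ok") = false);
      double amax = std::max(std::fabs(st0), std::fabs(st1));
      if (amax < 1e-9) { b0 += st0; b1 += st1; break; }
      double lam = 1.0;
      double h_new = h_fun(b0 + st0, b1 + st1);
      int hv = 0;
      while ((!std::isfinite(h_new) || h_new < h - 1e-10) && hv < 10) {
        lam *= 0.5;
        h_new = h_fun(b0 + lam * st0, b1 + lam * st1);
        ++hv;
      }
      b0 += lam * st0;
      b1 += lam * st1;
      h = h_new;
      if (lam * amax < 1e-9) break;
    }
    b0_out[i] = b0;
    b1_out[i] = b1;

    // curvature at the mode
    {
      double expo = beta * b0 + cb;
      if (expo > 700.0) expo = 700.0;
      double E0 = std::exp(expo);
      SurvInt q = surv_ints(beta * b1, t, r);
      H00 = -mi / s2 - beta * beta * E0 * q.Q0 - P11;
      H01 = -Sti / s2 - beta * beta * E0 * q.Q1 - P12;
      H11 = -Stti / s2 - beta * beta * E0 * q.Q2 - P22;
    }
    double a = -H00, b = -H01, c = -H11;
    if (!(a > 0.0) || !(c > 0.0)) return List::create(Named("ok") = false);
    double u11 = std::sqrt(a), u12 = b / u11;
    double arg = c - u12 * u12;
    if (!(arg > 0.0)) return List::create(Named("ok") = false);
    double u22 = std::sqrt(arg);
    double log_detB = -(std::log(u11) + std::log(u22));

    // adaptive Gauss-Hermite nodes: b = mode + sqrt(2) * U^{-1} x
    double hmax = -INFINITY;
    for (int qq = 0; qq < Q; ++qq) {
      double x1 = qx1[qq], x2 = qx2[qq];
      double bb0 = b0 + SQRT2 * (x1 / u11 - u12 * x2 / (u11 * u22));
      double bb1 = b1 + SQRT2 * (x2 / u22);
      double v = h_fun(bb0, bb1) + qlogw[qq];
      hq[qq] = v;
      if (v > hmax) hmax = v;
    }
    if (!std::isfinite(hmax)) return List::create(Named("ok") = false);
    double sum = 0.0;
    for (int qq = 0; qq < Q; ++qq) sum += std::exp(hq[qq] - hmax);
    ll += std::log(2.0) + log_detB + hmax + std::log(sum);
  }

  return List::create(Named("ok") = true, Named("ll") = ll,
                      Named("b0") = b0_out, Named("b1") = b1_out);
}
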