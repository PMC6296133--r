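// Compiled kernels for the screening-history likelihood.
//
// The acyclic four-state chain has closed-form piecewise transition
// probabilities; the per-woman likelihood is a forward recursion over a
// three-component belief (state 1; state 2 missed at the last attended
// screen; state 4 missed). Age pairs are fixed by the data, so the caller
// passes, per age interval, the compacted non-zero exposure durations with
// their pair indices (zero-duration segments are identity pieces and are
// skipped). The pure-R implementations of the same computations live in R/
// and serve as the cross-check in the test suite.

#include <Rcpp.h>
using namespace Rcpp;

// P12 piece factor with three regimes: plain difference quotient away from
// the degeneracy lambda23 = lambda12 (1 + r), an expm1 form close to it,
// and the second-order analytic limit lambda12 dt exp(-a dt) (1 - d dt / 2)
// inside the |d| < 1e-8 band.
static inline double q12_piece(double lam12, double d, double t, double ea,
                               double eb) {
  if (std::fabs(d) < 1e-8) return lam12 * t * ea * (1.0 - 0.5 * d * t);
  if (std::fabs(d) < 1e-4) return lam12 * ea * (-std::expm1(-d * t)) / d;
  return lam12 * (ea - eb) / d;
}

// Closed-form first/second-row entries of P(s, t) for stacked (s, t) pairs.
// nz_idx[l] (1-based pair indices) / nz_dt[l] hold the non-zero exposure of
// interval l. Output vectors have length n_pairs.
static void trans_core(int n_pairs, const List& nz_idx, const List& nz_dt,
                       const NumericVector& l12, const NumericVector& l23,
                       double r,
                       std::vector<double>& p11, std::vector<double>& p12,
                       std::vector<double>& p14, std::vector<double>& p22) {
  const int L = nz_idx.size();
  p11.assign(n_pairs, 1.0); p12.assign(n_pairs, 0.0);
  p14.assign(n_pairs, 0.0); p22.assign(n_pairs, 1.0);
  for (int l = 0; l < L; ++l) {
    const IntegerVector idx = nz_idx[l];
    const NumericVector tv = nz_dt[l];
    const double lam12 = l12[l], lam23 = l23[l];
    const double a = lam12 * (1.0 + r);
    const double d = lam23 - a;
    const double c14 = a > 0.0 ? r / (1.0 + r) : 0.0;
    const int m = idx.size();
    for (int j = 0; j < m; ++j) {
      const int i = idx[j] - 1;
      const double t = tv[j];
      const double ea = std::exp(-a * t);
      const double eb = std::exp(-lam23 * t);
      const double q12 = q12_piece(lam12, d, t, ea, eb);
      const double q14 = c14 * (1.0 - ea);
      const double np12 = p11[i] * q12 + p12[i] * eb;
      const double np14 = p11[i] * q14 + p14[i];
      p11[i] *= ea;
      p22[i] *= eb;
      p12[i] = np12;
      p14[i] = np14;
    }
  }
}

// [[Rcpp::export(name = ".trans_probs_cpp")]]
List trans_probs_cpp(int n_pairs, List nz_idx, List nz_dt, NumericVector l12,
                     NumericVector l23, double r) {
  std::vector<double> p11, p12, p14, p22;
  trans_core(n_pairs, nz_idx, nz_dt, l12, l23, r, p11, p12, p14, p22);
  NumericVector o11(n_pairs), o12(n_pairs), o13(n_pairs), o14(n_pairs),
      o22(n_pairs);
  for (int i = 0; i < n_pairs; ++i) {
    o11[i] = p11[i]; o12[i] = p12[i]; o14[i] = p14[i]; o22[i] = p22[i];
    const double v = 1.0 - p11[i] - p12[i] - p14[i];
    o13[i] = v > 0.0 ? v : 0.0;
  }
  return List::create(_["p11"] = o11, _["p12"] = o12, _["p13"] = o13,
                      _["p14"] = o14, _["p22"] = o22);
}

// Per-woman log-likelihood. Slice layout of the stacked pairs: screening
// steps (in step order), then clinical terminals, censoring terminals, and
// entry-conditioning pairs. Indices are 1-based (from R).
// [[Rcpp::export(name = ".loglik_cpp")]]
NumericVector loglik_cpp(int n, int n_pairs, List nz_idx, List nz_dt,
                         NumericVector l12, NumericVector l23, double r,
                         double S, IntegerVector steps_idx,
                         IntegerVector steps_det, IntegerVector cl_idx,
                         IntegerVector cl_int, IntegerVector cs_idx,
                         bool condition_entry) {
  std::vector<double> p11, p12, p14, p22;
  trans_core(n_pairs, nz_idx, nz_dt, l12, l23, r, p11, p12, p14, p22);

  std::vector<double> b1(n, 1.0), b2(n, 0.0), b4(n, 0.0), lw(n, 0.0);
  NumericVector ll(n, NA_REAL);
  int at = 0;
  const int n_steps = steps_idx.size();
  for (int sp = 0; sp < n_steps; ++sp, ++at) {
    const int i = steps_idx[sp] - 1;
    const double q11 = p11[at], q12 = p12[at], q14 = p14[at], q22 = p22[at];
    if (steps_det[sp]) {
      const double lik = b1[i] * (q12 + q14) * S + b2[i] * q22 + b4[i];
      ll[i] = lw[i] + std::log(lik);
    } else {
      const double nb1 = b1[i] * q11;
      const double nb2 = b1[i] * q12 * (1.0 - S);
      const double nb4 = b1[i] * q14 * (1.0 - S);
      const double norm = nb1 + nb2 + nb4;
      lw[i] += std::log(norm);
      b1[i] = nb1 / norm; b2[i] = nb2 / norm; b4[i] = nb4 / norm;
    }
  }
  for (int j = 0; j < cl_idx.size(); ++j, ++at) {
    const int i = cl_idx[j] - 1;
    const double lam = l23[cl_int[j] - 1];
    const double lik = lam * (b1[i] * p12[at] + b2[i] * p22[at]);
    ll[i] = lw[i] + std::log(lik);
  }
  for (int j = 0; j < cs_idx.size(); ++j, ++at) {
    const int i = cs_idx[j] - 1;
    double p13 = 1.0 - p11[at] - p12[at] - p14[at];
    if (p13 < 0.0) p13 = 0.0;
    const double lik = b1[i] * (1.0 - p13) + b2[i] * p22[at] + b4[i];
    ll[i] = lw[i] + std::log(lik);
  }
  if (condition_entry) {
    for (int i = 0; i < n; ++i, ++at) {
      double p13 = 1.0 - p11[at] - p12[at] - p14[at];
      if (p13 < 0.0) p13 = 0.0;
      ll[i] -= std::log1p(-p13);
    }
  }
  return ll;
}
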