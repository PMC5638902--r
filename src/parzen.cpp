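#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Gaussian Parzen accumulation of the unnormalized joint density of paired
// samples (x, y) on a regular bin-centre grid. Kernels are truncated at
// `cut` standard deviations; each sample touches only the bins inside its
// truncation window, so cost is O(n * window^2).
// Returns q with q(m, n) = (1/N) * sum_i phi_su(u_m - x_i) phi_sv(v_n - y_i),
// phi a normalized Gaussian density.
// [[Rcpp::export]]
NumericMatrix parzen_joint_raw(NumericVector x, NumericVector y,
                               NumericVector u, NumericVector v,
                               double su, double sv, double cut) {
  const int n = x.size();
  const int M = u.size(), N = v.size();
  const double du = u[1] - u[0], dv = v[1] - v[0];
  const double cu = 1.0 / (su * std::sqrt(2.0 * M_PI));
  const double cv = 1.0 / (sv * std::sqrt(2.0 * M_PI));
  NumericMatrix q(M, N);
  const int wu = (int)std::ceil(cut * su / du);
  const int wv = (int)std::ceil(cut * sv / dv);
  std::vector<double> au(2 * wu + 1), av(2 * wv + 1);
  for (int i = 0; i < n; ++i) {
    const double xi = x[i], yi = y[i];
    int mu0 = (int)std::floor((xi - u[0]) / du + 0.5);
    int nv0 = (int)std::floor((yi - v[0]) / dv + 0.5);
    int mlo = std::max(0, mu0 - wu), mhi = std::min(M - 1, mu0 + wu);
    int nlo = std::max(0, nv0 - wv), nhi = std::min(N - 1, nv0 + wv);
    if (mlo > mhi || nlo > nhi) continue;
    for (int m = mlo; m <= mhi; ++m) {
      double t = (u[m] - xi) / su;
      au[m - mlo] = cu * std::exp(-0.5 * t * t);
    }
    for (int nn = nlo; nn <= nhi; ++nn) {
      double t = (v[nn] - yi) / sv;
      av[nn - nlo] = cv * std::exp(-0.5 * t * t);
    }
    for (int nn = nlo; nn <= nhi; ++nn) {
      double bv = av[nn - nlo];
      double *col = &q(0, nn);
      for (int m = mlo; m <= mhi; ++m) col[m] += au[m - mlo] * bv;
    }
  }
  for (int j = 0; j < M * N; ++j) q[j] /= n;
  return q;
}

// Gradient of sum_{m,n} C(m,n) * q(m,n) with respect to each x_i, where q is
// the raw Parzen density above:
//   d q(m,n) / d x_i = (1/N) phi_su(u_m - x_i) (u_m - x_i)/su^2 phi_sv(v_n - y_i)
// The coefficient matrix C carries the entropy and normalization chain-rule
// terms, assembled in R.
// [[Rcpp::export]]
NumericVector parzen_joint_grad(NumericVector x, NumericVector y,
                                NumericVector u, NumericVector v,
                                double su, double sv, double cut,
                                NumericMatrix C) {
  const int n = x.size();
  const int M = u.size(), N = v.size();
  const double du = u[1] - u[0], dv = v[1] - v[0];
  const double cu = 1.0 / (su * std::sqrt(2.0 * M_PI));
  const double cv = 1.0 / (sv * std::sqrt(2.0 * M_PI));
  const int wu = (int)std::ceil(cut * su / du);
  const int wv = (int)std::ceil(cut * sv / dv);
  NumericVector g(n);
  std::vector<double> au(2 * wu + 1), av(2 * wv + 1);
  for (int i = 0; i < n; ++i) {
    const double xi = x[i], yi = y[i];
    int mu0 = (int)std::floor((xi - u[0]) / du + 0.5);
    int nv0 = (int)std::floor((yi - v[0]) / dv + 0.5);
    int mlo = std::max(0, mu0 - wu), mhi = std::min(M - 1, mu0 + wu);
    int nlo = std::max(0, nv0 - wv), nhi = std::min(N - 1, nv0 + wv);
    if (mlo > mhi || nlo > nhi) { g[i] = 0.0; continue; }
    for (int m = mlo; m <= mhi; ++m) {
      double d = u[m] - xi;
      double t = d / su;
      au[m - mlo] = cu * std::exp(-0.5 * t * t) * d / (su * su);
    }
    for (int nn = nlo; nn <= nhi; ++nn) {
      double t = (v[nn] - yi) / sv;
      av[nn - nlo] = cv * std::exp(-0.5 * t * t);
    }
    double acc = 0.0;
    for (int nn = nlo; nn <= nhi; ++nn) {
      double bv = av[nn - nlo];
      const double *col = &C(0, nn);
      double s = 0.0;
      for (int m = mlo; m <= mhi; ++m) s += au[m - mlo] * col[m];
      acc += s * bv;
    }
    g[i] = acc / n;
  }
  return g;
}
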