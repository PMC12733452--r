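#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Fused per-channel batch-norm forward on an (m x C) matrix view:
// xhat = (x - mu) * inv, y = xhat * gamma + beta.  Returns y and xhat
// (xhat is reused by the backward pass).
// [[Rcpp::export]]
List cpp_bn_fwd(NumericMatrix X, NumericVector mu, NumericVector inv,
                NumericVector gam, NumericVector bet) {
  const R_xlen_t m = X.nrow();
  const int C = X.ncol();
  NumericMatrix y(m, C), xhat(m, C);
  for (int c = 0; c < C; ++c) {
    const double* px = &X(0, c);
    double* py = &y(0, c);
    double* ph = &xhat(0, c);
    const double mc = mu[c], ic = inv[c], gc = gam[c], bc = bet[c];
    for (R_xlen_t i = 0; i < m; ++i) {
      const double h = (px[i] - mc) * ic;
      ph[i] = h;
      py[i] = h * gc + bc;
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat);
}

// Batch-norm backward (training mode): returns dX, dgamma, dbeta.
// [[Rcpp::export]]
List cpp_bn_bwd(NumericMatrix G, NumericMatrix xhat, NumericVector gam,
                NumericVector inv) {
  const R_xlen_t m = G.nrow();
  const int C = G.ncol();
  NumericMatrix dX(m, C);
  NumericVector dgam(C), dbet(C);
  for (int c = 0; c < C; ++c) {
    const double* pg = &G(0, c);
    const double* ph = &xhat(0, c);
    double s1 = 0, s2 = 0;
    for (R_xlen_t i = 0; i < m; ++i) {
      s1 += pg[i];
      s2 += pg[i] * ph[i];
    }
    dgam[c] = s2;
    dbet[c] = s1;
    const double gc = gam[c] * inv[c];
    const double a1 = s1 / m, a2 = s2 / m;
    double* pd = &dX(0, c);
    for (R_xlen_t i = 0; i < m; ++i) {
      pd[i] = gc * (pg[i] - a1 - ph[i] * a2);
    }
  }
  return List::create(_["dX"] = dX, _["dgam"] = dgam, _["dbet"] = dbet);
}

// y = max(x, 0), preserving dim attributes
// [[Rcpp::export]]
NumericVector cpp_relu(NumericVector x) {
  NumericVector y = clone(x);
  double* p = y.begin();
  const R_xlen_t n = y.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    if (p[i] < 0) p[i] = 0;
  }
  return y;
}

// g * (y > 0), where y is the relu output
// [[Rcpp::export]]
NumericVector cpp_relu_bwd(NumericVector g, NumericVector y) {
  NumericVector d = clone(g);
  double* p = d.begin();
  const double* py = y.begin();
  const R_xlen_t n = d.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    if (py[i] <= 0) p[i] = 0;
  }
  return d;
}

// in-place per-column bias add on a freshly allocated (m x C) matrix
// [[Rcpp::export]]
void cpp_add_bias(NumericMatrix X, NumericVector bias) {
  const R_xlen_t m = X.nrow();
  const int C = X.ncol();
  for (int c = 0; c < C; ++c) {
    double* p = &X(0, c);
    const double b = bias[c];
    for (R_xlen_t i = 0; i < m; ++i) p[i] += b;
  }
}
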