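#include <Rcpp.h>
using namespace Rcpp;

// Durbin-Levinson innovations for a stationary Gaussian series with Toeplitz
// autocovariance gamma[0..n-1], applied jointly to the K columns of Y and to
// an implicit column of ones (for GLS estimation of a constant mean).
//
// Returns:
//   logdet : log-determinant of the covariance matrix
//   Qyy[k] : y_k' Sigma^{-1} y_k
//   Qy1[k] : y_k' Sigma^{-1} 1
//   Q11    : 1' Sigma^{-1} 1
//   ok     : false if the recursion lost positive definiteness
// [[Rcpp::export]]
List dl_quad(NumericVector gamma, NumericMatrix Y) {
  const int n = Y.nrow(), K = Y.ncol();
  if (gamma.size() < n) stop("gamma shorter than the series");
  std::vector<double> phi(n, 0.0), phi_new(n, 0.0);
  std::vector<const double*> ycol(K);
  for (int k = 0; k < K; ++k) ycol[k] = &Y(0, k);
  const double* g = &gamma[0];
  NumericVector Qyy(K), Qy1(K);
  double Q11 = 0.0, logdet = 0.0;
  double v = g[0];
  if (v <= 0.0) return List::create(_["ok"] = false);
  logdet = std::log(v);
  double phisum = 0.0;  // running sum of prediction coefficients
  for (int k = 0; k < K; ++k) {
    const double e = ycol[k][0];
    Qyy[k] += e * e / v;
    Qy1[k] += e / v;
  }
  Q11 += 1.0 / v;
  std::vector<double> ework(K);
  for (int t = 1; t < n; ++t) {
    // reflection coefficient from the previous-step phi
    double num = g[t];
    {
      const double* p = phi.data();
      for (int j = 1; j < t; ++j) num -= p[j - 1] * g[t - j];
    }
    const double phitt = num / v;
    // fused: update phi and accumulate innovations with the new phi
    for (int k = 0; k < K; ++k) ework[k] = ycol[k][t];
    {
      const double* p = phi.data();
      double* pn = phi_new.data();
      for (int j = 1; j < t; ++j) {
        const double pj = p[j - 1] - phitt * p[t - 1 - j];
        pn[j - 1] = pj;
        for (int k = 0; k < K; ++k) ework[k] -= pj * ycol[k][t - j];
      }
      pn[t - 1] = phitt;
      for (int k = 0; k < K; ++k) ework[k] -= phitt * ycol[k][0];
    }
    phi.swap(phi_new);
    phisum = phisum * (1.0 - phitt) + phitt;
    v *= (1.0 - phitt * phitt);
    if (v <= 0.0 || !R_finite(v))
      return List::create(_["ok"] = false);
    logdet += std::log(v);
    const double e1 = 1.0 - phisum;
    for (int k = 0; k < K; ++k) {
      Qyy[k] += ework[k] * ework[k] / v;
      Qy1[k] += ework[k] * e1 / v;
    }
    Q11 += e1 * e1 / v;
  }
  return List::create(_["ok"] = true, _["logdet"] = logdet,
                      _["Qyy"] = Qyy, _["Qy1"] = Qy1, _["Q11"] = Q11);
}
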