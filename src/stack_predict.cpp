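#include <Rcpp.h>
using namespace Rcpp;

// Joint posterior means (and input gradients) of a stack of ARD-SE GP
// emulators sharing one training-input matrix.  This is the inner loop of
// gradient-based MCMC through the emulator, so it is kept in C++.
//
// X:       n x D standardized training inputs
// alpha:   n x m cached K^-1 y per output
// invlam2: D x m per-output inverse squared lengthscales
// sigf2:   m amplitudes, y_mean/y_sd: m output standardizations
// center/scale: D input standardization
// u:       D raw emulator inputs (after any log transform)
// [[Rcpp::export]]
List stack_predict_cpp(NumericMatrix X, NumericMatrix alpha,
                       NumericMatrix invlam2, NumericVector sigf2,
                       NumericVector y_mean, NumericVector y_sd,
                       NumericVector center, NumericVector scale,
                       NumericVector u, bool grad) {
  const int n = X.nrow(), D = X.ncol(), m = alpha.ncol();
  std::vector<double> z(D);
  for (int k = 0; k < D; ++k) z[k] = (u[k] - center[k]) / scale[k];

  NumericVector mean(m);
  NumericMatrix G(D, m);
  // per-point differences reused across outputs
  std::vector<double> A(n * D);
  for (int k = 0; k < D; ++k) {
    const double zk = z[k];
    for (int i = 0; i < n; ++i) A[k * n + i] = X(i, k) - zk;
  }
  std::vector<double> w(n);
  for (int j = 0; j < m; ++j) {
    double mw = 0.0;
    for (int i = 0; i < n; ++i) {
      double q = 0.0;
      for (int k = 0; k < D; ++k) {
        const double d = A[k * n + i];
        q += d * d * invlam2(k, j);
      }
      const double wij = std::exp(-0.5 * q) * alpha(i, j);
      w[i] = wij;
      mw += wij;
    }
    mean[j] = y_mean[j] + y_sd[j] * sigf2[j] * mw;
    if (grad) {
      for (int k = 0; k < D; ++k) {
        double g = 0.0;
        const double* Ak = &A[k * n];
        for (int i = 0; i < n; ++i) g += Ak[i] * w[i];
        G(k, j) = y_sd[j] * sigf2[j] * invlam2(k, j) * g / scale[k];
      }
    }
  }
  if (grad) return List::create(_["mean"] = mean, _["grad"] = G);
  return List::create(_["mean"] = mean);
}
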