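#include <Rcpp.h>
using namespace Rcpp;

// Sequential XOM adaptation. At step t a sampling vector S_t (row t of S,
// drawn by the caller from the uniform structure hypothesis) selects the
// best-match input X' via argmin_i ||S_t - Y_i||; every output vector is
// then moved toward S_t with strength given by the learning rate eps_t and
// a Gaussian cooperativity in input space:
//   Y_i <- Y_i + eps_t * exp(-||X_i - X'||^2 / (2 sigma_t^2)) * (S_t - Y_i).
// D2x holds the squared input-space distances ||X_i - X_j||^2.
// [[Rcpp::export(name = ".xom_adapt_cpp")]]
NumericMatrix xom_adapt_cpp(NumericMatrix Y0, NumericMatrix S,
                            NumericMatrix D2x, NumericVector sigma,
                            NumericVector eps) {
  const int n = Y0.nrow(), d = Y0.ncol(), T = S.nrow();
  NumericMatrix Y = clone(Y0);
  for (int t = 0; t < T; ++t) {
    // best match: output vector closest to the sampling vector
    int b = 0;
    double best = R_PosInf;
    for (int i = 0; i < n; ++i) {
      double acc = 0.0;
      for (int k = 0; k < d; ++k) {
        const double diff = S(t, k) - Y(i, k);
        acc += diff * diff;
      }
      if (acc < best) { best = acc; b = i; }
    }
    const double inv2s2 = 1.0 / (2.0 * sigma[t] * sigma[t]);
    for (int i = 0; i < n; ++i) {
      const double h = std::exp(-D2x(i, b) * inv2s2);
      const double step = eps[t] * h;
      for (int k = 0; k < d; ++k) {
        Y(i, k) += step * (S(t, k) - Y(i, k));
      }
    }
  }
  return Y;
}
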