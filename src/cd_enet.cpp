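#include <Rcpp.h>
using namespace Rcpp;

// Cyclic coordinate descent for the elastic-net penalized, observation-
// weighted least-squares problem that forms the inner loop of IRLS:
//
//   min_{b0,b}  (1/(2N)) sum_i v_i (z_i - b0 - x_i'b)^2
//               + lambda * ( alpha * ||b||_1 + (1-alpha)/2 * ||b||_2^2 )
//
// N is the number of rows; the intercept is unpenalized. Residuals are
// updated incrementally, so each full sweep is O(N * m).
// [[Rcpp::export]]
List cd_enet(NumericMatrix X, NumericVector z, NumericVector v,
             double lambda, double alpha, double b0, NumericVector b,
             bool intercept, double tol, int max_sweeps) {
  const int n = X.nrow(), m = X.ncol();
  const double N = static_cast<double>(n);
  NumericVector beta = clone(b);
  NumericVector r(n);
  for (int i = 0; i < n; ++i) {
    double fit = b0;
    for (int j = 0; j < m; ++j) fit += X(i, j) * beta[j];
    r[i] = z[i] - fit;
  }
  double sv = 0.0;
  for (int i = 0; i < n; ++i) sv += v[i];
  // weighted column sums of squares, scaled by 1/N
  NumericVector xv2(m);
  for (int j = 0; j < m; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += v[i] * X(i, j) * X(i, j);
    xv2[j] = s / N;
  }
  const double l1 = lambda * alpha;
  const double l2 = lambda * (1.0 - alpha);
  int sweep;
  for (sweep = 0; sweep < max_sweeps; ++sweep) {
    double maxdelta = 0.0;
    if (intercept && sv > 0.0) {
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += v[i] * r[i];
      const double d = s / sv;
      b0 += d;
      for (int i = 0; i < n; ++i) r[i] -= d;
      if (std::fabs(d) > maxdelta) maxdelta = std::fabs(d);
    }
    for (int j = 0; j < m; ++j) {
      if (xv2[j] <= 0.0) continue;  // all-zero (or zero-weight) column
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += v[i] * X(i, j) * r[i];
      const double u = s / N + xv2[j] * beta[j];
      double bj = 0.0;
      if (u > l1)       bj = (u - l1) / (xv2[j] + l2);
      else if (u < -l1) bj = (u + l1) / (xv2[j] + l2);
      const double d = bj - beta[j];
      if (d != 0.0) {
        for (int i = 0; i < n; ++i) r[i] -= X(i, j) * d;
        beta[j] = bj;
        if (std::fabs(d) > maxdelta) maxdelta = std::fabs(d);
      }
    }
    if (maxdelta < tol) { ++sweep; break; }
  }
  return List::create(_["b0"] = b0, _["b"] = beta, _["sweeps"] = sweep);
}
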