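#include <Rcpp.h>
using namespace Rcpp;

// Thomas algorithm for a tridiagonal system.
// lower: subdiagonal (length n-1), diag: length n, upper: superdiagonal
// (length n-1), rhs: length n. No pivoting; the Newton systems solved here
// are strictly diagonally dominant.
// [[Rcpp::export]]
NumericVector solve_tridiag(NumericVector lower, NumericVector diag,
                            NumericVector upper, NumericVector rhs) {
  const int n = diag.size();
  if (lower.size() != n - 1 || upper.size() != n - 1 || rhs.size() != n)
    stop("inconsistent tridiagonal system dimensions");
  std::vector<double> cp(n), dp(n);
  cp[0] = upper.size() ? upper[0] / diag[0] : 0.0;
  dp[0] = rhs[0] / diag[0];
  for (int i = 1; i < n; ++i) {
    double m = diag[i] - lower[i - 1] * cp[i - 1];
    cp[i] = (i < n - 1) ? upper[i] / m : 0.0;
    dp[i] = (rhs[i] - lower[i - 1] * dp[i - 1]) / m;
  }
  NumericVector x(n);
  x[n - 1] = dp[n - 1];
  for (int i = n - 2; i >= 0; --i) x[i] = dp[i] - cp[i] * x[i + 1];
  return x;
}
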