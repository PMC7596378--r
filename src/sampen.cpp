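#include <Rcpp.h>
using namespace Rcpp;

// Template-match counts for sample entropy: number of ordered pairs
// (i < j), i, j in 0..N-m-1, whose templates of length m (count B) and
// m+1 (count A) match under Chebyshev distance <= r. Self-matches are
// excluded by construction.
// [[Rcpp::export]]
NumericVector sampen_counts(NumericVector x, int m, double r) {
  const int n = x.size();
  const int nt = n - m; // number of templates of length m and m+1
  double A = 0.0, B = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      double d = 0.0;
      bool ok = true;
      for (int k = 0; k < m; ++k) {
        d = std::fabs(x[i + k] - x[j + k]);
        if (d > r) { ok = false; break; }
      }
      if (!ok) continue;
      B += 1.0;
      if (i + m < n && j + m < n && std::fabs(x[i + m] - x[j + m]) <= r) {
        A += 1.0;
      }
    }
  }
  return NumericVector::create(A, B);
}
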