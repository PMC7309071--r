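#include <Rcpp.h>
using namespace Rcpp;

// Sample entropy template-match counts (Richman & Moorman convention):
// B = number of pairs of length-m templates within Chebyshev distance r,
// A = number of those whose length-(m+1) extensions also match.
// Self-matches are excluded; templates run over the first n-m points so
// every counted template has an extension.
// [[Rcpp::export]]
NumericVector sampen_counts_cpp(NumericVector x, int m, double r) {
  const int n = x.size();
  double A = 0.0, B = 0.0;
  for (int i = 0; i < n - m; ++i) {
    for (int j = i + 1; j < n - m; ++j) {
      bool match = true;
      for (int k = 0; k < m; ++k) {
        if (std::fabs(x[i + k] - x[j + k]) > r) { match = false; break; }
      }
      if (match) {
        B += 1.0;
        if (std::fabs(x[i + m] - x[j + m]) <= r) A += 1.0;
      }
    }
  }
  return NumericVector::create(_["A"] = A, _["B"] = B);
}
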