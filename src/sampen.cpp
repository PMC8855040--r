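#include <Rcpp.h>
#include <algorithm>
#include <numeric>
using namespace Rcpp;

// Template match counts for sample entropy.
// B: pairs (i < j) of m-length templates with Chebyshev distance < r,
// A: those whose (m+1)-th coordinates also differ by < r.
// Templates are taken at starts 0..N-m-1 so every m-template has an
// (m+1)-length extension; self-matches excluded by i < j.
// Implementation: candidate pairs are pruned by sorting on the first
// coordinate (a pair can only match if the first coordinates are within r),
// then checked exactly; counts are identical to the naive double loop.
// [[Rcpp::export]]
List sampen_counts(NumericVector x, int m, double r) {
  int n = x.size();
  int nt = n - m; // number of templates with an extension
  if (nt < 2) stop("series too short for embedding dimension m");
  std::vector<int> ord(nt);
  std::iota(ord.begin(), ord.end(), 0);
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return x[a] < x[b]; });
  double A = 0.0, B = 0.0;
  for (int a = 0; a < nt - 1; ++a) {
    int i = ord[a];
    for (int b = a + 1; b < nt; ++b) {
      int j = ord[b];
      if (x[j] - x[i] >= r) break; // sorted: no further first-coord matches
      bool match = true;
      for (int k = 1; k < m; ++k) {
        double d = x[i + k] - x[j + k];
        if (d < 0) d = -d;
        if (d >= r) { match = false; break; }
      }
      if (match) {
        B += 1.0;
        double d = x[i + m] - x[j + m];
        if (d < 0) d = -d;
        if (d < r) A += 1.0;
      }
    }
  }
  return List::create(Named("A") = A, Named("B") = B);
}
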