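#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Global (end-to-end) alignment with linear gap penalty and a fixed,
// documented traceback preference (diagonal, then up = gap in b, then
// left = gap in a) so that the reported identity is reproducible even
// when co-optimal alignments exist. Terminal gaps are penalized.
// 'N' never counts as a match, not even against another 'N'.
// [[Rcpp::export]]
List nw_align_cpp(std::string a, std::string b,
                  double match, double mismatch, double gap) {
  const int n = (int) a.size();
  const int m = (int) b.size();
  NumericMatrix H(n + 1, m + 1);
  IntegerMatrix P(n + 1, m + 1); // 0 = diag, 1 = up, 2 = left

  for (int i = 1; i <= n; ++i) { H(i, 0) = i * gap; P(i, 0) = 1; }
  for (int j = 1; j <= m; ++j) { H(0, j) = j * gap; P(0, j) = 2; }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const bool is_match = (a[i - 1] == b[j - 1]) && (a[i - 1] != 'N');
      const double d = H(i - 1, j - 1) + (is_match ? match : mismatch);
      const double u = H(i - 1, j) + gap;
      const double l = H(i, j - 1) + gap;
      double best = d; int ptr = 0;
      if (u > best) { best = u; ptr = 1; }
      if (l > best) { best = l; ptr = 2; }
      H(i, j) = best; P(i, j) = ptr;
    }
  }

  std::string A, B;
  A.reserve(n + m); B.reserve(n + m);
  int i = n, j = m, cols = 0, matches = 0;
  while (i > 0 || j > 0) {
    int p = (i == 0) ? 2 : (j == 0) ? 1 : P(i, j);
    if (p == 0) {
      A.push_back(a[i - 1]); B.push_back(b[j - 1]);
      if (a[i - 1] == b[j - 1] && a[i - 1] != 'N') ++matches;
      --i; --j;
    } else if (p == 1) {
      A.push_back(a[i - 1]); B.push_back('-'); --i;
    } else {
      A.push_back('-'); B.push_back(b[j - 1]); --j;
    }
    ++cols;
  }
  std::reverse(A.begin(), A.end());
  std::reverse(B.begin(), B.end());

  return List::create(
    _["score"] = H(n, m),
    _["aligned_a"] = A,
    _["aligned_b"] = B,
    _["columns"] = cols,
    _["matches"] = matches,
    _["identity"] = cols > 0 ? 100.0 * matches / cols : NA_REAL);
}
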