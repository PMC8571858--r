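#include <Rcpp.h>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with linear gap penalty.
// Traceback ties are broken up (gap in b) > diagonal > left (gap in a), so
// the result is fully deterministic and unmatched reference suffixes stay
// contiguous trailing gaps (a target lacking a region maps it to an empty
// interval instead of smearing stray residues into it).
// [[Rcpp::export(name = ".nw_align")]]
List nw_align(std::string a, std::string b,
              double match, double mismatch, double gap) {
  const int n = a.size(), m = b.size();
  NumericMatrix M(n + 1, m + 1);
  for (int i = 1; i <= n; ++i) M(i, 0) = i * gap;
  for (int j = 1; j <= m; ++j) M(0, j) = j * gap;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      double d = M(i - 1, j - 1) + s;
      double u = M(i - 1, j) + gap;
      double l = M(i, j - 1) + gap;
      M(i, j) = std::max(d, std::max(u, l));
    }
  }
  std::string ra, rb;
  ra.reserve(n + m); rb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (i > 0 && M(i, j) == M(i - 1, j) + gap) {
      ra += a[i - 1]; rb += '-'; --i; continue;
    }
    if (i > 0 && j > 0) {
      double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      if (M(i, j) == M(i - 1, j - 1) + s) {
        ra += a[i - 1]; rb += b[j - 1]; --i; --j; continue;
      }
    }
    ra += '-'; rb += b[j - 1]; --j;
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["aligned_a"] = ra, _["aligned_b"] = rb,
                      _["score"] = M(n, m));
}
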