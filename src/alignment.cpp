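#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Local alignment of two integer-coded token sequences under the scheme
// match = +1 (identical codes only), mismatch forbidden, gap = -2.
// Because a mismatched column can never occur, the "mismatch" transition is a
// disallowed move rather than a large negative score (no overflow concerns).
//
// `forbid` marks (i,j) cells whose diagonal (match) transition is banned; it
// implements Waterman-Eggert style suboptimal enumeration: after reporting an
// alignment, its matched cells are banned and the DP is recomputed.

struct Alignment {
  int score;
  std::vector<int> ai; // 1-based index into A, or NA
  std::vector<int> bi; // 1-based index into B, or NA
};

static Alignment sw_once(const IntegerVector& a, const IntegerVector& b,
                         const std::vector<char>& forbid,
                         int match, int gap) {
  const int n = a.size(), m = b.size();
  std::vector<int> H((size_t)(n + 1) * (m + 1), 0);
  std::vector<char> P((size_t)(n + 1) * (m + 1), 0); // 0 stop, 1 diag, 2 up, 3 left
  const size_t W = (size_t)m + 1;
  int best = 0, bi = -1, bj = -1;
  for (int i = 1; i <= n; ++i) {
    const size_t row = (size_t)i * W, prow = (size_t)(i - 1) * W;
    for (int j = 1; j <= m; ++j) {
      int h = 0; char p = 0;
      if (a[i - 1] == b[j - 1] && !forbid[(size_t)(i - 1) * m + (j - 1)]) {
        const int d = H[prow + j - 1] + match;
        if (d > h) { h = d; p = 1; }
      }
      const int u = H[prow + j] + gap;   // gap in B (consumes A[i])
      if (u > h) { h = u; p = 2; }
      const int l = H[row + j - 1] + gap; // gap in A (consumes B[j])
      if (l > h) { h = l; p = 3; }
      H[row + j] = h; P[row + j] = p;
      // strictly-greater keeps the lexicographically smallest (i, j) maximum
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  Alignment out; out.score = best;
  if (best <= 0) return out;
  int i = bi, j = bj;
  std::vector<int> rai, rbi;
  while (i > 0 && j > 0) {
    const char p = P[(size_t)i * W + j];
    if (p == 0) break;
    if (p == 1)      { rai.push_back(i); rbi.push_back(j); --i; --j; }
    else if (p == 2) { rai.push_back(i); rbi.push_back(NA_INTEGER); --i; }
    else             { rai.push_back(NA_INTEGER); rbi.push_back(j); --j; }
  }
  out.ai.assign(rai.rbegin(), rai.rend());
  out.bi.assign(rbi.rbegin(), rbi.rend());
  return out;
}

static List wrap_alignment(const Alignment& al) {
  return List::create(_["score"] = al.score,
                      _["posA"] = IntegerVector(al.ai.begin(), al.ai.end()),
                      _["posB"] = IntegerVector(al.bi.begin(), al.bi.end()));
}

// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(IntegerVector a, IntegerVector b, int match = 1, int gap = -2) {
  std::vector<char> forbid((size_t)a.size() * b.size(), 0);
  return wrap_alignment(sw_once(a, b, forbid, match, gap));
}

// [[Rcpp::export(name = ".sw_suboptimal_cpp")]]
List sw_suboptimal_cpp(IntegerVector a, IntegerVector b, int min_matches,
                       int max_segments, int match = 1, int gap = -2) {
  const int n = a.size(), m = b.size();
  std::vector<char> forbid((size_t)n * m, 0);
  List out;
  for (int k = 0; k < max_segments; ++k) {
    Alignment al = sw_once(a, b, forbid, match, gap);
    if (al.score <= 0) break;
    int nmatch = 0;
    for (size_t c = 0; c < al.ai.size(); ++c)
      if (al.ai[c] != NA_INTEGER && al.bi[c] != NA_INTEGER) ++nmatch;
    if (nmatch < min_matches) break; // enumeration stops at the first short alignment
    out.push_back(wrap_alignment(al));
    for (size_t c = 0; c < al.ai.size(); ++c)
      if (al.ai[c] != NA_INTEGER && al.bi[c] != NA_INTEGER)
        forbid[(size_t)(al.ai[c] - 1) * m + (al.bi[c] - 1)] = 1;
  }
  return out;
}
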