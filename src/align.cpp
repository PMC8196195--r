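#include <Rcpp.h>
#include <string>
#include <vector>
#include <climits>
using namespace Rcpp;

// Alignment kernels shared by guide-bound classification and the read end
// scan. Sequences arrive as plain uppercase character strings; 'N' never
// matches anything (including another 'N').

static inline bool base_match(char a, char b) {
  return a == b && a != 'N';
}

// Semi-global placement of a short guide inside an element: the guide is
// aligned end-to-end, the element contributes a free prefix and suffix.
// Returns c(edit, matches):
//   edit    -- minimum unit-cost edit distance (substitutions + indels)
//   matches -- number of aligned identical bases in the best-scoring
//              placement under match +1 / mismatch -1 / gap -1, maximised
//              over all optimal-score alignments (lexicographic DP), so the
//              value is well defined.
// [[Rcpp::export]]
IntegerVector cpp_guide_match(std::string guide, std::string element) {
  const int m = (int) guide.size(), n = (int) element.size();
  if (m == 0) stop("empty guide");
  if (n == 0) return IntegerVector::create(m, 0);

  std::vector<int> dPrev(n + 1), dCur(n + 1);
  std::vector<int> sPrev(n + 1), sCur(n + 1);
  std::vector<int> mPrev(n + 1), mCur(n + 1);
  for (int j = 0; j <= n; ++j) { dPrev[j] = 0; sPrev[j] = 0; mPrev[j] = 0; }

  for (int i = 1; i <= m; ++i) {
    dCur[0] = i;
    sCur[0] = -i;
    mCur[0] = 0;
    const char g = guide[i - 1];
    for (int j = 1; j <= n; ++j) {
      const bool eq = base_match(g, element[j - 1]);
      // edit distance
      int d = dPrev[j - 1] + (eq ? 0 : 1);
      if (dPrev[j] + 1 < d) d = dPrev[j] + 1;
      if (dCur[j - 1] + 1 < d) d = dCur[j - 1] + 1;
      dCur[j] = d;
      // score with lexicographic (score, matches)
      int sDiag = sPrev[j - 1] + (eq ? 1 : -1), mDiag = mPrev[j - 1] + (eq ? 1 : 0);
      int sUp   = sPrev[j] - 1,                 mUp   = mPrev[j];
      int sLeft = sCur[j - 1] - 1,              mLeft = mCur[j - 1];
      int s = sDiag, mm = mDiag;
      if (sUp > s || (sUp == s && mUp > mm))     { s = sUp;   mm = mUp; }
      if (sLeft > s || (sLeft == s && mLeft > mm)) { s = sLeft; mm = mLeft; }
      sCur[j] = s; mCur[j] = mm;
    }
    std::swap(dPrev, dCur); std::swap(sPrev, sCur); std::swap(mPrev, mCur);
  }

  int bestEdit = INT_MAX, bestS = INT_MIN, bestM = 0;
  for (int j = 0; j <= n; ++j) {
    if (dPrev[j] < bestEdit) bestEdit = dPrev[j];
    if (sPrev[j] > bestS || (sPrev[j] == bestS && mPrev[j] > bestM)) {
      bestS = sPrev[j]; bestM = mPrev[j];
    }
  }
  return IntegerVector::create(bestEdit, bestM);
}

// Smith-Waterman local alignment score with affine gaps (Gotoh, score only).
// A gap of length L costs gap_open + L * gap_ext, matching the
// Biostrings::pairwiseAlignment convention used as the test oracle.
// [[Rcpp::export]]
double cpp_local_score(std::string a, std::string b,
                       double match = 2.0, double mismatch = -3.0,
                       double gap_open = 5.0, double gap_ext = 2.0) {
  const int m = (int) a.size(), n = (int) b.size();
  if (m == 0 || n == 0) return 0.0;
  const double NEG = -1e18;
  std::vector<double> hPrev(n + 1, 0.0), hCur(n + 1, 0.0);
  std::vector<double> ePrev(n + 1, NEG), eCur(n + 1, NEG); // gap in b (vertical)
  double best = 0.0;
  for (int i = 1; i <= m; ++i) {
    hCur[0] = 0.0; eCur[0] = NEG;
    double f = NEG; // gap in a (horizontal), row-local
    for (int j = 1; j <= n; ++j) {
      eCur[j] = std::max(hPrev[j] - gap_open - gap_ext, ePrev[j] - gap_ext);
      f = std::max(hCur[j - 1] - gap_open - gap_ext, f - gap_ext);
      double diag = hPrev[j - 1] + (base_match(a[i - 1], b[j - 1]) ? match : mismatch);
      double h = std::max(std::max(diag, 0.0), std::max(eCur[j], f));
      hCur[j] = h;
      if (h > best) best = h;
    }
    std::swap(hPrev, hCur); std::swap(ePrev, eCur);
  }
  return best;
}
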