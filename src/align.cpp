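#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Global pairwise alignment (Needleman-Wunsch with affine gaps, Gotoh
// three-state recursion). Scores: substitution matrix lookup; a gap of
// length L costs gap_open + L * gap_extend (both penalties <= 0).
//
// Traceback is deterministic: on score ties the diagonal (match) state is
// preferred over the vertical (gap in the second sequence) state, which is
// preferred over the horizontal state, both when choosing the final state
// and when choosing each predecessor.
//
// a, b: 0-based indices into the substitution matrix rows/columns.
// Returns an alignment as two integer vectors of equal length holding
// 1-based residue indices, 0 marking a gap, plus the optimal score.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// [[Rcpp::export]]
List nw_align(IntegerVector a, IntegerVector b, NumericMatrix sub,
              double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  const double go = gap_open + gap_extend; // cost of the first gap residue
  const double ge = gap_extend;

  // state codes: 0 = M (diagonal), 1 = Ix (up, gap in b), 2 = Iy (left)
  std::vector<double> M((n + 1) * (m + 1), NEG_INF);
  std::vector<double> Ix((n + 1) * (m + 1), NEG_INF);
  std::vector<double> Iy((n + 1) * (m + 1), NEG_INF);
  std::vector<signed char> ptrM((n + 1) * (m + 1), -1);
  std::vector<signed char> ptrIx((n + 1) * (m + 1), -1);
  std::vector<signed char> ptrIy((n + 1) * (m + 1), -1);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    Ix[at(i, 0)] = go + ge * (i - 1);
    ptrIx[at(i, 0)] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    Iy[at(0, j)] = go + ge * (j - 1);
    ptrIy[at(0, j)] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const double s = sub(a[i - 1], b[j - 1]);
      // M from best of the three states at (i-1, j-1); prefer M > Ix > Iy
      {
        double best = M[at(i - 1, j - 1)];
        signed char p = 0;
        if (Ix[at(i - 1, j - 1)] > best) { best = Ix[at(i - 1, j - 1)]; p = 1; }
        if (Iy[at(i - 1, j - 1)] > best) { best = Iy[at(i - 1, j - 1)]; p = 2; }
        if (best > NEG_INF) { M[at(i, j)] = best + s; ptrM[at(i, j)] = p; }
      }
      // Ix: consume a[i-1] against a gap; open from M/Iy or extend Ix
      {
        double open = std::max(M[at(i - 1, j)], Iy[at(i - 1, j)]) + go;
        signed char po = (M[at(i - 1, j)] >= Iy[at(i - 1, j)]) ? 0 : 2;
        double ext = Ix[at(i - 1, j)] + ge;
        if (open >= ext) { Ix[at(i, j)] = open; ptrIx[at(i, j)] = po; }
        else             { Ix[at(i, j)] = ext;  ptrIx[at(i, j)] = 1; }
      }
      // Iy: consume b[j-1] against a gap
      {
        double open = std::max(M[at(i, j - 1)], Ix[at(i, j - 1)]) + go;
        signed char po = (M[at(i, j - 1)] >= Ix[at(i, j - 1)]) ? 0 : 1;
        double ext = Iy[at(i, j - 1)] + ge;
        if (open >= ext) { Iy[at(i, j)] = open; ptrIy[at(i, j)] = po; }
        else             { Iy[at(i, j)] = ext;  ptrIy[at(i, j)] = 2; }
      }
    }
  }

  // final state: prefer M > Ix > Iy on ties
  int state = 0;
  double best = M[at(n, m)];
  if (Ix[at(n, m)] > best) { best = Ix[at(n, m)]; state = 1; }
  if (Iy[at(n, m)] > best) { best = Iy[at(n, m)]; state = 2; }

  std::vector<int> ra, rb;
  ra.reserve(n + m); rb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      signed char p = ptrM[at(i, j)];
      ra.push_back(i); rb.push_back(j);
      --i; --j;
      state = p;
    } else if (state == 1) {
      signed char p = ptrIx[at(i, j)];
      ra.push_back(i); rb.push_back(0);
      --i;
      state = p;
    } else {
      signed char p = ptrIy[at(i, j)];
      ra.push_back(0); rb.push_back(j);
      --j;
      state = p;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());

  return List::create(_["a_index"] = IntegerVector(ra.begin(), ra.end()),
                      _["b_index"] = IntegerVector(rb.begin(), rb.end()),
                      _["score"] = best);
}
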