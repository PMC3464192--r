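#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with affine gaps, Gotoh three-state
// DP. A gap of length L costs gap_open + (L - 1) * gap_extend (both
// penalties are negative). Tie-breaking is deterministic: on equal scores
// the match (diagonal) state is preferred over a gap in b (up), which is
// preferred over a gap in a (left); gap extension is preferred over
// re-opening. Returns the optimal score and the edit path as a string of
// operations (M = aligned pair, X = residue of a against a gap, Y =
// residue of b against a gap); the caller reconstructs aligned strings.
//
// a, b: 0-based integer codes into the score matrix rows/columns.
// [[Rcpp::export(name = ".align_affine")]]
List align_affine(IntegerVector a, IntegerVector b, IntegerMatrix score,
                  double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  const double NEG = -std::numeric_limits<double>::infinity();

  std::vector<std::vector<double>> M(n + 1, std::vector<double>(m + 1, NEG));
  std::vector<std::vector<double>> X(n + 1, std::vector<double>(m + 1, NEG));
  std::vector<std::vector<double>> Y(n + 1, std::vector<double>(m + 1, NEG));
  // predecessor state per cell: 0 = M, 1 = X (up), 2 = Y (left)
  std::vector<std::vector<signed char>> tM(n + 1, std::vector<signed char>(m + 1, -1));
  std::vector<std::vector<signed char>> tX(n + 1, std::vector<signed char>(m + 1, -1));
  std::vector<std::vector<signed char>> tY(n + 1, std::vector<signed char>(m + 1, -1));

  M[0][0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[i][0] = gap_open + (i - 1) * gap_extend;
    tX[i][0] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[0][j] = gap_open + (j - 1) * gap_extend;
    tY[0][j] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // match state: priority M > X > Y on ties
      double best = M[i - 1][j - 1];
      signed char from = 0;
      if (X[i - 1][j - 1] > best) { best = X[i - 1][j - 1]; from = 1; }
      if (Y[i - 1][j - 1] > best) { best = Y[i - 1][j - 1]; from = 2; }
      M[i][j] = best + score(a[i - 1], b[j - 1]);
      tM[i][j] = from;
      // gap in b (consume a[i]): open from M or Y, extend from X
      double xo = std::max(M[i - 1][j], Y[i - 1][j]) + gap_open;
      double xe = X[i - 1][j] + gap_extend;
      if (xe >= xo) { X[i][j] = xe; tX[i][j] = 1; }
      else { X[i][j] = xo; tX[i][j] = (M[i - 1][j] >= Y[i - 1][j]) ? 0 : 2; }
      // gap in a (consume b[j])
      double yo = std::max(M[i][j - 1], X[i][j - 1]) + gap_open;
      double ye = Y[i][j - 1] + gap_extend;
      if (ye >= yo) { Y[i][j] = ye; tY[i][j] = 2; }
      else { Y[i][j] = yo; tY[i][j] = (M[i][j - 1] >= X[i][j - 1]) ? 0 : 1; }
    }
  }

  double best = M[n][m];
  int state = 0;
  if (X[n][m] > best) { best = X[n][m]; state = 1; }
  if (Y[n][m] > best) { best = Y[n][m]; state = 2; }

  std::string ops;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      ops.push_back('M');
      state = tM[i][j];
      --i; --j;
    } else if (state == 1) {
      ops.push_back('X');
      state = tX[i][j];
      --i;
    } else {
      ops.push_back('Y');
      state = tY[i][j];
      --j;
    }
  }
  std::reverse(ops.begin(), ops.end());
  return List::create(_["score"] = best, _["ops"] = ops);
}
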