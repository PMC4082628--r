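#include <Rcpp.h>
using namespace Rcpp;

// Global profile-profile alignment with affine gaps (Gotoh) over a
// precomputed column-score matrix M (rows = columns of profile A, cols =
// columns of profile B).  A gap of length k costs gap_open + (k-1)*gap_ext.
// Tie-break order: match > gap-in-B > gap-in-A (deterministic).
// Returns 1-based column indices per alignment column, 0 denoting a gap.
// [[Rcpp::export]]
List align_profiles_cpp(NumericMatrix M, double gap_open, double gap_ext) {
  const int n = M.nrow(), m = M.ncol();
  const double NEG = -1e30;
  NumericMatrix S(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  // traceback state per matrix: 0 = from S, 1 = from X, 2 = from Y
  IntegerMatrix tS(n + 1, m + 1), tX(n + 1, m + 1), tY(n + 1, m + 1);

  S(0, 0) = 0.0; X(0, 0) = NEG; Y(0, 0) = NEG;
  for (int i = 1; i <= n; ++i) {
    S(i, 0) = NEG; Y(i, 0) = NEG;
    X(i, 0) = -(gap_open + (i - 1) * gap_ext);
    tX(i, 0) = 1;
  }
  for (int j = 1; j <= m; ++j) {
    S(0, j) = NEG; X(0, j) = NEG;
    Y(0, j) = -(gap_open + (j - 1) * gap_ext);
    tY(0, j) = 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // S
      double best = S(i - 1, j - 1); int arg = 0;
      if (X(i - 1, j - 1) > best) { best = X(i - 1, j - 1); arg = 1; }
      if (Y(i - 1, j - 1) > best) { best = Y(i - 1, j - 1); arg = 2; }
      S(i, j) = M(i - 1, j - 1) + best;
      tS(i, j) = arg;
      // X: gap in B, consume a column of A
      best = S(i - 1, j) - gap_open; arg = 0;
      if (X(i - 1, j) - gap_ext > best) { best = X(i - 1, j) - gap_ext; arg = 1; }
      if (Y(i - 1, j) - gap_open > best) { best = Y(i - 1, j) - gap_open; arg = 2; }
      X(i, j) = best; tX(i, j) = arg;
      // Y: gap in A, consume a column of B
      best = S(i, j - 1) - gap_open; arg = 0;
      if (X(i, j - 1) - gap_open > best) { best = X(i, j - 1) - gap_open; arg = 1; }
      if (Y(i, j - 1) - gap_ext > best) { best = Y(i, j - 1) - gap_ext; arg = 2; }
      Y(i, j) = best; tY(i, j) = arg;
    }
  }

  int state = 0;
  double fin = S(n, m);
  if (X(n, m) > fin) { fin = X(n, m); state = 1; }
  if (Y(n, m) > fin) { fin = Y(n, m); state = 2; }

  std::vector<int> ai, bi;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      int prev = tS(i, j);
      ai.push_back(i); bi.push_back(j);
      --i; --j;
      state = prev;
    } else if (state == 1) {
      int prev = tX(i, j);
      ai.push_back(i); bi.push_back(0);
      --i;
      state = prev;
    } else {
      int prev = tY(i, j);
      ai.push_back(0); bi.push_back(j);
      --j;
      state = prev;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());
  return List::create(_["a"] = wrap(ai), _["b"] = wrap(bi),
                      _["score"] = fin);
}
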