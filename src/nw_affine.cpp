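#include <Rcpp.h>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with affine gap costs over a
// precomputed position-score matrix S, where S(i, j) is the score of
// pairing position i of sequence/profile A with position j of B.
// Working on a position-score matrix lets the same routine serve both
// sequence-sequence alignment (S = substitution-matrix lookups) and
// profile-profile alignment (S = expected substitution score between
// column residue distributions).
//
// A gap of length L costs gap_open + (L - 1) * gap_extend; terminal gaps
// are penalized like internal ones.  Traceback ties are broken by
// preferring the diagonal move, then up (gap in B), then left (gap in A),
// so the alignment is deterministic across platforms.
//
// Returns list(score, a_idx, b_idx): per output column the 1-based source
// position in A resp. B, with 0 marking a gap in that row.

static const double NEG_INF = -1e30;

// [[Rcpp::export(name = ".nw_affine_path")]]
List nw_affine_path(NumericMatrix S, double gap_open, double gap_extend) {
  const int n = S.nrow(), m = S.ncol();
  if (n == 0 || m == 0)
    stop("both inputs must have positive length");

  // State 0 = M (diagonal), 1 = X (gap in B, consumes A), 2 = Y (gap in A).
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  IntegerMatrix TM(n + 1, m + 1), TX(n + 1, m + 1), TY(n + 1, m + 1);

  M(0, 0) = 0.0;
  X(0, 0) = NEG_INF;
  Y(0, 0) = NEG_INF;
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = NEG_INF;
    Y(i, 0) = NEG_INF;
    X(i, 0) = -(gap_open + (i - 1) * gap_extend);
    TX(i, 0) = 1;
  }
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NEG_INF;
    X(0, j) = NEG_INF;
    Y(0, j) = -(gap_open + (j - 1) * gap_extend);
    TY(0, j) = 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // M: best predecessor at (i-1, j-1); ties prefer M, then X, then Y.
      double bm = M(i - 1, j - 1);
      int tm = 0;
      if (X(i - 1, j - 1) > bm) { bm = X(i - 1, j - 1); tm = 1; }
      if (Y(i - 1, j - 1) > bm) { bm = Y(i - 1, j - 1); tm = 2; }
      M(i, j) = bm + S(i - 1, j - 1);
      TM(i, j) = tm;

      // X: gap in B (move up).
      double bx = M(i - 1, j) - gap_open;
      int tx = 0;
      if (X(i - 1, j) - gap_extend > bx) { bx = X(i - 1, j) - gap_extend; tx = 1; }
      if (Y(i - 1, j) - gap_open > bx) { bx = Y(i - 1, j) - gap_open; tx = 2; }
      X(i, j) = bx;
      TX(i, j) = tx;

      // Y: gap in A (move left).
      double by = M(i, j - 1) - gap_open;
      int ty = 0;
      if (X(i, j - 1) - gap_open > by) { by = X(i, j - 1) - gap_open; ty = 1; }
      if (Y(i, j - 1) - gap_extend > by) { by = Y(i, j - 1) - gap_extend; ty = 2; }
      Y(i, j) = by;
      TY(i, j) = ty;
    }
  }

  double best = M(n, m);
  int state = 0;
  if (X(n, m) > best) { best = X(n, m); state = 1; }
  if (Y(n, m) > best) { best = Y(n, m); state = 2; }

  std::vector<int> ai, bi;
  ai.reserve(n + m);
  bi.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      ai.push_back(i);
      bi.push_back(j);
      int prev = TM(i, j);
      --i; --j;
      state = prev;
    } else if (state == 1) {
      ai.push_back(i);
      bi.push_back(0);
      int prev = TX(i, j);
      --i;
      state = prev;
    } else {
      ai.push_back(0);
      bi.push_back(j);
      int prev = TY(i, j);
      --j;
      state = prev;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());

  return List::create(_["score"] = best,
                      _["a_idx"] = wrap(ai),
                      _["b_idx"] = wrap(bi));
}
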