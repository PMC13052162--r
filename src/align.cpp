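#include <Rcpp.h>
using namespace Rcpp;

// Gotoh (affine-gap) global alignment between two profiles.
//
// Profiles arrive as integer matrices (rows = sequences, cols = alignment
// columns) with the encoding A=0, C=1, G=2, T=3, gap=4, other/ambiguous=5.
// Column-pair substitution score is the mean pairwise score over all row
// pairs: +1 for identical unambiguous bases, -1 for differing unambiguous
// bases, 0 when either partner is a gap or ambiguous. Gap penalties
// (open/extend) are applied once per inserted gap column, not scaled by
// profile depth, which keeps the scheme consistent between the pairwise and
// the profile stage of the progressive alignment.

static const double NEG_INF = -1e30;

// per-column base counts (A,C,G,T) and number of unambiguous bases
static void column_counts(const IntegerMatrix& prof, int col,
                          double cnt[4], double& nvalid) {
  cnt[0] = cnt[1] = cnt[2] = cnt[3] = 0.0;
  for (int r = 0; r < prof.nrow(); ++r) {
    int b = prof(r, col);
    if (b >= 0 && b < 4) cnt[b] += 1.0;
  }
  nvalid = cnt[0] + cnt[1] + cnt[2] + cnt[3];
}

// [[Rcpp::export(name = ".cpp_profile_align")]]
List cpp_profile_align(IntegerMatrix profA, IntegerMatrix profB,
                       double match = 1.0, double mismatch = -1.0,
                       double gap_open = -5.0, double gap_extend = -1.0) {
  const int La = profA.ncol(), Lb = profB.ncol();
  const double npairs = (double)profA.nrow() * (double)profB.nrow();

  // precompute column counts
  std::vector<double> cA(4 * La), cB(4 * Lb), vA(La), vB(Lb);
  double tmp[4], nv;
  for (int i = 0; i < La; ++i) {
    column_counts(profA, i, tmp, nv);
    for (int k = 0; k < 4; ++k) cA[4 * i + k] = tmp[k];
    vA[i] = nv;
  }
  for (int j = 0; j < Lb; ++j) {
    column_counts(profB, j, tmp, nv);
    for (int k = 0; k < 4; ++k) cB[4 * j + k] = tmp[k];
    vB[j] = nv;
  }

  auto colscore = [&](int i, int j) -> double {
    double same = 0.0;
    for (int k = 0; k < 4; ++k) same += cA[4 * i + k] * cB[4 * j + k];
    double valid = vA[i] * vB[j];
    // matches score +match, mismatching unambiguous pairs score mismatch
    return (same * match + (valid - same) * mismatch) / npairs;
  };

  // DP over three states: M (aligned), X (gap in B), Y (gap in A)
  const int W = Lb + 1;
  std::vector<double> M((La + 1) * W, NEG_INF), X((La + 1) * W, NEG_INF),
      Y((La + 1) * W, NEG_INF);
  std::vector<signed char> tbM((La + 1) * W), tbX((La + 1) * W),
      tbY((La + 1) * W);

  M[0] = 0.0;
  for (int i = 1; i <= La; ++i) {
    X[i * W] = gap_open + gap_extend * (i - 1);
    tbX[i * W] = (i == 1) ? 0 : 1; // from M at origin, else extend
  }
  for (int j = 1; j <= Lb; ++j) {
    Y[j] = gap_open + gap_extend * (j - 1);
    tbY[j] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= La; ++i) {
    for (int j = 1; j <= Lb; ++j) {
      const int ij = i * W + j;
      // M: consume one column from each
      double s = colscore(i - 1, j - 1);
      double m0 = M[ij - W - 1], m1 = X[ij - W - 1], m2 = Y[ij - W - 1];
      if (m0 >= m1 && m0 >= m2) { M[ij] = m0 + s; tbM[ij] = 0; }
      else if (m1 >= m2)        { M[ij] = m1 + s; tbM[ij] = 1; }
      else                      { M[ij] = m2 + s; tbM[ij] = 2; }
      // X: gap column inserted into B (consume A column i)
      double xo = M[ij - W] + gap_open, xe = X[ij - W] + gap_extend;
      if (xo >= xe) { X[ij] = xo; tbX[ij] = 0; } else { X[ij] = xe; tbX[ij] = 1; }
      // Y: gap column inserted into A (consume B column j)
      double yo = M[ij - 1] + gap_open, ye = Y[ij - 1] + gap_extend;
      if (yo >= ye) { Y[ij] = yo; tbY[ij] = 0; } else { Y[ij] = ye; tbY[ij] = 2; }
    }
  }

  // traceback from the best end state
  int i = La, j = Lb, state;
  double best = M[i * W + j];
  state = 0;
  if (X[i * W + j] > best) { best = X[i * W + j]; state = 1; }
  if (Y[i * W + j] > best) { best = Y[i * W + j]; state = 2; }

  std::vector<int> ia, ib; // source column (1-based) or 0 for gap
  while (i > 0 || j > 0) {
    if (state == 0) {
      int prev = tbM[i * W + j];
      ia.push_back(i); ib.push_back(j); --i; --j; state = prev;
    } else if (state == 1) {
      int prev = tbX[i * W + j];
      ia.push_back(i); ib.push_back(0); --i; state = prev;
    } else {
      int prev = tbY[i * W + j];
      ia.push_back(0); ib.push_back(j); --j; state = prev;
    }
  }
  std::reverse(ia.begin(), ia.end());
  std::reverse(ib.begin(), ib.end());
  return List::create(_["score"] = best,
                      _["idxA"] = IntegerVector(ia.begin(), ia.end()),
                      _["idxB"] = IntegerVector(ib.begin(), ib.end()));
}

// [[Rcpp::export(name = ".cpp_mismatch_pairs")]]
NumericMatrix cpp_mismatch_pairs(IntegerMatrix prof) {
  // pairwise mismatch counts with pairwise deletion over an encoded
  // alignment matrix (same encoding as above); also returns comparable
  // site counts in the upper triangle duplicate structure:
  // result is n x n with mismatches below, comparable sites above diagonal.
  int n = prof.nrow(), L = prof.ncol();
  NumericMatrix out(n, n);
  for (int a = 0; a < n; ++a) {
    for (int b = a + 1; b < n; ++b) {
      double mm = 0, comp = 0;
      for (int k = 0; k < L; ++k) {
        int x = prof(a, k), y = prof(b, k);
        if (x < 4 && y < 4) { comp += 1; if (x != y) mm += 1; }
      }
      out(b, a) = mm;
      out(a, b) = comp;
    }
  }
  return out;
}
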