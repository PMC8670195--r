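#include <Rcpp.h>
using namespace Rcpp;

// Global profile-profile alignment with affine gaps (Gotoh three-state DP).
// f1, f2: alphabet x L frequency profiles (columns are alignment columns);
// smat: alphabet x alphabet substitution scores (gap rows/cols must be 0).
// Gap costs: a run of length L costs gapo + L * gape, end gaps included.
// Returns integer move vector: 0 = column from both, 1 = column from f1 only
// (gap inserted in profile 2), 2 = column from f2 only.
// Tie-break order diag > up > left makes the traceback deterministic.
// [[Rcpp::export]]
IntegerVector cpp_profile_align(NumericMatrix f1, NumericMatrix f2,
                                NumericMatrix smat, double gapo, double gape) {
  const int A = f1.nrow();
  const int n = f1.ncol(), m = f2.ncol();
  if (f2.nrow() != A || smat.nrow() != A || smat.ncol() != A)
    stop("profile/substitution dimensions disagree");
  const double NEG = -1e30;

  // Precompute expected column-vs-column scores.
  NumericMatrix cs(n, m);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j) {
      double s = 0.0;
      for (int a = 0; a < A; ++a) {
        double fa = f1(a, i);
        if (fa == 0.0) continue;
        for (int b = 0; b < A; ++b) {
          double fb = f2(b, j);
          if (fb != 0.0) s += fa * fb * smat(a, b);
        }
      }
      cs(i, j) = s;
    }

  std::vector<double> M((n + 1) * (m + 1), NEG), X(M), Y(M);
  std::vector<signed char> tM(M.size()), tX(M.size()), tY(M.size());
  auto at = [m](int i, int j) { return i * (m + 1) + j; };
  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {  // X: gap in profile 2 (consume f1)
    X[at(i, 0)] = -gapo - gape * i;
    tX[at(i, 0)] = 1;  // came from X
  }
  for (int j = 1; j <= m; ++j) {
    Y[at(0, j)] = -gapo - gape * j;
    tY[at(0, j)] = 2;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // M
      double dM = M[at(i - 1, j - 1)], dX = X[at(i - 1, j - 1)],
             dY = Y[at(i - 1, j - 1)];
      double best = dM; signed char tb = 0;
      if (dX > best) { best = dX; tb = 1; }
      if (dY > best) { best = dY; tb = 2; }
      M[at(i, j)] = best + cs(i - 1, j - 1);
      tM[at(i, j)] = tb;
      // X (consume f1, gap in f2)
      double oM = M[at(i - 1, j)] - gapo - gape;
      double oX = X[at(i - 1, j)] - gape;
      if (oM >= oX) { X[at(i, j)] = oM; tX[at(i, j)] = 0; }
      else          { X[at(i, j)] = oX; tX[at(i, j)] = 1; }
      // Y (consume f2)
      double pM = M[at(i, j - 1)] - gapo - gape;
      double pY = Y[at(i, j - 1)] - gape;
      if (pM >= pY) { Y[at(i, j)] = pM; tY[at(i, j)] = 0; }
      else          { Y[at(i, j)] = pY; tY[at(i, j)] = 2; }
    }
  }

  // Traceback from best final state, preference M > X > Y.
  int i = n, j = m;
  double fM = M[at(n, m)], fX = X[at(n, m)], fY = Y[at(n, m)];
  int state = 0;
  if (fX > fM && fX >= fY) state = 1;
  else if (fY > fM && fY > fX) state = 2;
  std::vector<int> rev;
  while (i > 0 || j > 0) {
    if (state == 0) {
      signed char tb = tM[at(i, j)];
      rev.push_back(0); --i; --j; state = tb;
    } else if (state == 1) {
      signed char tb = tX[at(i, j)];
      rev.push_back(1); --i; state = (tb == 0) ? 0 : 1;
    } else {
      signed char tb = tY[at(i, j)];
      rev.push_back(2); --j; state = (tb == 0) ? 0 : 2;
    }
  }
  IntegerVector out(rev.size());
  for (size_t k = 0; k < rev.size(); ++k) out[k] = rev[rev.size() - 1 - k];
  return out;
}
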