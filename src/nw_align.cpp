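#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with affine gaps, Gotoh three-state
// recursion. A gap of length L costs gapOpen + L * gapExtend. Traceback is
// deterministic: on score ties prefer the diagonal (match) state, then up
// (gap in b), then left (gap in a). Backpointers are stored as bytes so
// sequences of several kb stay cheap in memory.
//
// a, b: integer codes (0-based) into the substitution matrix `sub`.
// [[Rcpp::export(name = ".nwAlignCpp")]]
List nwAlignCpp(IntegerVector a, IntegerVector b, NumericMatrix sub,
                double gapOpen, double gapExtend) {
  const int n = a.size(), m = b.size();
  const double NEG = -std::numeric_limits<double>::infinity();
  const size_t W = static_cast<size_t>(m) + 1;

  std::vector<double> Mprev(W), Xprev(W), Yprev(W);
  std::vector<double> Mcur(W), Xcur(W), Ycur(W);
  // backpointers: for M, predecessor state at (i-1, j-1); for X, at (i-1, j);
  // for Y, at (i, j-1). 0 = M, 1 = X, 2 = Y, 3 = none (boundary).
  std::vector<unsigned char> ptrM(( (size_t)n + 1) * W, 3);
  std::vector<unsigned char> ptrX(( (size_t)n + 1) * W, 3);
  std::vector<unsigned char> ptrY(( (size_t)n + 1) * W, 3);

  Mprev[0] = 0.0; Xprev[0] = NEG; Yprev[0] = NEG;
  for (int j = 1; j <= m; ++j) {
    Mprev[j] = NEG;
    Xprev[j] = NEG;
    Yprev[j] = gapOpen + j * gapExtend;
    ptrY[(size_t)j] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    Mcur[0] = NEG;
    Xcur[0] = gapOpen + i * gapExtend;
    Ycur[0] = NEG;
    ptrX[(size_t)i * W] = (i == 1) ? 0 : 1;
    for (int j = 1; j <= m; ++j) {
      // M: consume a_i and b_j
      double s = sub(a[i - 1], b[j - 1]);
      double fromM = Mprev[j - 1], fromX = Xprev[j - 1], fromY = Yprev[j - 1];
      unsigned char pm = 0; double best = fromM;
      if (fromX > best) { best = fromX; pm = 1; }
      if (fromY > best) { best = fromY; pm = 2; }
      Mcur[j] = (best == NEG) ? NEG : best + s;
      ptrM[(size_t)i * W + j] = pm;
      // X: gap in b (consume a_i), comes from row i-1 same j
      double openX = Mprev[j] + gapOpen + gapExtend;
      double extX = Xprev[j] + gapExtend;
      if (openX >= extX) { Xcur[j] = openX; ptrX[(size_t)i * W + j] = 0; }
      else { Xcur[j] = extX; ptrX[(size_t)i * W + j] = 1; }
      // Y: gap in a (consume b_j), comes from column j-1 same i
      double openY = Mcur[j - 1] + gapOpen + gapExtend;
      double extY = Ycur[j - 1] + gapExtend;
      if (openY >= extY) { Ycur[j] = openY; ptrY[(size_t)i * W + j] = 0; }
      else { Ycur[j] = extY; ptrY[(size_t)i * W + j] = 2; }
    }
    std::swap(Mprev, Mcur); std::swap(Xprev, Xcur); std::swap(Yprev, Ycur);
  }

  // final scores live in the "prev" rows after the last swap
  double scM = Mprev[m], scX = Xprev[m], scY = Yprev[m];
  unsigned char state = 0; double score = scM;
  if (scX > score) { score = scX; state = 1; }
  if (scY > score) { score = scY; state = 2; }

  // traceback using the pointer matrices only
  std::vector<int> opsA, opsB;  // 1 = consume, 0 = gap
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      unsigned char p = ptrM[(size_t)i * W + j];
      opsA.push_back(1); opsB.push_back(1);
      --i; --j; state = p;
    } else if (state == 1) {
      unsigned char p = ptrX[(size_t)i * W + j];
      opsA.push_back(1); opsB.push_back(0);
      --i; state = p;
    } else {
      unsigned char p = ptrY[(size_t)i * W + j];
      opsA.push_back(0); opsB.push_back(1);
      --j; state = p;
    }
  }
  std::reverse(opsA.begin(), opsA.end());
  std::reverse(opsB.begin(), opsB.end());
  return List::create(_["score"] = score,
                      _["opsA"] = wrap(opsA), _["opsB"] = wrap(opsB));
}
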