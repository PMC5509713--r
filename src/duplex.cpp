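#include <Rcpp.h>
using namespace Rcpp;

// Interaction-only duplex minimum-free-energy dynamic programme.
//
// x, y: integer-encoded sequences (A=0, C=1, G=2, T/U=3, N=4), both 5'->3'.
// An antiparallel duplex pairs x[i] with y[j] such that successive pairs
// move right on x and left on y. H(i,j) is the best energy of a duplex
// whose rightmost-on-x pair is (i,j); it is extended either by stacking
// (adjacent pair) or across an interior/bulge loop of up to maxSpan
// unpaired nt per side with an affine penalty. The duplex initiation cost
// is added once at the end.
//
// pairCode: 5x5 matrix, 0 = not pairable, else 1..6 pair-type code.
// stack(a, b): stacking energy for pair-type a followed by pair-type b
//              (already temperature-rescaled); NA = stack not allowed.
// [[Rcpp::export]]
List duplex_dp(IntegerVector x, IntegerVector y, NumericMatrix stack,
               IntegerMatrix pairCode, double loopOpen, double loopExt,
               int maxSpan, double init) {
  const int n = x.size(), m = y.size();
  const double INF = 1e12;
  std::vector<double> H((size_t)n * m, INF);
  std::vector<int> bpi((size_t)n * m, -1), bpj((size_t)n * m, -1);
  std::vector<int> P((size_t)n * m, 0);

  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j)
      P[(size_t)i * m + j] = pairCode(x[i], y[j]);

  double best = INF;
  int bi = -1, bj = -1;

  for (int i = 0; i < n; ++i) {
    for (int j = m - 1; j >= 0; --j) {
      const size_t ij = (size_t)i * m + j;
      const int pc = P[ij];
      if (pc == 0) continue;
      double h = 0.0;  // open a new duplex at this pair
      int pbi = -1, pbj = -1;
      // stacking on the adjacent pair
      if (i > 0 && j + 1 < m) {
        const size_t pij = (size_t)(i - 1) * m + (j + 1);
        const int ppc = P[pij];
        if (ppc != 0) {
          const double s = stack(ppc - 1, pc - 1);
          if (R_finite(s) && H[pij] + s < h) {
            h = H[pij] + s; pbi = i - 1; pbj = j + 1;
          }
        }
      }
      // interior / bulge loop closure
      if (maxSpan > 0) {
        const int liMax = std::min(maxSpan, i - 1);
        for (int li = 0; li <= liMax; ++li) {
          const int ip = i - 1 - li;
          const int ljMax = std::min(maxSpan, m - j - 2);
          const size_t rowBase = (size_t)ip * m;
          for (int lj = (li == 0 ? 1 : 0); lj <= ljMax; ++lj) {
            const int jp = j + 1 + lj;
            if (P[rowBase + jp] == 0) continue;
            const double cand =
              H[rowBase + jp] + loopOpen + loopExt * (li + lj);
            if (cand < h) { h = cand; pbi = ip; pbj = jp; }
          }
        }
      }
      H[ij] = h;
      bpi[ij] = pbi;
      bpj[ij] = pbj;
      if (h < best) { best = h; bi = i; bj = j; }
    }
  }

  if (bi < 0) {
    return List::create(_["found"] = false);
  }
  // traceback
  std::vector<int> pi, pj;
  int i = bi, j = bj;
  while (i >= 0) {
    pi.push_back(i);
    pj.push_back(j);
    const size_t ij = (size_t)i * m + j;
    const int ni = bpi[ij], nj = bpj[ij];
    i = ni; j = nj;
  }
  std::reverse(pi.begin(), pi.end());
  std::reverse(pj.begin(), pj.end());
  return List::create(_["found"] = true,
                      _["energy"] = best + init,
                      _["pairs_i"] = wrap(pi),
                      _["pairs_j"] = wrap(pj));
}
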