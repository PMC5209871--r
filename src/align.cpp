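#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap global alignment (Gotoh) over a precomputed column-score
// matrix C, where C(i, j) is the score of pairing unit i of A with unit j
// of B.  A gap of length L costs gap_open + L * gap_ext (charged via an
// opening transition of gap_open + gap_ext followed by extensions of
// gap_ext).  Ties are broken deterministically: diagonal (match/mismatch)
// is preferred over a gap in A, which is preferred over a gap in B.
//
// Returns 1-based index paths for A and B (0 = gap) and the optimal score.
// Shared by residue-level pairwise alignment and profile-profile alignment.

static const double NEG = -1e300;

// [[Rcpp::export]]
List affine_global_dp(NumericMatrix C, double gap_open, double gap_ext) {
  const int n = C.nrow(), m = C.ncol();
  const double open = gap_open + gap_ext;  // first gap character
  // state codes: 0 = M (diagonal), 1 = E (gap in A, consumes B),
  //              2 = F (gap in B, consumes A)
  NumericMatrix M(n + 1, m + 1), E(n + 1, m + 1), F(n + 1, m + 1);
  IntegerMatrix tbM(n + 1, m + 1), tbE(n + 1, m + 1), tbF(n + 1, m + 1);

  M(0, 0) = 0.0; E(0, 0) = NEG; F(0, 0) = NEG;
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NEG; F(0, j) = NEG;
    E(0, j) = -(open + (j - 1) * gap_ext);
    tbE(0, j) = (j == 1) ? 0 : 1;
  }
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = NEG; E(i, 0) = NEG;
    F(i, 0) = -(open + (i - 1) * gap_ext);
    tbF(i, 0) = (i == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // M: arrive diagonally from any state (preference M > E > F)
      double best = M(i - 1, j - 1); int bs = 0;
      if (E(i - 1, j - 1) > best) { best = E(i - 1, j - 1); bs = 1; }
      if (F(i - 1, j - 1) > best) { best = F(i - 1, j - 1); bs = 2; }
      M(i, j) = best + C(i - 1, j - 1);
      tbM(i, j) = bs;
      // E: gap in A
      best = M(i, j - 1) - open; bs = 0;
      if (E(i, j - 1) - gap_ext > best) { best = E(i, j - 1) - gap_ext; bs = 1; }
      if (F(i, j - 1) - open > best) { best = F(i, j - 1) - open; bs = 2; }
      E(i, j) = best; tbE(i, j) = bs;
      // F: gap in B
      best = M(i - 1, j) - open; bs = 0;
      if (E(i - 1, j) - open > best) { best = E(i - 1, j) - open; bs = 1; }
      if (F(i - 1, j) - gap_ext > best) { best = F(i - 1, j) - gap_ext; bs = 2; }
      F(i, j) = best; tbF(i, j) = bs;
    }
  }

  double score = M(n, m); int state = 0;
  if (E(n, m) > score) { score = E(n, m); state = 1; }
  if (F(n, m) > score) { score = F(n, m); state = 2; }

  std::vector<int> ai, bi;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      ai.push_back(i); bi.push_back(j);
      state = tbM(i, j); --i; --j;
    } else if (state == 1) {
      ai.push_back(0); bi.push_back(j);
      state = tbE(i, j); --j;
    } else {
      ai.push_back(i); bi.push_back(0);
      state = tbF(i, j); --i;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());
  return List::create(_["a"] = wrap(ai), _["b"] = wrap(bi),
                      _["score"] = score);
}
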