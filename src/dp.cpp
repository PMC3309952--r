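#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Needleman-Wunsch style fill with linear gap penalty and free end gaps
// (boundary row/column = 0; traceback starts at the best cell on the last
// row or column).  Tie-breaking: diagonal > up > left; among equal start
// cells the larger i, then larger j wins.  Returns 0-based matched pairs.
// [[Rcpp::export]]
List dp_fill_traceback(const arma::mat& S, double gap) {
  const int n = S.n_rows, m = S.n_cols;
  arma::mat H(n + 1, m + 1, arma::fill::zeros);
  arma::imat D(n + 1, m + 1, arma::fill::zeros);  // 0 stop, 1 diag, 2 up, 3 left

  // A match may start a fresh path (zero floor on the diagonal move):
  // residues before the first aligned pair are free in BOTH chains, and
  // likewise after the last pair, so only gaps between matches pay.
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double diag = S(i - 1, j - 1) + std::max(H(i - 1, j - 1), 0.0);
      double up   = H(i - 1, j) + gap;
      double left = H(i, j - 1) + gap;
      double best = diag;
      int dir = 1;
      if (up > best)   { best = up;   dir = 2; }
      if (left > best) { best = left; dir = 3; }
      H(i, j) = best;
      D(i, j) = dir;
    }
  }

  // end gaps are free on both sides, so the path may end anywhere: start
  // the traceback at the best cell of the whole matrix (boundary zeros
  // keep the empty path admissible).  Ties prefer larger i, then larger j.
  int bi = 0, bj = 0;
  double bscore = 0.0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      if (H(i, j) >= bscore) { bscore = H(i, j); bi = i; bj = j; }
    }
  }

  std::vector<int> qi, pj;
  int i = bi, j = bj;
  while (i > 0 && j > 0) {
    int dir = D(i, j);
    if (dir == 1) {
      qi.push_back(i - 1);
      pj.push_back(j - 1);
      // a non-positive predecessor means this match started the path
      if (H(i - 1, j - 1) <= 0.0) break;
      --i; --j;
    } else if (dir == 2) {
      --i;
    } else if (dir == 3) {
      --j;
    } else {
      break;
    }
  }
  std::reverse(qi.begin(), qi.end());
  std::reverse(pj.begin(), pj.end());

  IntegerMatrix pairs(qi.size(), 2);
  for (size_t k = 0; k < qi.size(); ++k) {
    pairs(k, 0) = qi[k];
    pairs(k, 1) = pj[k];
  }
  return List::create(_["pairs"] = pairs, _["score"] = bscore);
}
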