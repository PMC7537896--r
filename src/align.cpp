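#include <Rcpp.h>
using namespace Rcpp;

// Alignment kernels shared by the repeat scanner (profile local alignment)
// and the phylogeny stage (global alignment for p-distances).
//
// Residues arrive as 1-based integer codes into the package alphabet; code 0
// marks a masked residue and scores -inf against every profile position so a
// masked stretch can never be re-used by a later greedy pass.

static const double NEG_INF = -1e12;

// Smith-Waterman of a protein (rows) against a position-weight profile
// (columns). weights is L x A: score of alphabet code a at profile column j
// is weights(j, a - 1). Linear gap penalty (gap < 0). The best cell is the
// first one encountered in row-major order achieving the maximum, which
// fixes ties at the smallest end coordinate; traceback prefers
// diagonal > up (skip protein residue) > left (skip profile column).
// [[Rcpp::export(name = ".cpp_profile_local_align")]]
List cpp_profile_local_align(IntegerVector seq, NumericMatrix weights,
                             double gap) {
  const int n = seq.size();        // protein length
  const int L = weights.nrow();    // profile length
  const int A = weights.ncol();
  NumericMatrix H(n + 1, L + 1);   // zero-initialised
  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    const int code = seq[i - 1];
    for (int j = 1; j <= L; ++j) {
      double s;
      if (code < 1 || code > A) {
        s = NEG_INF;
      } else {
        s = weights(j - 1, code - 1);
      }
      double diag = H(i - 1, j - 1) + s;
      double up = H(i - 1, j) + gap;
      double left = H(i, j - 1) + gap;
      double v = diag;
      if (up > v) v = up;
      if (left > v) v = left;
      if (v < 0.0) v = 0.0;
      H(i, j) = v;
      if (v > best) {  // strict: earliest maximal cell wins
        best = v;
        bi = i;
        bj = j;
      }
    }
  }
  if (best <= 0.0) {
    return List::create(_["score"] = 0.0, _["start"] = NA_INTEGER,
                        _["end"] = NA_INTEGER,
                        _["seq_idx"] = IntegerVector(0),
                        _["prof_idx"] = IntegerVector(0));
  }
  // traceback
  std::vector<int> si, pj;
  int i = bi, j = bj;
  while (i > 0 && j > 0 && H(i, j) > 0.0) {
    const int code = seq[i - 1];
    double s = (code < 1 || code > A) ? NEG_INF : weights(j - 1, code - 1);
    if (H(i, j) == H(i - 1, j - 1) + s) {
      si.push_back(i);
      pj.push_back(j);
      --i; --j;
    } else if (H(i, j) == H(i - 1, j) + gap) {
      --i;
    } else {
      --j;
    }
  }
  std::reverse(si.begin(), si.end());
  std::reverse(pj.begin(), pj.end());
  int start = si.empty() ? bi : si.front();
  // the aligned region starts at the first consumed protein residue; i is
  // the residue before the alignment after traceback, so start = i + 1
  start = i + 1;
  return List::create(_["score"] = best, _["start"] = start, _["end"] = bi,
                      _["seq_idx"] = wrap(si), _["prof_idx"] = wrap(pj));
}

// Needleman-Wunsch with simple match/mismatch scores and linear gaps.
// Deterministic traceback, tie order diagonal > up (gap in b) > left
// (gap in a). Returns aligned sequences as integer vectors with 0 = gap.
// [[Rcpp::export(name = ".cpp_nw_align")]]
List cpp_nw_align(IntegerVector a, IntegerVector b, double match,
                  double mismatch, double gap) {
  const int n = a.size(), m = b.size();
  NumericMatrix H(n + 1, m + 1);
  for (int i = 1; i <= n; ++i) H(i, 0) = i * gap;
  for (int j = 1; j <= m; ++j) H(0, j) = j * gap;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      double diag = H(i - 1, j - 1) + s;
      double up = H(i - 1, j) + gap;
      double left = H(i, j - 1) + gap;
      double v = diag;
      if (up > v) v = up;
      if (left > v) v = left;
      H(i, j) = v;
    }
  }
  std::vector<int> aa, bb;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0) {
      double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      if (H(i, j) == H(i - 1, j - 1) + s) {
        aa.push_back(a[i - 1]);
        bb.push_back(b[j - 1]);
        --i; --j;
        continue;
      }
    }
    if (i > 0 && H(i, j) == H(i - 1, j) + gap) {
      aa.push_back(a[i - 1]);
      bb.push_back(0);
      --i;
    } else {
      aa.push_back(0);
      bb.push_back(b[j - 1]);
      --j;
    }
  }
  std::reverse(aa.begin(), aa.end());
  std::reverse(bb.begin(), bb.end());
  return List::create(_["score"] = H(n, m), _["a"] = wrap(aa),
                      _["b"] = wrap(bb));
}
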