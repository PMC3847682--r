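#include <Rcpp.h>
#include <vector>
#include <cstring>
using namespace Rcpp;

// Pairwise alignment with linear gap penalty and an arbitrary substitution
// matrix.  modes: 0 = local (Smith-Waterman), 1 = global (Needleman-Wunsch),
// 2 = ends-free overlap (leading/trailing gaps on either sequence are free,
// the geometry used for read suffix-prefix overlap detection).
//
// Sequences arrive as 0-based integer vectors indexing the rows/columns of
// the substitution matrix.  Coordinates in the result are 0-based half-open.

struct AlnResult {
  double score;
  int matches, mismatches, gapopens, aln_len;
  int q_start, q_end, s_start, s_end;
};

static AlnResult align_core(const int *q, int lq, const int *s, int ls,
                            const double *S, int nrowS, double gap, int mode) {
  const int W = ls + 1;
  std::vector<double> H((size_t)(lq + 1) * W);
  std::vector<unsigned char> T((size_t)(lq + 1) * W, 0); // 0 stop,1 diag,2 up,3 left

  // init
  for (int j = 0; j <= ls; ++j) {
    if (mode == 1) { H[j] = -gap * j; T[j] = j ? 3 : 0; }
    else H[j] = 0.0;
  }
  for (int i = 1; i <= lq; ++i) {
    size_t r = (size_t)i * W;
    if (mode == 1) { H[r] = -gap * i; T[r] = 2; }
    else H[r] = 0.0;
  }

  double best = (mode == 0) ? 0.0 : R_NegInf;
  int bi = 0, bj = 0;

  for (int i = 1; i <= lq; ++i) {
    size_t r = (size_t)i * W, p = r - W;
    const double *Srow = S + (size_t)q[i - 1];
    for (int j = 1; j <= ls; ++j) {
      double d = H[p + j - 1] + Srow[(size_t)s[j - 1] * nrowS];
      double u = H[p + j] - gap;
      double l = H[r + j - 1] - gap;
      double v = d; unsigned char t = 1;
      if (u > v) { v = u; t = 2; }
      if (l > v) { v = l; t = 3; }
      if (mode == 0 && v <= 0.0) { v = 0.0; t = 0; }
      H[r + j] = v; T[r + j] = t;
      if (mode == 0 && v > best) { best = v; bi = i; bj = j; }
    }
    if (mode == 2) { // candidate end on last column
      double v = H[r + ls];
      if (v > best) { best = v; bi = i; bj = ls; }
    }
  }
  if (mode == 1) { best = H[(size_t)lq * W + ls]; bi = lq; bj = ls; }
  else if (mode == 2) { // also ends on last row
    size_t r = (size_t)lq * W;
    for (int j = 0; j <= ls; ++j)
      if (H[r + j] > best) { best = H[r + j]; bi = lq; bj = j; }
  }

  AlnResult res; res.score = best;
  res.matches = res.mismatches = res.gapopens = res.aln_len = 0;
  int i = bi, j = bj;
  unsigned char prev = 0;
  while (i > 0 || j > 0) {
    unsigned char t = T[(size_t)i * W + j];
    if (mode == 0 && t == 0) break;
    if (mode == 2 && (i == 0 || j == 0)) break;
    if (mode == 1 && i == 0 && j == 0) break;
    if (t == 1) {
      ++res.aln_len;
      if (q[i - 1] == s[j - 1]) ++res.matches; else ++res.mismatches;
      --i; --j; prev = 1;
    } else if (t == 2) {
      ++res.aln_len; if (prev != 2) ++res.gapopens; --i; prev = 2;
    } else if (t == 3) {
      ++res.aln_len; if (prev != 3) ++res.gapopens; --j; prev = 3;
    } else break;
  }
  res.q_start = i; res.q_end = bi; res.s_start = j; res.s_end = bj;
  return res;
}

static DataFrame results_to_df(const std::vector<AlnResult> &rs) {
  int n = rs.size();
  NumericVector score(n);
  IntegerVector matches(n), mismatches(n), gapopens(n), aln_len(n),
      q_start(n), q_end(n), s_start(n), s_end(n);
  for (int k = 0; k < n; ++k) {
    score[k] = rs[k].score; matches[k] = rs[k].matches;
    mismatches[k] = rs[k].mismatches; gapopens[k] = rs[k].gapopens;
    aln_len[k] = rs[k].aln_len;
    q_start[k] = rs[k].q_start; q_end[k] = rs[k].q_end;
    s_start[k] = rs[k].s_start; s_end[k] = rs[k].s_end;
  }
  return DataFrame::create(
      _["score"] = score, _["matches"] = matches,
      _["mismatches"] = mismatches, _["gap_opens"] = gapopens,
      _["aln_len"] = aln_len, _["q_start"] = q_start, _["q_end"] = q_end,
      _["s_start"] = s_start, _["s_end"] = s_end);
}

// [[Rcpp::export(name = ".cpp_align_pairs")]]
DataFrame cpp_align_pairs(List qseqs, List sseqs, IntegerVector qi,
                          IntegerVector si, NumericMatrix S, double gap,
                          int mode) {
  int n = qi.size();
  if (si.size() != n) stop("qi and si must have equal length");
  std::vector<AlnResult> rs; rs.reserve(n);
  int nrowS = S.nrow();
  for (int k = 0; k < n; ++k) {
    IntegerVector q = qseqs[qi[k] - 1];
    IntegerVector s = sseqs[si[k] - 1];
    rs.push_back(align_core(INTEGER(q), q.size(), INTEGER(s), s.size(),
                            REAL(S), nrowS, gap, mode));
  }
  return results_to_df(rs);
}

// Banded ends-free overlap alignment of b against a, restricted to
// diagonals d = i - j (position of b's origin within a) in
// [diag - band, diag + band].  Used for overlap detection once a shared
// k-mer has proposed the diagonal.
// [[Rcpp::export(name = ".cpp_overlap_banded")]]
List cpp_overlap_banded(IntegerVector a, IntegerVector b, int diag, int band,
                        double match, double mismatch, double gap) {
  int la = a.size(), lb = b.size();
  int dlo = diag - band, dhi = diag + band;
  const int W = dhi - dlo + 1;
  const double NEG = -1e30;
  std::vector<double> H((size_t)(la + 1) * W, NEG);
  std::vector<unsigned char> T((size_t)(la + 1) * W, 0);

  // cell (i,j) stored at row i, column (i - j) - dlo; valid j = i - d
  // ends-free: any (i,0) or (0,j) inside the band starts at 0.
  for (int i = 0; i <= la; ++i) {
    int d = i; // j = 0
    if (d >= dlo && d <= dhi) H[(size_t)i * W + (d - dlo)] = 0.0;
  }
  for (int j = 0; j <= lb; ++j) {
    int d = -j; // i = 0
    if (d >= dlo && d <= dhi) H[(size_t)0 * W + (d - dlo)] = 0.0;
  }

  double best = NEG; int bi = -1, bj = -1;
  const int *pa = INTEGER(a), *pb = INTEGER(b);
  for (int i = 1; i <= la; ++i) {
    size_t r = (size_t)i * W, p = r - W;
    int jlo = i - dhi, jhi = i - dlo;
    if (jlo < 1) jlo = 1;
    if (jhi > lb) jhi = lb;
    for (int j = jlo; j <= jhi; ++j) {
      int c = (i - j) - dlo;
      double vbest = NEG; unsigned char t = 0;
      double dd = H[p + c]; // (i-1, j-1) same diagonal
      if (dd > NEG / 2) {
        double v = dd + ((pa[i - 1] == pb[j - 1]) ? match : mismatch);
        if (v > vbest) { vbest = v; t = 1; }
      }
      // up (i-1, j): diagonal (i-1-j) = (i-j)-1 -> column c-1
      if (c - 1 >= 0) {
        double u = H[p + (c - 1)];
        if (u > NEG / 2 && u - gap > vbest) { vbest = u - gap; t = 2; }
      }
      // left (i, j-1): diagonal (i-j)+1 -> column c+1
      if (c + 1 <= W - 1) {
        double l = H[r + (c + 1)];
        if (l > NEG / 2 && l - gap > vbest) { vbest = l - gap; t = 3; }
      }
      if (t == 0) continue;
      H[r + c] = vbest; T[r + c] = t;
      if ((i == la || j == lb) && vbest > best) { best = vbest; bi = i; bj = j; }
    }
  }
  if (bi < 0)
    return List::create(_["score"] = NA_REAL);

  int i = bi, j = bj, matches = 0, mismatches_n = 0, gapopens = 0, len = 0;
  unsigned char prev = 0;
  while (i > 0 && j > 0) {
    int c = (i - j) - dlo;
    unsigned char t = T[(size_t)i * W + c];
    if (t == 0) break;
    if (t == 1) {
      ++len; if (pa[i - 1] == pb[j - 1]) ++matches; else ++mismatches_n;
      --i; --j; prev = 1;
    } else if (t == 2) { ++len; if (prev != 2) ++gapopens; --i; prev = 2; }
    else { ++len; if (prev != 3) ++gapopens; --j; prev = 3; }
  }
  return List::create(
      _["score"] = best, _["matches"] = matches,
      _["mismatches"] = mismatches_n, _["gap_opens"] = gapopens,
      _["aln_len"] = len, _["a_start"] = i, _["a_end"] = bi,
      _["b_start"] = j, _["b_end"] = bj);
}
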