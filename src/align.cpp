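#include <Rcpp.h>
#include <vector>
#include <string>
#include <cctype>
#include <climits>
using namespace Rcpp;

// Affine-gap pairwise alignment (Gotoh three-state DP).
//
// mode: 0 = local (Smith-Waterman), 1 = global (Needleman-Wunsch, terminal
// gaps penalized), 2 = overlap (global with cost-free terminal gaps in
// either sequence).
//
// A gap of length L costs gap_open + L * gap_ext (BLAST convention).
// band > 0 restricts the DP to |i - j| <= band (global/overlap only); the
// caller guarantees band >= |len(a) - len(b)|.
//
// Characters are mapped through `alphabet` onto rows/cols of `sub`;
// characters absent from the alphabet map to its last symbol (the caller
// places the wildcard N/X last).

// [[Rcpp::export]]
List align_pair_cpp(std::string a, std::string b, IntegerMatrix sub,
                    std::string alphabet, int gap_open, int gap_ext,
                    int mode, int band) {
  const long n = (long)a.size(), m = (long)b.size();
  if (n == 0 || m == 0) stop("empty sequence");
  const int NEG = INT_MIN / 4;

  std::vector<int> code(256, (int)alphabet.size() - 1);
  for (size_t i = 0; i < alphabet.size(); ++i) {
    code[(unsigned char)std::toupper(alphabet[i])] = (int)i;
    code[(unsigned char)std::tolower(alphabet[i])] = (int)i;
  }
  std::vector<int> ai(n), bi(m);
  for (long i = 0; i < n; ++i) ai[i] = code[(unsigned char)a[i]];
  for (long j = 0; j < m; ++j) bi[j] = code[(unsigned char)b[j]];

  const bool local = (mode == 0), global = (mode == 1);
  const long W = m + 1;
  std::vector<int> M((n + 1) * W, NEG), X((n + 1) * W, NEG), Y((n + 1) * W, NEG);
  // traceback: tM 0=from M,1=from X,2=from Y,3=start; tX/tY 0=open,1=extend
  std::vector<unsigned char> tM((n + 1) * W, 3), tX((n + 1) * W, 0), tY((n + 1) * W, 0);

  M[0] = 0;
  for (long i = 1; i <= n; ++i) {
    if (global) {
      X[i * W] = -(gap_open + (int)i * gap_ext);
      tX[i * W] = (i == 1) ? 0 : 1;
    } else {
      M[i * W] = 0;  // free start in a
    }
  }
  for (long j = 1; j <= m; ++j) {
    if (global) {
      Y[j] = -(gap_open + (int)j * gap_ext);
      tY[j] = (j == 1) ? 0 : 1;
    } else {
      M[j] = 0;  // free start in b
    }
  }

  // flatten the substitution matrix for tight inner-loop access
  const int A = (int)alphabet.size();
  std::vector<int> SUB(A * A);
  for (int r = 0; r < A; ++r)
    for (int cix = 0; cix < A; ++cix)
      SUB[r * A + cix] = sub(r, cix);

  const int open_cost = gap_open + gap_ext;
  int* Mv = M.data(); int* Xv = X.data(); int* Yv = Y.data();
  unsigned char* tMv = tM.data(); unsigned char* tXv = tX.data();
  unsigned char* tYv = tY.data();
  for (long i = 1; i <= n; ++i) {
    long jlo = 1, jhi = m;
    if (band > 0 && !local) {
      jlo = std::max(1L, i - (long)band);
      jhi = std::min(m, i + (long)band);
    }
    const int* srow = &SUB[ai[i - 1] * A];
    int* Mi = Mv + i * W; const int* Mp = Mv + (i - 1) * W;
    int* Xi = Xv + i * W; const int* Xp = Xv + (i - 1) * W;
    int* Yi = Yv + i * W; const int* Yp = Yv + (i - 1) * W;
    unsigned char* tMi = tMv + i * W;
    unsigned char* tXi = tXv + i * W;
    unsigned char* tYi = tYv + i * W;
    for (long j = jlo; j <= jhi; ++j) {
      const int s = srow[bi[j - 1]];

      int best = Mp[j - 1];
      unsigned char tb = 0;
      if (Xp[j - 1] > best) { best = Xp[j - 1]; tb = 1; }
      if (Yp[j - 1] > best) { best = Yp[j - 1]; tb = 2; }
      if (local && best < 0) { best = 0; tb = 3; }
      Mi[j] = best + s;
      tMi[j] = tb;

      const int xo = Mp[j] - open_cost;
      const int xe = Xp[j] - gap_ext;
      if (xe > xo) { Xi[j] = xe; tXi[j] = 1; } else { Xi[j] = xo; tXi[j] = 0; }

      const int yo = Mi[j - 1] - open_cost;
      const int ye = Yi[j - 1] - gap_ext;
      if (ye > yo) { Yi[j] = ye; tYi[j] = 1; } else { Yi[j] = yo; tYi[j] = 0; }
    }
  }

  // locate alignment end
  long ei = n, ej = m;
  int state = 0, score = 0;
  if (local) {
    int bestv = 0;
    ei = ej = 0;
    for (long i = 1; i <= n; ++i)
      for (long j = 1; j <= m; ++j)
        if (M[i * W + j] > bestv) { bestv = M[i * W + j]; ei = i; ej = j; }
    score = bestv;
    if (bestv <= 0) {
      return List::create(_["score"] = 0, _["a_aln"] = "", _["b_aln"] = "",
                          _["a_start"] = 0, _["a_end"] = 0,
                          _["b_start"] = 0, _["b_end"] = 0,
                          _["matches"] = 0, _["mismatches"] = 0,
                          _["gap_opens"] = 0, _["gap_cols"] = 0,
                          _["ncols"] = 0);
    }
  } else if (global) {
    const long c = n * W + m;
    score = M[c]; state = 0;
    if (X[c] > score) { score = X[c]; state = 1; }
    if (Y[c] > score) { score = Y[c]; state = 2; }
  } else {
    // overlap: best M over last row and last column
    int bestv = NEG;
    for (long j = 1; j <= m; ++j)
      if (M[n * W + j] > bestv) { bestv = M[n * W + j]; ei = n; ej = j; }
    for (long i = 1; i <= n; ++i)
      if (M[i * W + m] > bestv) { bestv = M[i * W + m]; ei = i; ej = m; }
    score = bestv;
    state = 0;
  }

  // traceback
  std::string ra, rb;
  ra.reserve(n + m); rb.reserve(n + m);
  long i = ei, j = ej;
  int matches = 0, mismatches = 0, gap_opens = 0, gap_cols = 0;
  while (true) {
    const long c = i * W + j;
    if (state == 0) {
      if (i == 0 || j == 0) break;  // border start cell (global: (0,0))
      unsigned char tb = tM[c];
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      if (std::toupper(a[i - 1]) == std::toupper(b[j - 1])) ++matches; else ++mismatches;
      --i; --j;
      if (tb == 3) break;  // local fresh start: this pair opened the alignment
      state = tb;
    } else if (state == 1) {
      ra.push_back(a[i - 1]); rb.push_back('-');
      ++gap_cols;
      if (tX[c] == 0) { state = 0; ++gap_opens; } // opening step
      --i;
    } else {
      ra.push_back('-'); rb.push_back(b[j - 1]);
      ++gap_cols;
      if (tY[c] == 0) { state = 0; ++gap_opens; }
      --j;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());

  return List::create(_["score"] = score, _["a_aln"] = ra, _["b_aln"] = rb,
                      _["a_start"] = (double)i, _["a_end"] = (double)ei,
                      _["b_start"] = (double)j, _["b_end"] = (double)ej,
                      _["matches"] = matches, _["mismatches"] = mismatches,
                      _["gap_opens"] = gap_opens, _["gap_cols"] = gap_cols,
                      _["ncols"] = (int)ra.size());
}

// Ungapped X-drop extension of an exact seed match at (qpos, spos)
// (0-based), seed length k. Returns the best ungapped segment score
// through the seed — the cheap prefilter that decides whether a seed
// cluster earns a gapped extension.

// [[Rcpp::export]]
int ungapped_extend_cpp(std::string a, std::string b, IntegerMatrix sub,
                        std::string alphabet, int qpos, int spos, int k,
                        int xdrop) {
  const long n = (long)a.size(), m = (long)b.size();
  const int A = (int)alphabet.size();
  std::vector<int> code(256, A - 1);
  for (size_t i = 0; i < alphabet.size(); ++i) {
    code[(unsigned char)std::toupper(alphabet[i])] = (int)i;
    code[(unsigned char)std::tolower(alphabet[i])] = (int)i;
  }
  std::vector<int> SUB(A * A);
  for (int r = 0; r < A; ++r)
    for (int cix = 0; cix < A; ++cix) SUB[r * A + cix] = sub(r, cix);
  auto sc = [&](long qi, long si) {
    return SUB[code[(unsigned char)a[qi]] * A + code[(unsigned char)b[si]]];
  };
  int score = 0;
  for (int t = 0; t < k; ++t) score += sc(qpos + t, spos + t);
  // extend right
  int run = 0, best_run = 0;
  for (long qi = qpos + k, si = spos + k; qi < n && si < m; ++qi, ++si) {
    run += sc(qi, si);
    if (run > best_run) best_run = run;
    if (best_run - run > xdrop) break;
  }
  score += best_run;
  // extend left
  run = 0; best_run = 0;
  for (long qi = qpos - 1, si = spos - 1; qi >= 0 && si >= 0; --qi, --si) {
    run += sc(qi, si);
    if (run > best_run) best_run = run;
    if (best_run - run > xdrop) break;
  }
  return score + best_run;
}

// Banded local (Smith-Waterman) alignment with affine gaps, restricted to
// diagonals d = j - i in [diag_lo, diag_hi]. Storage is (n+1) x W with
// W = diag_hi - diag_lo + 1, so memory stays linear in the query length
// for a fixed band; used for seed-guided extension of long queries.

// [[Rcpp::export]]
List align_banded_cpp(std::string a, std::string b, IntegerMatrix sub,
                      std::string alphabet, int gap_open, int gap_ext,
                      int diag_lo, int diag_hi) {
  const long n = (long)a.size(), m = (long)b.size();
  if (n == 0 || m == 0) stop("empty sequence");
  if (diag_hi < diag_lo) stop("empty band");
  const int NEG = INT_MIN / 4;
  const long W = (long)diag_hi - diag_lo + 1;

  const int A = (int)alphabet.size();
  std::vector<int> code(256, A - 1);
  for (size_t i = 0; i < alphabet.size(); ++i) {
    code[(unsigned char)std::toupper(alphabet[i])] = (int)i;
    code[(unsigned char)std::tolower(alphabet[i])] = (int)i;
  }
  std::vector<int> ai(n), bi(m);
  for (long i = 0; i < n; ++i) ai[i] = code[(unsigned char)a[i]];
  for (long j = 0; j < m; ++j) bi[j] = code[(unsigned char)b[j]];
  std::vector<int> SUB(A * A);
  for (int r = 0; r < A; ++r)
    for (int cix = 0; cix < A; ++cix) SUB[r * A + cix] = sub(r, cix);

  // score rows: previous and current, band-indexed k = (j - i) - diag_lo
  std::vector<int> Mp(W, NEG), Xp(W, NEG), Yp(W, NEG);
  std::vector<int> Mc(W, NEG), Xc(W, NEG), Yc(W, NEG);
  // full byte tracebacks
  std::vector<unsigned char> tM((n + 1) * W, 3), tX((n + 1) * W, 0),
      tY((n + 1) * W, 0);
  const int open_cost = gap_open + gap_ext;

  int best_score = 0;
  long best_i = 0, best_k = 0;
  // row 0: cells (0, j) with j in [diag_lo, diag_hi] are free starts
  for (long k = 0; k < W; ++k) {
    long j = k + diag_lo;
    Mp[k] = (j >= 0 && j <= m) ? 0 : NEG;
  }
  for (long i = 1; i <= n; ++i) {
    const int* srow = &SUB[ai[i - 1] * A];
    unsigned char* tMi = &tM[i * W];
    unsigned char* tXi = &tX[i * W];
    unsigned char* tYi = &tY[i * W];
    for (long k = 0; k < W; ++k) { Mc[k] = NEG; Xc[k] = NEG; Yc[k] = NEG; }
    long klo = std::max(0L, 1 - i - (long)diag_lo);
    long khi = std::min(W - 1, m - i - (long)diag_lo);
    for (long k = klo; k <= khi; ++k) {
      const long j = i + k + diag_lo;
      // M: diag neighbor is (i-1, j-1) -> same k in previous row
      int best = Mp[k];
      unsigned char tb = 0;
      if (Xp[k] > best) { best = Xp[k]; tb = 1; }
      if (Yp[k] > best) { best = Yp[k]; tb = 2; }
      if (best < 0) { best = 0; tb = 3; }
      const int mm = best + srow[bi[j - 1]];
      Mc[k] = mm; tMi[k] = tb;
      if (mm > best_score) { best_score = mm; best_i = i; best_k = k; }
      // X consumes a (up neighbor (i-1, j) -> k+1 in previous row)
      int xo = (k + 1 < W) ? Mp[k + 1] - open_cost : NEG;
      int xe = (k + 1 < W) ? Xp[k + 1] - gap_ext : NEG;
      if (xe > xo) { Xc[k] = xe; tXi[k] = 1; } else { Xc[k] = xo; tXi[k] = 0; }
      // Y consumes b (left neighbor (i, j-1) -> k-1 in current row)
      int yo = (k - 1 >= 0) ? Mc[k - 1] - open_cost : NEG;
      int ye = (k - 1 >= 0) ? Yc[k - 1] - gap_ext : NEG;
      if (ye > yo) { Yc[k] = ye; tYi[k] = 1; } else { Yc[k] = yo; tYi[k] = 0; }
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
  }

  if (best_score <= 0)
    return List::create(_["score"] = 0, _["a_aln"] = "", _["b_aln"] = "",
                        _["a_start"] = 0, _["a_end"] = 0,
                        _["b_start"] = 0, _["b_end"] = 0,
                        _["matches"] = 0, _["mismatches"] = 0,
                        _["gap_opens"] = 0, _["gap_cols"] = 0,
                        _["ncols"] = 0);

  // traceback from (best_i, best_k), state M
  std::string ra, rb;
  long i = best_i, k = best_k;
  int state = 0;
  int matches = 0, mismatches = 0, gap_opens = 0, gap_cols = 0;
  while (i > 0) {
    long j = i + k + diag_lo;
    if (j <= 0) break;
    if (state == 0) {
      unsigned char tb = tM[i * W + k];
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      if (std::toupper(a[i - 1]) == std::toupper(b[j - 1])) ++matches;
      else ++mismatches;
      --i;  // diag: same k
      if (tb == 3) break;
      state = tb;
    } else if (state == 1) {
      ra.push_back(a[i - 1]); rb.push_back('-');
      ++gap_cols;
      if (tX[i * W + k] == 0) { state = 0; ++gap_opens; }
      --i; ++k;
    } else {
      ra.push_back('-'); rb.push_back(b[j - 1]);
      ++gap_cols;
      if (tY[i * W + k] == 0) { state = 0; ++gap_opens; }
      --k;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  const long ei = best_i, ej = best_i + best_k + diag_lo;

  return List::create(_["score"] = best_score, _["a_aln"] = ra,
                      _["b_aln"] = rb,
                      _["a_start"] = (double)i,
                      _["a_end"] = (double)ei,
                      _["b_start"] = (double)(i + k + diag_lo),
                      _["b_end"] = (double)ej,
                      _["matches"] = matches, _["mismatches"] = mismatches,
                      _["gap_opens"] = gap_opens, _["gap_cols"] = gap_cols,
                      _["ncols"] = (int)ra.size());
}

// Mutate a nucleotide sequence under the Kimura two-parameter process for
// branch length d (expected substitutions/site), transition/transversion
// rate ratio kappa. Uses the closed-form K80 transition probabilities so
// multiple hits are modelled. `u` are pre-drawn uniforms (one per site) and
// `u2` pick among the two transversion targets.

// [[Rcpp::export]]
std::string k80_mutate_cpp(std::string s, double d, double kappa,
                           NumericVector u, NumericVector u2) {
  const double beta = 1.0 / (kappa + 2.0);
  const double alpha = kappa * beta;
  const double e4b = std::exp(-4.0 * beta * d);
  const double e2ab = std::exp(-2.0 * (alpha + beta) * d);
  const double p_ts = 0.25 + 0.25 * e4b - 0.5 * e2ab;
  const double p_tv = 0.5 - 0.5 * e4b;  // both transversions combined
  for (size_t i = 0; i < s.size(); ++i) {
    char c = (char)std::toupper(s[i]);
    if (c != 'A' && c != 'C' && c != 'G' && c != 'T') continue;
    double r = u[i];
    if (r < p_ts) {
      switch (c) {
        case 'A': s[i] = 'G'; break;
        case 'G': s[i] = 'A'; break;
        case 'C': s[i] = 'T'; break;
        case 'T': s[i] = 'C'; break;
      }
    } else if (r < p_ts + p_tv) {
      bool first = (u2[i] < 0.5);
      switch (c) {
        case 'A': s[i] = first ? 'C' : 'T'; break;
        case 'G': s[i] = first ? 'C' : 'T'; break;
        case 'C': s[i] = first ? 'A' : 'G'; break;
        case 'T': s[i] = first ? 'A' : 'G'; break;
      }
    } else {
      s[i] = c;
    }
  }
  return s;
}
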