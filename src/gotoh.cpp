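#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Affine-gap pairwise alignment (Gotoh three-state DP).
//
// Scoring convention: a gap of length k costs gap_open + gap_extend*(k-1),
// i.e. the first gapped column of a run pays gap_open and every further
// column pays gap_extend.  Traceback tie-break: diagonal > up > left
// (up = column consuming a / gap in b).  Moves: 0 diagonal, 1 up, 2 left.

static const double NEG = -1e30;
enum { ST_M = 0, ST_X = 1, ST_Y = 2, ST_START = 3 };

// [[Rcpp::export]]
List gotoh_pair_cpp(IntegerVector a, IntegerVector b, NumericMatrix sub,
                    double gap_open, double gap_extend,
                    bool local, bool end_gap_free) {
  const int n = a.size(), m = b.size();
  std::vector<unsigned char> pM((size_t)(n + 1) * (m + 1));
  std::vector<unsigned char> pX((size_t)(n + 1) * (m + 1));
  std::vector<unsigned char> pY((size_t)(n + 1) * (m + 1));
  std::vector<double> M0(m + 1), X0(m + 1), Y0(m + 1),
      M1(m + 1), X1(m + 1), Y1(m + 1);
  // best-of-states score along the last column, per row (for end_gap_free)
  std::vector<double> colBest(n + 1, NEG);
  std::vector<unsigned char> colSt(n + 1, ST_M);
  auto at = [m](int i, int j) { return (size_t)i * (m + 1) + j; };

  // row 0.  In local mode all borders are NEG: alignments begin only
  // through the explicit fresh-start option in the M recurrence.
  M0[0] = local ? NEG : 0.0; X0[0] = NEG; Y0[0] = NEG;
  for (int j = 1; j <= m; ++j) {
    M0[j] = NEG;
    X0[j] = NEG;
    if (local) {
      Y0[j] = NEG;
    } else {
      Y0[j] = end_gap_free ? 0.0 : -(gap_open + (j - 1) * gap_extend);
      pY[at(0, j)] = (j == 1) ? ST_M : ST_Y;
    }
  }
  { // last-column entry for row 0
    double v = M0[m]; unsigned char s = ST_M;
    if (X0[m] > v) { v = X0[m]; s = ST_X; }
    if (Y0[m] > v) { v = Y0[m]; s = ST_Y; }
    colBest[0] = v; colSt[0] = s;
  }

  double bestLoc = 0.0; int bi = 0, bj = 0; bool haveLoc = false;

  for (int i = 1; i <= n; ++i) {
    M1[0] = NEG;
    Y1[0] = NEG;
    if (local) {
      X1[0] = NEG;
    } else {
      X1[0] = end_gap_free ? 0.0 : -(gap_open + (i - 1) * gap_extend);
      pX[at(i, 0)] = (i == 1) ? ST_M : ST_X;
    }
    const int ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      // M: diagonal from (i-1, j-1)
      double best = M0[j - 1]; unsigned char st = ST_M;
      if (X0[j - 1] > best) { best = X0[j - 1]; st = ST_X; }
      if (Y0[j - 1] > best) { best = Y0[j - 1]; st = ST_Y; }
      if (local && 0.0 > best) { best = 0.0; st = ST_START; }
      M1[j] = sub(ai, b[j - 1]) + best;
      pM[at(i, j)] = st;
      // X (up): gap in b, consume a, from row i-1 same j
      best = M0[j] - gap_open; st = ST_M;
      if (X0[j] - gap_extend > best) { best = X0[j] - gap_extend; st = ST_X; }
      if (Y0[j] - gap_open > best) { best = Y0[j] - gap_open; st = ST_Y; }
      X1[j] = best; pX[at(i, j)] = st;
      // Y (left): gap in a, consume b, from (i, j-1)
      best = M1[j - 1] - gap_open; st = ST_M;
      if (X1[j - 1] - gap_open > best) { best = X1[j - 1] - gap_open; st = ST_X; }
      if (Y1[j - 1] - gap_extend > best) { best = Y1[j - 1] - gap_extend; st = ST_Y; }
      Y1[j] = best; pY[at(i, j)] = st;

      if (local && M1[j] > bestLoc) {
        bestLoc = M1[j]; bi = i; bj = j; haveLoc = true;
      }
    }
    { double v = M1[m]; unsigned char s = ST_M;
      if (X1[m] > v) { v = X1[m]; s = ST_X; }
      if (Y1[m] > v) { v = Y1[m]; s = ST_Y; }
      colBest[i] = v; colSt[i] = s; }
    std::swap(M0, M1); std::swap(X0, X1); std::swap(Y0, Y1);
  }
  // after the loop M0/X0/Y0 hold row n

  std::vector<int> path; // reversed moves
  double score; int ti, tj; unsigned char st;

  if (local) {
    if (!haveLoc || bestLoc <= 0.0) {
      return List::create(_["score"] = 0.0,
                          _["path"] = IntegerVector(0),
                          _["a_start"] = 0, _["a_end"] = 0,
                          _["b_start"] = 0, _["b_end"] = 0);
    }
    score = bestLoc; ti = bi; tj = bj; st = ST_M;
    while (true) {
      if (st == ST_M) {
        unsigned char p = pM[at(ti, tj)];
        path.push_back(0); --ti; --tj;
        if (p == ST_START || (ti == 0 && tj == 0)) break;
        st = p;
      } else if (st == ST_X) {
        unsigned char p = pX[at(ti, tj)];
        path.push_back(1); --ti; st = p;
      } else {
        unsigned char p = pY[at(ti, tj)];
        path.push_back(2); --tj; st = p;
      }
    }
    std::reverse(path.begin(), path.end());
    return List::create(_["score"] = score,
                        _["path"] = IntegerVector(path.begin(), path.end()),
                        _["a_start"] = ti, _["a_end"] = bi,
                        _["b_start"] = tj, _["b_end"] = bj);
  }

  // global: choose end cell (prefer (n,m); end_gap_free scans last row/col)
  ti = n; tj = m;
  score = colBest[n]; st = colSt[n];
  int tailUp = 0, tailLeft = 0;
  if (end_gap_free) {
    for (int i = n - 1; i >= 0; --i)
      if (colBest[i] > score) { score = colBest[i]; st = colSt[i]; ti = i; tj = m; }
    for (int j = m - 1; j >= 0; --j) {
      double v = M0[j]; unsigned char s = ST_M;
      if (X0[j] > v) { v = X0[j]; s = ST_X; }
      if (Y0[j] > v) { v = Y0[j]; s = ST_Y; }
      if (v > score) { score = v; st = s; ti = n; tj = j; }
    }
    tailUp = n - ti; tailLeft = m - tj;
  }
  for (int k = 0; k < tailLeft; ++k) path.push_back(2);
  for (int k = 0; k < tailUp; ++k) path.push_back(1);
  while (!(ti == 0 && tj == 0)) {
    if (st == ST_M) {
      unsigned char p = pM[at(ti, tj)];
      path.push_back(0); --ti; --tj; st = p;
    } else if (st == ST_X) {
      unsigned char p = pX[at(ti, tj)];
      path.push_back(1); --ti; st = p;
    } else {
      unsigned char p = pY[at(ti, tj)];
      path.push_back(2); --tj; st = p;
    }
  }
  std::reverse(path.begin(), path.end());
  return List::create(_["score"] = score,
                      _["path"] = IntegerVector(path.begin(), path.end()),
                      _["a_start"] = 0, _["a_end"] = n,
                      _["b_start"] = 0, _["b_end"] = m);
}

// Global affine alignment on a precomputed column-pair score matrix
// (profile-profile alignment).  Same conventions as gotoh_pair_cpp.
// [[Rcpp::export]]
List gotoh_matrix_cpp(NumericMatrix S, double gap_open, double gap_extend) {
  const int n = S.nrow(), m = S.ncol();
  std::vector<unsigned char> pM((size_t)(n + 1) * (m + 1));
  std::vector<unsigned char> pX((size_t)(n + 1) * (m + 1));
  std::vector<unsigned char> pY((size_t)(n + 1) * (m + 1));
  std::vector<double> M0(m + 1), X0(m + 1), Y0(m + 1),
      M1(m + 1), X1(m + 1), Y1(m + 1);
  auto at = [m](int i, int j) { return (size_t)i * (m + 1) + j; };
  M0[0] = 0.0; X0[0] = NEG; Y0[0] = NEG;
  for (int j = 1; j <= m; ++j) {
    M0[j] = NEG; X0[j] = NEG;
    Y0[j] = -(gap_open + (j - 1) * gap_extend);
    pY[at(0, j)] = (j == 1) ? ST_M : ST_Y;
  }
  for (int i = 1; i <= n; ++i) {
    M1[0] = NEG; Y1[0] = NEG;
    X1[0] = -(gap_open + (i - 1) * gap_extend);
    pX[at(i, 0)] = (i == 1) ? ST_M : ST_X;
    for (int j = 1; j <= m; ++j) {
      double best = M0[j - 1]; unsigned char st = ST_M;
      if (X0[j - 1] > best) { best = X0[j - 1]; st = ST_X; }
      if (Y0[j - 1] > best) { best = Y0[j - 1]; st = ST_Y; }
      M1[j] = S(i - 1, j - 1) + best; pM[at(i, j)] = st;
      best = M0[j] - gap_open; st = ST_M;
      if (X0[j] - gap_extend > best) { best = X0[j] - gap_extend; st = ST_X; }
      if (Y0[j] - gap_open > best) { best = Y0[j] - gap_open; st = ST_Y; }
      X1[j] = best; pX[at(i, j)] = st;
      best = M1[j - 1] - gap_open; st = ST_M;
      if (X1[j - 1] - gap_open > best) { best = X1[j - 1] - gap_open; st = ST_X; }
      if (Y1[j - 1] - gap_extend > best) { best = Y1[j - 1] - gap_extend; st = ST_Y; }
      Y1[j] = best; pY[at(i, j)] = st;
    }
    std::swap(M0, M1); std::swap(X0, X1); std::swap(Y0, Y1);
  }
  double score = M0[m]; unsigned char st = ST_M;
  if (X0[m] > score) { score = X0[m]; st = ST_X; }
  if (Y0[m] > score) { score = Y0[m]; st = ST_Y; }
  std::vector<int> path;
  int ti = n, tj = m;
  while (!(ti == 0 && tj == 0)) {
    if (st == ST_M) {
      unsigned char p = pM[at(ti, tj)];
      path.push_back(0); --ti; --tj; st = p;
    } else if (st == ST_X) {
      unsigned char p = pX[at(ti, tj)];
      path.push_back(1); --ti; st = p;
    } else {
      unsigned char p = pY[at(ti, tj)];
      path.push_back(2); --tj; st = p;
    }
  }
  std::reverse(path.begin(), path.end());
  return List::create(_["score"] = score,
                      _["path"] = IntegerVector(path.begin(), path.end()));
}

// Dot plot with dotmatcher semantics: for every diagonal, every window
// placement whose summed pairwise score >= threshold contributes its
// midpoint (0-based, offset floor(window/2) from the window start).
// [[Rcpp::export]]
IntegerMatrix dotplot_cpp(IntegerVector a, IntegerVector b, NumericMatrix sub,
                          int window, double threshold) {
  const int n = a.size(), m = b.size();
  std::vector<int> pi, pj;
  const int half = window / 2;
  for (int d = -(m - window); d <= n - window; ++d) {
    // diagonal: cells (i, i - d) with i in [max(0,d), min(n, m+d))
    int i0 = d > 0 ? d : 0;
    int iend = (m + d < n) ? (m + d) : n; // exclusive
    int L = iend - i0;
    if (L < window) continue;
    double s = 0.0;
    for (int k = 0; k < window; ++k)
      s += sub(a[i0 + k], b[i0 + k - d]);
    if (s >= threshold) { pi.push_back(i0 + half); pj.push_back(i0 + half - d); }
    for (int k = 1; k + window <= L; ++k) {
      s += sub(a[i0 + k + window - 1], b[i0 + k + window - 1 - d]) -
           sub(a[i0 + k - 1], b[i0 + k - 1 - d]);
      if (s >= threshold) {
        pi.push_back(i0 + k + half);
        pj.push_back(i0 + k + half - d);
      }
    }
  }
  IntegerMatrix out(pi.size(), 2);
  for (size_t r = 0; r < pi.size(); ++r) { out(r, 0) = pi[r]; out(r, 1) = pj[r]; }
  colnames(out) = CharacterVector::create("i", "j");
  return out;
}
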