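#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Affine-gap pairwise alignment (Gotoh). Sequences arrive as 1-based integer
// encodings into the rows/columns of the substitution matrix S. Gap scoring
// follows the BLAST convention: a gap of length L costs open + L * extend.
//
// local = true  -> Smith-Waterman (best local alignment)
// local = false -> Needleman-Wunsch with end gaps penalized

static const double NEG_INF = -1e18;

// [[Rcpp::export]]
List gotoh_align_cpp(IntegerVector ai, IntegerVector bi, NumericMatrix S,
                     double gap_open, double gap_extend, bool local) {
  const int n = ai.size(), m = bi.size();
  // M: match/mismatch ending; X: gap in b (consumes a); Y: gap in a (consumes b)
  std::vector<std::vector<double>> M(n + 1, std::vector<double>(m + 1, NEG_INF));
  std::vector<std::vector<double>> X(n + 1, std::vector<double>(m + 1, NEG_INF));
  std::vector<std::vector<double>> Y(n + 1, std::vector<double>(m + 1, NEG_INF));
  // explicit predecessor-state pointers (no float matching in the traceback);
  // 9 = local start / undefined
  std::vector<std::vector<uint8_t>> pM(n + 1, std::vector<uint8_t>(m + 1, 9));
  std::vector<std::vector<uint8_t>> pX(n + 1, std::vector<uint8_t>(m + 1, 9));
  std::vector<std::vector<uint8_t>> pY(n + 1, std::vector<uint8_t>(m + 1, 9));

  M[0][0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[i][0] = local ? 0.0 : -(gap_open + i * gap_extend);
    pX[i][0] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[0][j] = local ? 0.0 : -(gap_open + j * gap_extend);
    pY[0][j] = (j == 1) ? 0 : 2;
  }
  if (local) {
    for (int i = 1; i <= n; ++i) M[i][0] = 0.0;
    for (int j = 1; j <= m; ++j) M[0][j] = 0.0;
  }

  double best = 0.0;
  int best_i = 0, best_j = 0;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const double s = S(ai[i - 1] - 1, bi[j - 1] - 1);
      // diagonal: prefer M, then X, then Y on ties
      double diag = M[i - 1][j - 1]; uint8_t dstate = 0;
      if (X[i - 1][j - 1] > diag) { diag = X[i - 1][j - 1]; dstate = 1; }
      if (Y[i - 1][j - 1] > diag) { diag = Y[i - 1][j - 1]; dstate = 2; }
      double mm = diag + s;
      if (local && mm < 0.0) { mm = 0.0; dstate = 9; }
      M[i][j] = mm; pM[i][j] = dstate;

      double xo = std::max(M[i - 1][j], Y[i - 1][j]) - (gap_open + gap_extend);
      double xe = X[i - 1][j] - gap_extend;
      if (xe >= xo) { X[i][j] = xe; pX[i][j] = 1; }
      else {
        X[i][j] = xo;
        pX[i][j] = (M[i - 1][j] >= Y[i - 1][j]) ? 0 : 2;
      }

      double yo = std::max(M[i][j - 1], X[i][j - 1]) - (gap_open + gap_extend);
      double ye = Y[i][j - 1] - gap_extend;
      if (ye >= yo) { Y[i][j] = ye; pY[i][j] = 2; }
      else {
        Y[i][j] = yo;
        pY[i][j] = (M[i][j - 1] >= X[i][j - 1]) ? 0 : 1;
      }

      if (local) {
        double here = std::max(M[i][j], std::max(X[i][j], Y[i][j]));
        if (here > best) { best = here; best_i = i; best_j = j; }
      }
    }
  }

  int i, j, state; // state 0 = M, 1 = X, 2 = Y
  double score;
  if (local) {
    score = best; i = best_i; j = best_j;
    state = 0;
    if (i > 0 && j > 0) {
      if (M[i][j] >= X[i][j] && M[i][j] >= Y[i][j]) state = 0;
      else if (X[i][j] >= Y[i][j]) state = 1;
      else state = 2;
    }
  } else {
    i = n; j = m;
    if (M[i][j] >= X[i][j] && M[i][j] >= Y[i][j]) { state = 0; score = M[i][j]; }
    else if (X[i][j] >= Y[i][j]) { state = 1; score = X[i][j]; }
    else { state = 2; score = Y[i][j]; }
  }

  std::vector<int> out_a, out_b; // aligned columns, 0 marks a gap
  while (!(i == 0 && j == 0)) {
    if (local && state == 0 && M[i][j] <= 0.0) break; // local alignment start
    uint8_t prev;
    if (state == 0) {
      prev = pM[i][j];
      out_a.push_back(ai[i - 1]); out_b.push_back(bi[j - 1]);
      --i; --j;
      if (local && prev == 9) break; // the local alignment's first pair
    } else if (state == 1) {
      prev = pX[i][j];
      out_a.push_back(ai[i - 1]); out_b.push_back(0);
      --i;
    } else {
      prev = pY[i][j];
      out_a.push_back(0); out_b.push_back(bi[j - 1]);
      --j;
    }
    if (prev == 9) {
      if (local) break;
      // global boundary: continue along the exhausted-sequence edge
      prev = (i > 0) ? 1 : 2;
      if (i == 0 && j == 0) break;
    }
    state = prev;
  }

  std::reverse(out_a.begin(), out_a.end());
  std::reverse(out_b.begin(), out_b.end());
  return List::create(_["score"] = score,
                      _["a"] = IntegerVector(out_a.begin(), out_a.end()),
                      _["b"] = IntegerVector(out_b.begin(), out_b.end()),
                      _["a_start"] = i + 1, _["b_start"] = j + 1);
}

// Score-only alignment of every query against every subject (for RBH ortholog
// mapping and panel classification). Rolling rows keep memory linear.
// [[Rcpp::export]]
NumericMatrix gotoh_score_many_cpp(List queries, List subjects, NumericMatrix S,
                                   double gap_open, double gap_extend, bool local) {
  const int nq = queries.size(), ns = subjects.size();
  NumericMatrix out(nq, ns);
  for (int q = 0; q < nq; ++q) {
    IntegerVector ai = queries[q];
    const int n = ai.size();
    for (int s = 0; s < ns; ++s) {
      IntegerVector bi = subjects[s];
      const int m = bi.size();
      std::vector<double> Mprev(m + 1), Xprev(m + 1), Yprev(m + 1);
      std::vector<double> Mcur(m + 1), Xcur(m + 1), Ycur(m + 1);
      Mprev[0] = 0.0; Xprev[0] = NEG_INF; Yprev[0] = NEG_INF;
      for (int j = 1; j <= m; ++j) {
        Mprev[j] = local ? 0.0 : NEG_INF;
        Xprev[j] = NEG_INF;
        Yprev[j] = local ? 0.0 : -(gap_open + j * gap_extend);
      }
      double best = 0.0;
      for (int i = 1; i <= n; ++i) {
        Mcur[0] = local ? 0.0 : NEG_INF;
        Xcur[0] = local ? 0.0 : -(gap_open + i * gap_extend);
        Ycur[0] = NEG_INF;
        const int a = ai[i - 1] - 1;
        for (int j = 1; j <= m; ++j) {
          double diag = std::max(Mprev[j - 1], std::max(Xprev[j - 1], Yprev[j - 1]));
          double mm = diag + S(a, bi[j - 1] - 1);
          if (local && mm < 0.0) mm = 0.0;
          Mcur[j] = mm;
          Xcur[j] = std::max(std::max(Mprev[j], Yprev[j]) - (gap_open + gap_extend),
                             Xprev[j] - gap_extend);
          Ycur[j] = std::max(std::max(Mcur[j - 1], Xcur[j - 1]) - (gap_open + gap_extend),
                             Ycur[j - 1] - gap_extend);
          if (local) {
            double here = std::max(Mcur[j], std::max(Xcur[j], Ycur[j]));
            if (here > best) best = here;
          }
        }
        std::swap(Mprev, Mcur); std::swap(Xprev, Xcur); std::swap(Yprev, Ycur);
      }
      if (local) {
        out(q, s) = best;
      } else {
        out(q, s) = std::max(Mprev[m], std::max(Xprev[m], Yprev[m]));
      }
    }
  }
  return out;
}
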