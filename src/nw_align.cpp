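#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Three-state affine-gap global alignment (Needleman-Wunsch / Gotoh).
// States: M (a_i ~ b_j), X (a_i ~ gap), Y (gap ~ b_j).
// A gap of length L costs gap_open + (L - 1) * gap_extend.
// Terminal gap runs are free unless penalize_end_gaps is true.
// Tie-break everywhere: M preferred over X preferred over Y, which makes the
// traceback (and hence identity statistics) fully deterministic.

static const double NEG = -std::numeric_limits<double>::infinity();

// pick the best of (m, x, y) with preference order M > X > Y on ties
static inline int argmax3(double m, double x, double y, double& best) {
  best = m; int s = 0;
  if (x > best) { best = x; s = 1; }
  if (y > best) { best = y; s = 2; }
  return s;
}

// [[Rcpp::export]]
List nw_align_cpp(IntegerVector a, IntegerVector b, NumericMatrix S,
                  double gap_open, double gap_extend, bool penalize_end_gaps) {
  const int m = a.size(), n = b.size();
  if (m == 0 || n == 0) stop("sequences must be nonempty");
  const size_t ncell = (size_t)(m + 1) * (size_t)(n + 1);
  std::vector<double> M(ncell, NEG), X(ncell, NEG), Y(ncell, NEG);
  // pointer = previous state (0/1/2); -1 marks origin
  std::vector<signed char> pM(ncell, -1), pX(ncell, -1), pY(ncell, -1);
  const size_t W = (size_t)(n + 1);
#define IDX(i, j) ((size_t)(i) * W + (size_t)(j))

  M[IDX(0, 0)] = 0.0;
  for (int i = 1; i <= m; ++i) {
    X[IDX(i, 0)] = penalize_end_gaps ? -(gap_open + (i - 1) * gap_extend) : 0.0;
    pX[IDX(i, 0)] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= n; ++j) {
    Y[IDX(0, j)] = penalize_end_gaps ? -(gap_open + (j - 1) * gap_extend) : 0.0;
    pY[IDX(0, j)] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= m; ++i) {
    const double* Srow = &S(a[i - 1] - 1, 0);
    const int snrow = S.nrow();
    for (int j = 1; j <= n; ++j) {
      double best;
      // M
      int s = argmax3(M[IDX(i - 1, j - 1)], X[IDX(i - 1, j - 1)], Y[IDX(i - 1, j - 1)], best);
      if (best > NEG) {
        M[IDX(i, j)] = best + Srow[(size_t)(b[j - 1] - 1) * snrow];
        pM[IDX(i, j)] = (signed char)s;
      }
      // X: consume a_i, gap in b
      s = argmax3(M[IDX(i - 1, j)] - gap_open,
                  X[IDX(i - 1, j)] - gap_extend,
                  Y[IDX(i - 1, j)] - gap_open, best);
      if (best > NEG) { X[IDX(i, j)] = best; pX[IDX(i, j)] = (signed char)s; }
      // Y: consume b_j, gap in a
      s = argmax3(M[IDX(i, j - 1)] - gap_open,
                  X[IDX(i, j - 1)] - gap_open,
                  Y[IDX(i, j - 1)] - gap_extend, best);
      if (best > NEG) { Y[IDX(i, j)] = best; pY[IDX(i, j)] = (signed char)s; }
    }
  }

  // choose the end cell; with free end gaps the remaining tail of one
  // sequence is appended as a zero-cost terminal gap run
  int bi = m, bj = n, bstate;
  double bscore;
  bstate = argmax3(M[IDX(m, n)], X[IDX(m, n)], Y[IDX(m, n)], bscore);
  if (!penalize_end_gaps) {
    for (int i = m - 1; i >= 0; --i) {     // trailing gap in b, prefer longer i
      double v; int s = argmax3(M[IDX(i, n)], X[IDX(i, n)], Y[IDX(i, n)], v);
      if (v > bscore) { bscore = v; bi = i; bj = n; bstate = s; }
    }
    for (int j = n - 1; j >= 0; --j) {     // trailing gap in a
      double v; int s = argmax3(M[IDX(m, j)], X[IDX(m, j)], Y[IDX(m, j)], v);
      if (v > bscore) { bscore = v; bi = m; bj = j; bstate = s; }
    }
  }
  if (bscore == NEG) stop("no feasible alignment");

  std::vector<int> outa, outb;
  outa.reserve(m + n); outb.reserve(m + n);
  // terminal gap columns after the chosen end cell
  for (int j = n; j > bj; --j) { outa.push_back(0); outb.push_back(j); }
  for (int i = m; i > bi; --i) { outa.push_back(i); outb.push_back(0); }

  int i = bi, j = bj, st = bstate;
  while (i > 0 || j > 0) {
    signed char prev;
    if (st == 0) {
      prev = pM[IDX(i, j)];
      outa.push_back(i); outb.push_back(j); --i; --j;
    } else if (st == 1) {
      prev = pX[IDX(i, j)];
      outa.push_back(i); outb.push_back(0); --i;
    } else {
      prev = pY[IDX(i, j)];
      outa.push_back(0); outb.push_back(j); --j;
    }
    if (prev < 0) break;
    st = prev;
  }
  std::reverse(outa.begin(), outa.end());
  std::reverse(outb.begin(), outb.end());
#undef IDX
  return List::create(_["a_pos"] = wrap(outa), _["b_pos"] = wrap(outb),
                      _["score"] = bscore);
}
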