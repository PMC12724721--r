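#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Gotoh affine-gap pairwise alignment over integer-encoded sequences.
//
// Sequences arrive as 1-based indices into the substitution matrix `sub`.
// Penalties: opening a gap costs gap_open, every gap residue (including the
// first) costs gap_ext, so a gap of length L costs gap_open + L * gap_ext.
//
// Traceback tie-breaks are fixed so that results are fully deterministic and
// reproducible by an independent implementation using the same rules:
//   * local mode start cell: highest M; ties broken by smallest i, then j
//   * state M sources at equal value: M > X > Y > (local) stop
//   * state X (gap in b, consumes a): close gap (M) preferred over extend (X)
//   * state Y (gap in a, consumes b): close gap (M) preferred over extend (Y)
//   * global end state at (n, m): M > X > Y

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// traceback codes
enum { SRC_M = 0, SRC_X = 1, SRC_Y = 2, SRC_STOP = 3 };

// [[Rcpp::export(name = ".align_pair_cpp")]]
List align_pair_cpp(IntegerVector a, IntegerVector b, NumericMatrix sub,
                    double gap_open, double gap_ext, bool local) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("empty sequence");
  const double go = gap_open + gap_ext;  // cost of first gap residue
  const double ge = gap_ext;

  // DP values, row-major (n+1) x (m+1)
  std::vector<double> M((n + 1) * (m + 1), NEG_INF);
  std::vector<double> X((n + 1) * (m + 1), NEG_INF);
  std::vector<double> Y((n + 1) * (m + 1), NEG_INF);
  // traceback: which state fed each cell's value
  std::vector<signed char> tM((n + 1) * (m + 1), SRC_STOP);
  std::vector<signed char> tX((n + 1) * (m + 1), SRC_STOP);
  std::vector<signed char> tY((n + 1) * (m + 1), SRC_STOP);

  #define AT(i, j) ((i) * (m + 1) + (j))

  M[AT(0, 0)] = 0.0;
  if (!local) {
    for (int i = 1; i <= n; ++i) {
      X[AT(i, 0)] = -go - (i - 1) * ge;
      tX[AT(i, 0)] = (i == 1) ? SRC_M : SRC_X;
    }
    for (int j = 1; j <= m; ++j) {
      Y[AT(0, j)] = -go - (j - 1) * ge;
      tY[AT(0, j)] = (j == 1) ? SRC_M : SRC_Y;
    }
  } else {
    for (int i = 0; i <= n; ++i) M[AT(i, 0)] = 0.0;
    for (int j = 0; j <= m; ++j) M[AT(0, j)] = 0.0;
  }

  double best = local ? 0.0 : NEG_INF;
  int best_i = 0, best_j = 0;

  for (int i = 1; i <= n; ++i) {
    const int ai = a[i - 1] - 1;
    for (int j = 1; j <= m; ++j) {
      const int bj = b[j - 1] - 1;
      const double s = sub(ai, bj);

      // M: consume a_i and b_j
      double vm = M[AT(i - 1, j - 1)], vx = X[AT(i - 1, j - 1)],
             vy = Y[AT(i - 1, j - 1)];
      double mv = vm; signed char msrc = SRC_M;
      if (vx > mv) { mv = vx; msrc = SRC_X; }
      if (vy > mv) { mv = vy; msrc = SRC_Y; }
      double cand = (mv == NEG_INF) ? NEG_INF : mv + s;
      if (local && cand < 0.0) { cand = 0.0; msrc = SRC_STOP; }
      M[AT(i, j)] = cand; tM[AT(i, j)] = msrc;

      // X: gap in b (consume a_i)
      double xo = (M[AT(i - 1, j)] == NEG_INF) ? NEG_INF : M[AT(i - 1, j)] - go;
      double xe = (X[AT(i - 1, j)] == NEG_INF) ? NEG_INF : X[AT(i - 1, j)] - ge;
      if (xo >= xe) { X[AT(i, j)] = xo; tX[AT(i, j)] = SRC_M; }
      else          { X[AT(i, j)] = xe; tX[AT(i, j)] = SRC_X; }

      // Y: gap in a (consume b_j)
      double yo = (M[AT(i, j - 1)] == NEG_INF) ? NEG_INF : M[AT(i, j - 1)] - go;
      double ye = (Y[AT(i, j - 1)] == NEG_INF) ? NEG_INF : Y[AT(i, j - 1)] - ge;
      if (yo >= ye) { Y[AT(i, j)] = yo; tY[AT(i, j)] = SRC_M; }
      else          { Y[AT(i, j)] = ye; tY[AT(i, j)] = SRC_Y; }

      if (local && M[AT(i, j)] > best) {
        best = M[AT(i, j)]; best_i = i; best_j = j;
      }
    }
  }

  int end_state;
  if (local) {
    end_state = SRC_M;
  } else {
    best_i = n; best_j = m;
    double vm = M[AT(n, m)], vx = X[AT(n, m)], vy = Y[AT(n, m)];
    best = vm; end_state = SRC_M;
    if (vx > best) { best = vx; end_state = SRC_X; }
    if (vy > best) { best = vy; end_state = SRC_Y; }
  }

  // traceback
  // Local mode ends when the path is in state M at a cell of value 0 (an
  // empty-prefix start cell); global mode ends at (0, 0).
  std::vector<int> cols_a, cols_b;  // 1-based indices, 0 = gap
  int i = best_i, j = best_j, state = end_state;
  bool run = !(local && best == 0.0);
  while (run) {
    if (local) {
      if (state == SRC_M && M[AT(i, j)] == 0.0) break;
    } else {
      if (i == 0 && j == 0) break;
    }
    if (state == SRC_M) {
      signed char src = tM[AT(i, j)];
      cols_a.push_back(i); cols_b.push_back(j);
      --i; --j;
      state = (src == SRC_STOP) ? SRC_M : src;
    } else if (state == SRC_X) {
      signed char src = tX[AT(i, j)];
      cols_a.push_back(i); cols_b.push_back(0);
      --i;
      state = src;
    } else {  // SRC_Y
      signed char src = tY[AT(i, j)];
      cols_a.push_back(0); cols_b.push_back(j);
      --j;
      state = src;
    }
  }

  const int L = cols_a.size();
  IntegerVector a_idx(L), b_idx(L);
  int n_match = 0;
  for (int k = 0; k < L; ++k) {  // reverse into alignment order
    const int ca = cols_a[L - 1 - k], cb = cols_b[L - 1 - k];
    a_idx[k] = ca == 0 ? NA_INTEGER : ca;
    b_idx[k] = cb == 0 ? NA_INTEGER : cb;
    if (ca > 0 && cb > 0 && a[ca - 1] == b[cb - 1]) ++n_match;
  }

  int a_start = 0, a_end = 0, b_start = 0, b_end = 0;
  for (int k = 0; k < L; ++k) {
    if (a_idx[k] != NA_INTEGER) { if (a_start == 0) a_start = a_idx[k]; a_end = a_idx[k]; }
    if (b_idx[k] != NA_INTEGER) { if (b_start == 0) b_start = b_idx[k]; b_end = b_idx[k]; }
  }

  return List::create(
    _["score"] = best, _["n_match"] = n_match, _["align_len"] = L,
    _["a_start"] = a_start, _["a_end"] = a_end,
    _["b_start"] = b_start, _["b_end"] = b_end,
    _["a_idx"] = a_idx, _["b_idx"] = b_idx);
}
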