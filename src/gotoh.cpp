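#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Global (end-gap penalised) affine-gap alignment, Gotoh three-state
// recursion. A gap of length L costs open + L * extend. Sequences arrive
// as 0-based integer codes indexing the substitution matrix.

static const double NEG = -std::numeric_limits<double>::infinity();

// ends_free = overlap alignment: leading/trailing gaps cost nothing
// (database-search semantics); otherwise fully global.
// [[Rcpp::export(name = ".gotoh_score_multi")]]
NumericVector gotoh_score_multi(IntegerVector a, List bs, NumericMatrix sub,
                                double open, double extend,
                                bool ends_free = false) {
  const int n = a.size();
  const int nb = bs.size();
  NumericVector out(nb);
  std::vector<double> M0(n + 1), X0(n + 1), Y0(n + 1);
  std::vector<double> M1(n + 1), X1(n + 1), Y1(n + 1);
  for (int k = 0; k < nb; ++k) {
    IntegerVector b = bs[k];
    const int m = b.size();
    M0[0] = 0.0; X0[0] = NEG; Y0[0] = NEG;
    for (int i = 1; i <= n; ++i) {
      M0[i] = ends_free ? 0.0 : NEG;
      X0[i] = ends_free ? NEG : -(open + i * extend);  // gap in b consuming a
      Y0[i] = NEG;
    }
    double best_edge = NEG;  // best score ending on the i = n edge (ends_free)
    for (int j = 1; j <= m; ++j) {
      M1[0] = ends_free ? 0.0 : NEG;
      X1[0] = NEG;
      Y1[0] = ends_free ? NEG : -(open + j * extend);  // gap in a consuming b
      const int bj = b[j - 1];
      for (int i = 1; i <= n; ++i) {
        const double diag = std::max(M0[i - 1], std::max(X0[i - 1], Y0[i - 1]));
        M1[i] = diag + sub(a[i - 1], bj);
        const double mx = std::max(M1[i - 1], Y1[i - 1]) - (open + extend);
        X1[i] = std::max(mx, X1[i - 1] - extend);
        const double my = std::max(M0[i], X0[i]) - (open + extend);
        Y1[i] = std::max(my, Y0[i] - extend);
      }
      if (ends_free && j < m) {
        best_edge = std::max(best_edge, std::max(M1[n], std::max(X1[n], Y1[n])));
      }
      std::swap(M0, M1); std::swap(X0, X1); std::swap(Y0, Y1);
    }
    double fin = std::max(M0[n], std::max(X0[n], Y0[n]));
    if (ends_free) {
      for (int i = 1; i <= n; ++i) {
        fin = std::max(fin, std::max(M0[i], std::max(X0[i], Y0[i])));
      }
      fin = std::max(fin, best_edge);
    }
    out[k] = fin;
  }
  return out;
}

// Traceback tie preference: diagonal, then up (gap in b, consuming a),
// then left (gap in a, consuming b). States: 0 = M, 1 = X (up), 2 = Y (left).
// [[Rcpp::export(name = ".gotoh_align")]]
List gotoh_align(IntegerVector a, IntegerVector b, NumericMatrix sub,
                 double open, double extend) {
  const int n = a.size(), m = b.size();
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  M(0, 0) = 0.0; X(0, 0) = NEG; Y(0, 0) = NEG;
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = NEG; X(i, 0) = -(open + i * extend); Y(i, 0) = NEG;
  }
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NEG; X(0, j) = NEG; Y(0, j) = -(open + j * extend);
  }
  for (int j = 1; j <= m; ++j) {
    for (int i = 1; i <= n; ++i) {
      const double diag = std::max(M(i - 1, j - 1),
                                   std::max(X(i - 1, j - 1), Y(i - 1, j - 1)));
      M(i, j) = diag + sub(a[i - 1], b[j - 1]);
      X(i, j) = std::max(std::max(M(i - 1, j), Y(i - 1, j)) - (open + extend),
                         X(i - 1, j) - extend);
      Y(i, j) = std::max(std::max(M(i, j - 1), X(i, j - 1)) - (open + extend),
                         Y(i, j - 1) - extend);
    }
  }
  // final state, preferring M then X then Y on ties
  int state = 0;
  double best = M(n, m);
  if (X(n, m) > best) { best = X(n, m); state = 1; }
  if (Y(n, m) > best) { best = Y(n, m); state = 2; }
  const double score = best;

  std::vector<int> pa, pb;  // residue index per column (0 = gap)
  int i = n, j = m;
  const double eps = 1e-9;
  while (i > 0 || j > 0) {
    if (state == 0) {
      // diagonal move into (i-1, j-1); choose predecessor state M > X > Y
      pa.push_back(i); pb.push_back(j);
      const double need = M(i, j) - sub(a[i - 1], b[j - 1]);
      --i; --j;
      if (i == 0 && j == 0) break;
      if (std::abs(M(i, j) - need) < eps) state = 0;
      else if (std::abs(X(i, j) - need) < eps) state = 1;
      else state = 2;
    } else if (state == 1) {
      pa.push_back(i); pb.push_back(0);
      const double here = X(i, j);
      // predecessor at (i-1, j): opened here (from M or Y) or extended (X)
      if (std::abs(M(i - 1, j) - (open + extend) - here) < eps) state = 0;
      else if (std::abs(X(i - 1, j) - extend - here) < eps) state = 1;
      else state = 2;
      --i;
    } else {
      pa.push_back(0); pb.push_back(j);
      const double here = Y(i, j);
      if (std::abs(M(i, j - 1) - (open + extend) - here) < eps) state = 0;
      else if (std::abs(X(i, j - 1) - (open + extend) - here) < eps) state = 1;
      else state = 2;
      --j;
    }
    if (i == 0 && j == 0) break;
    if (i == 0 && state != 2) state = 2;
    if (j == 0 && state != 1) state = 1;
  }
  std::reverse(pa.begin(), pa.end());
  std::reverse(pb.begin(), pb.end());
  return List::create(_["score"] = score,
                      _["pos_a"] = IntegerVector(pa.begin(), pa.end()),
                      _["pos_b"] = IntegerVector(pb.begin(), pb.end()));
}
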