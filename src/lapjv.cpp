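#include <Rcpp.h>
#include <vector>
#include <limits>

using namespace Rcpp;

// Dense square linear assignment by shortest augmenting paths with
// potentials (Jonker-Volgenant style, O(n^3)). Costs may contain large
// "forbidden" values; the caller guarantees a finite-cost perfect matching
// exists. Ties are broken by scanning columns in increasing index order,
// which makes the returned matching deterministic.
//
// Returns a 0-based column index for every row.
// [[Rcpp::export(name = ".lap_solve_dense")]]
IntegerVector lap_solve_dense(NumericMatrix cost) {
  const int n = cost.nrow();
  if (cost.ncol() != n) stop("cost matrix must be square");
  if (n == 0) return IntegerVector(0);

  const double INF = std::numeric_limits<double>::infinity();
  // 1-based with a dummy column 0, as in the classical formulation.
  std::vector<double> u(n + 1, 0.0), v(n + 1, 0.0), minv(n + 1, 0.0);
  std::vector<int> p(n + 1, 0), way(n + 1, 0);
  std::vector<char> used(n + 1, 0);

  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::fill(minv.begin(), minv.end(), INF);
    std::fill(used.begin(), used.end(), 0);
    do {
      used[j0] = 1;
      const int i0 = p[j0];
      double delta = INF;
      int j1 = -1;
      for (int j = 1; j <= n; ++j) {
        if (used[j]) continue;
        const double cur = cost(i0 - 1, j - 1) - u[i0] - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      if (j1 < 0) stop("assignment infeasible");
      for (int j = 0; j <= n; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do {
      const int j1 = way[j0];
      p[j0] = p[j1];
      j0 = j1;
    } while (j0);
  }

  IntegerVector assign(n);
  for (int j = 1; j <= n; ++j) assign[p[j] - 1] = j - 1;
  return assign;
}
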