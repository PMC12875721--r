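#include <Rcpp.h>
using namespace Rcpp;

// Exact maximisation of sum_{i<j, c_i == c_j} B(i,j) over all set
// partitions of n nodes, by branch and bound over restricted-growth
// assignments. B is the (symmetric) pairwise modularity gain matrix
// B_ij = w_ij - k_i * k_j / (2m); the caller converts the optimal pair sum
// S into Q = (2S + sum_i B_ii) / (2m).
//
// Admissible bound: with nodes 0..t-1 assigned, every still-open pair
// (max index >= t) can contribute at most max(0, B_ij), so
// UB = S_current + remain[t] where remain is a precomputed suffix sum.
// Placing each remaining node in its own community realises the zero
// alternative, so the bound is tight enough to prune hard once a good
// incumbent exists (communities with strongly positive internal B are
// found early because callers pass nodes in decreasing strength order).

namespace {

struct BBState {
  int n;
  const double *B;       // column-major n x n
  std::vector<double> remain;
  std::vector<int> assign, best_assign;
  double S, bestS;
  static constexpr double eps = 1e-12;

  double b(int i, int j) const { return B[i + n * j]; }

  void search(int t, int ncomm) {
    if (t == n) {
      if (S > bestS + eps) {
        bestS = S;
        best_assign = assign;
      }
      return;
    }
    if (S + remain[t] <= bestS + eps) return;  // cannot beat incumbent
    // gain[c] = sum of B(i,t) over assigned i in community c
    std::vector<double> gain(ncomm, 0.0);
    for (int i = 0; i < t; ++i) gain[assign[i]] += b(i, t);
    for (int c = 0; c <= ncomm; ++c) {   // c == ncomm opens a new community
      double g = (c < ncomm) ? gain[c] : 0.0;
      assign[t] = c;
      S += g;
      search(t + 1, c < ncomm ? ncomm : ncomm + 1);
      S -= g;
    }
    assign[t] = -1;
  }
};

}  // namespace

// [[Rcpp::export]]
List bb_max_pair_sum(NumericMatrix B) {
  int n = B.nrow();
  if (n != B.ncol()) stop("B must be square");
  BBState st;
  st.n = n;
  st.B = B.begin();
  st.assign.assign(n, -1);
  st.best_assign.assign(n, 0);
  st.S = 0.0;
  st.bestS = -std::numeric_limits<double>::infinity();
  // remain[t]: sum over pairs i<j with j >= t of max(0, B_ij)
  st.remain.assign(n + 1, 0.0);
  for (int t = n - 1; t >= 0; --t) {
    double add = 0.0;
    for (int i = 0; i < t; ++i) add += std::max(0.0, st.b(i, t));
    st.remain[t] = st.remain[t + 1] + add;
  }
  st.search(0, 0);
  IntegerVector memb(n);
  for (int i = 0; i < n; ++i) memb[i] = st.best_assign[i] + 1;
  return List::create(_["membership"] = memb, _["pair_sum"] = st.bestS);
}
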