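#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected components over a channel x frequency x time grid.
// state: -1 / 0 / +1 per grid point (column-major, ch fastest).
// Connectivity: same sign AND (neighbouring channel at same freq/time,
// adjacent frequency bin at same channel/time, or adjacent time bin at
// same channel/freq).  adj: per-channel 0-based neighbour index vectors.
static void label_components(const std::vector<int>& state,
                             const std::vector<std::vector<int>>& adj,
                             int nch, int nf, int nt,
                             std::vector<int>& labels, int& n_clusters) {
  const int P = nch * nf * nt;
  labels.assign(P, 0);
  n_clusters = 0;
  std::vector<int> stack;
  stack.reserve(256);
  for (int p = 0; p < P; ++p) {
    if (state[p] == 0 || labels[p] != 0) continue;
    const int sgn = state[p];
    ++n_clusters;
    labels[p] = n_clusters;
    stack.clear();
    stack.push_back(p);
    while (!stack.empty()) {
      const int q = stack.back();
      stack.pop_back();
      const int ch = q % nch;
      const int rest = q / nch;
      const int f = rest % nf;
      const int t = rest / nf;
      // frequency neighbours
      if (f > 0) {
        const int r = q - nch;
        if (state[r] == sgn && labels[r] == 0) { labels[r] = n_clusters; stack.push_back(r); }
      }
      if (f < nf - 1) {
        const int r = q + nch;
        if (state[r] == sgn && labels[r] == 0) { labels[r] = n_clusters; stack.push_back(r); }
      }
      // time neighbours
      if (t > 0) {
        const int r = q - nch * nf;
        if (state[r] == sgn && labels[r] == 0) { labels[r] = n_clusters; stack.push_back(r); }
      }
      if (t < nt - 1) {
        const int r = q + nch * nf;
        if (state[r] == sgn && labels[r] == 0) { labels[r] = n_clusters; stack.push_back(r); }
      }
      // channel neighbours (same f, t)
      const int base = f * nch + t * nch * nf;
      for (int nb : adj[ch]) {
        const int r = base + nb;
        if (state[r] == sgn && labels[r] == 0) { labels[r] = n_clusters; stack.push_back(r); }
      }
    }
  }
}

static std::vector<std::vector<int>> build_adj(const List& adj_list) {
  std::vector<std::vector<int>> adj(adj_list.size());
  for (int i = 0; i < adj_list.size(); ++i) {
    IntegerVector v = adj_list[i];
    adj[i].assign(v.begin(), v.end());
  }
  return adj;
}

// [[Rcpp::export]]
IntegerVector label_clusters_cpp(IntegerVector state, List adj_list,
                                 int nch, int nf, int nt) {
  std::vector<int> st(state.begin(), state.end());
  std::vector<std::vector<int>> adj = build_adj(adj_list);
  std::vector<int> labels;
  int k = 0;
  label_components(st, adj, nch, nf, nt, labels, k);
  IntegerVector out(labels.begin(), labels.end());
  out.attr("n_clusters") = k;
  return out;
}

// For each permutation row of `stats` (n_perm x P): threshold against lo/hi,
// label clusters, and return the maximal positive cluster mass and maximal
// absolute negative cluster mass.  `usable[p] == 0` excludes a point.
// [[Rcpp::export]]
NumericMatrix perm_max_mass_cpp(NumericMatrix stats, NumericVector lo,
                                NumericVector hi, IntegerVector usable,
                                List adj_list, int nch, int nf, int nt) {
  const int n_perm = stats.nrow();
  const int P = stats.ncol();
  std::vector<std::vector<int>> adj = build_adj(adj_list);
  NumericMatrix out(n_perm, 2);
  std::vector<int> state(P), labels;
  for (int i = 0; i < n_perm; ++i) {
    for (int p = 0; p < P; ++p) {
      double s = stats(i, p);
      if (!usable[p] || !R_finite(s)) state[p] = 0;
      else if (s > hi[p]) state[p] = 1;
      else if (s < lo[p]) state[p] = -1;
      else state[p] = 0;
    }
    int k = 0;
    label_components(state, adj, nch, nf, nt, labels, k);
    double max_pos = 0.0, max_neg = 0.0;
    if (k > 0) {
      std::vector<double> mass(k + 1, 0.0);
      for (int p = 0; p < P; ++p)
        if (labels[p] > 0) mass[labels[p]] += stats(i, p);
      for (int c = 1; c <= k; ++c) {
        if (mass[c] > max_pos) max_pos = mass[c];
        if (-mass[c] > max_neg) max_neg = -mass[c];
      }
    }
    out(i, 0) = max_pos;
    out(i, 1) = max_neg;
  }
  return out;
}
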