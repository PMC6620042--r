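// Greedy two-phase Louvain community detection on a dense symmetric
// non-negative weight matrix. Local moving uses best-gain moves over a
// seeded-random node order (own Fisher-Yates on a mt19937 stream so a
// given seed is reproducible across platforms), followed by community
// aggregation, repeated until no further improvement. Nodes move only on a
// strict modularity gain (current community wins ties), so each sweep is
// monotone in Q and the local-moving loop terminates.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <numeric>

using namespace Rcpp;

// [[Rcpp::export]]
IntegerVector louvain_cpp(NumericMatrix W0, double gamma, int seed) {
  const int n0 = W0.nrow();
  const double eps = 1e-12;
  std::mt19937 rng(static_cast<uint32_t>(seed));

  std::vector<std::vector<double>> w(n0, std::vector<double>(n0));
  double v = 0.0;
  for (int i = 0; i < n0; ++i)
    for (int j = 0; j < n0; ++j) {
      w[i][j] = W0(i, j);
      v += w[i][j];
    }

  // membership of the original nodes in the current level's super-nodes
  std::vector<int> node2super(n0);
  std::iota(node2super.begin(), node2super.end(), 0);

  int m = n0;
  while (true) {
    std::vector<double> s(m, 0.0);
    for (int i = 0; i < m; ++i)
      for (int j = 0; j < m; ++j) s[i] += w[i][j];

    std::vector<int> comm(m);
    std::iota(comm.begin(), comm.end(), 0);
    std::vector<double> stot(s);
    std::vector<int> csize(m, 1);

    bool level_changed = false;
    bool moved = true;
    std::vector<int> order(m);
    std::vector<double> kin(m);
    while (moved) {
      moved = false;
      // seeded Fisher-Yates shuffle of the visiting order
      std::iota(order.begin(), order.end(), 0);
      for (int i = m - 1; i > 0; --i) {
        int j = static_cast<int>(rng() % static_cast<uint32_t>(i + 1));
        std::swap(order[i], order[j]);
      }
      for (int oi = 0; oi < m; ++oi) {
        const int i = order[oi];
        const int ci = comm[i];
        std::fill(kin.begin(), kin.end(), 0.0);
        for (int j = 0; j < m; ++j)
          if (j != i && w[i][j] != 0.0) kin[comm[j]] += w[i][j];
        // remove i from its community
        stot[ci] -= s[i];
        csize[ci] -= 1;
        // gain of community c relative to i sitting alone; staying put
        // wins ties so moves happen only on strict improvement
        double best_gain = kin[ci] - gamma * s[i] * stot[ci] / v;
        int best_c = ci;
        for (int c = 0; c < m; ++c) {
          if (c == ci || csize[c] == 0) continue;
          double gain = kin[c] - gamma * s[i] * stot[c] / v;
          if (gain > best_gain + eps) {
            best_gain = gain;
            best_c = c;
          }
        }
        if (best_gain < -eps) {
          // leaving for an empty community is the best move; one must
          // exist because i's old community was not a singleton
          for (int c = 0; c < m; ++c)
            if (csize[c] == 0) { best_c = c; break; }
        }
        stot[best_c] += s[i];
        csize[best_c] += 1;
        if (best_c != ci) {
          comm[i] = best_c;
          moved = true;
          level_changed = true;
        }
      }
    }

    // relabel communities consecutively
    std::vector<int> relab(m, -1);
    int k = 0;
    for (int i = 0; i < m; ++i)
      if (relab[comm[i]] < 0) relab[comm[i]] = k++;
    for (int i = 0; i < m; ++i) comm[i] = relab[comm[i]];

    for (int i = 0; i < n0; ++i) node2super[i] = comm[node2super[i]];

    if (!level_changed || k == m) break;

    // aggregate: super-node weights are the summed within/between weights
    std::vector<std::vector<double>> w2(k, std::vector<double>(k, 0.0));
    for (int i = 0; i < m; ++i)
      for (int j = 0; j < m; ++j) w2[comm[i]][comm[j]] += w[i][j];
    w = std::move(w2);
    m = k;
  }

  IntegerVector out(n0);
  for (int i = 0; i < n0; ++i) out[i] = node2super[i] + 1;
  return out;
}
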