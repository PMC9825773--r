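#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include "rng.h"

using namespace Rcpp;

// CSR out-adjacency: adj[offset[v] .. offset[v+1]) are the (sorted)
// out-neighbours of v, all 0-based.

static inline bool has_neighbor(const std::vector<int> &adj,
                                const std::vector<int> &offset,
                                int v, int x) {
  return std::binary_search(adj.begin() + offset[v],
                            adj.begin() + offset[v + 1], x);
}

// One second-order step: successor distribution over out-neighbours of
// curr with unnormalized weights 1/p (back to prev), 1 (out-neighbour of
// prev), 1/q (otherwise).
static int biased_step(const std::vector<int> &adj,
                       const std::vector<int> &offset,
                       int prev, int curr, double p, double q,
                       std::vector<double> &wbuf, XRng &rng) {
  int beg = offset[curr], end = offset[curr + 1];
  int deg = end - beg;
  if (deg == 0) return -1;
  wbuf.resize(deg);
  double total = 0.0;
  for (int i = 0; i < deg; ++i) {
    int s = adj[beg + i];
    double w;
    if (s == prev)
      w = 1.0 / p;
    else if (has_neighbor(adj, offset, prev, s))
      w = 1.0;
    else
      w = 1.0 / q;
    total += w;
    wbuf[i] = total;
  }
  double u = rng.unif() * total;
  int lo = 0, hi = deg - 1;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (wbuf[mid] <= u) lo = mid + 1; else hi = mid;
  }
  return adj[beg + lo];
}

// [[Rcpp::export(name = ".cpp_generate_walks")]]
IntegerMatrix cpp_generate_walks(int n_nodes, IntegerVector offset0,
                                 IntegerVector adj0, double p, double q,
                                 int num_walks, int walk_length,
                                 double seed) {
  std::vector<int> offset(offset0.begin(), offset0.end());
  std::vector<int> adj(adj0.begin(), adj0.end());
  XRng rng(static_cast<uint64_t>(seed));
  IntegerMatrix walks(n_nodes * num_walks, walk_length);
  std::vector<int> order(n_nodes);
  for (int i = 0; i < n_nodes; ++i) order[i] = i;
  std::vector<double> wbuf;

  int row = 0;
  for (int rep = 0; rep < num_walks; ++rep) {
    // Fisher-Yates shuffle of start-node order per repetition
    for (int i = n_nodes - 1; i > 0; --i) {
      int j = static_cast<int>(rng.below(i + 1));
      std::swap(order[i], order[j]);
    }
    for (int k = 0; k < n_nodes; ++k, ++row) {
      int start = order[k];
      walks(row, 0) = start + 1;
      int beg = offset[start], deg = offset[start + 1] - beg;
      if (deg == 0 || walk_length == 1) continue;  // truncated walk
      int curr = adj[beg + rng.below(deg)];        // first step uniform
      walks(row, 1) = curr + 1;
      int prev = start;
      for (int t = 2; t < walk_length; ++t) {
        int nxt = biased_step(adj, offset, prev, curr, p, q, wbuf, rng);
        if (nxt < 0) break;
        walks(row, t) = nxt + 1;
        prev = curr;
        curr = nxt;
      }
    }
  }
  return walks;
}
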