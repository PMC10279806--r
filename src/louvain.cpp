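#include <Rcpp.h>
using namespace Rcpp;

// One greedy phase of Louvain on a dense (possibly signed) modularity matrix.
// Nodes are visited in the given order; each node moves to the community
// maximizing the gain in sum_{same community pairs} B, until a full pass
// makes no move. Ties keep the current community, otherwise the lowest
// community id wins. comm is 1-based on the R side; order is a 1-based
// permutation. Returns the final 1-based assignment.
// [[Rcpp::export]]
IntegerVector louvain_phase_cpp(NumericMatrix B, IntegerVector comm0,
                                IntegerVector order) {
  const int n = B.nrow();
  std::vector<int> comm(n);
  for (int i = 0; i < n; ++i) comm[i] = comm0[i] - 1;
  // keep slots for up to n communities so a node can always split off on
  // its own (with signed weights, isolating a node can carry positive gain)
  const int nslot = n;
  std::vector<int> size(nslot, 0);
  for (int i = 0; i < n; ++i) ++size[comm[i]];

  std::vector<double> links(nslot);
  bool moved = true;
  while (moved) {
    moved = false;
    for (int oi = 0; oi < n; ++oi) {
      const int v = order[oi] - 1;
      const int cv = comm[v];
      std::fill(links.begin(), links.end(), 0.0);
      for (int j = 0; j < n; ++j) {
        if (j == v) continue;
        links[comm[j]] += B(v, j);
      }
      int best = cv;
      double best_val = links[cv];
      int empty_slot = -1;
      for (int c = 0; c < nslot; ++c) {
        if (c == cv) continue;
        if (size[c] == 0) {            // candidate: isolate v (gain -links[cv])
          if (empty_slot < 0) empty_slot = c;
          continue;
        }
        if (links[c] > best_val) { best_val = links[c]; best = c; }
        // exact tie with a non-current community: lowest id among the tied
        else if (links[c] == best_val && best != cv && c < best) best = c;
      }
      if (empty_slot >= 0 && size[cv] > 1 && 0.0 > best_val) {
        best = empty_slot;
        best_val = 0.0;
      }
      if (best != cv) {
        comm[v] = best;
        --size[cv];
        ++size[best];
        moved = true;
      }
    }
  }
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = comm[i] + 1;
  return out;
}

// Aggregate a modularity matrix by community: Bagg[c, d] = sum of B[i, j]
// over i in c, j in d. comm is 1-based with communities 1..K.
// [[Rcpp::export]]
NumericMatrix aggregate_matrix_cpp(NumericMatrix B, IntegerVector comm,
                                   int ncomm) {
  const int n = B.nrow();
  NumericMatrix out(ncomm, ncomm);
  for (int i = 0; i < n; ++i) {
    const int ci = comm[i] - 1;
    for (int j = 0; j < n; ++j) {
      out(ci, comm[j] - 1) += B(i, j);
    }
  }
  return out;
}
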