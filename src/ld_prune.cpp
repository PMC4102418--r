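#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Greedy keep-best pruning on the conflict graph (r2 >= r2_max).
//
// ord:       0-based SNP indices in visiting order (ascending priority,
//            ties already broken by SNP id on the R side).
// adj_start: CSR row pointers (length n + 1) into adj_idx.
// adj_idx:   0-based neighbor indices (symmetric adjacency).
//
// Returns a logical keep-flag per SNP: a SNP is kept iff none of its
// conflict-graph neighbors has been kept before it in the visiting order.
// [[Rcpp::export]]
LogicalVector cpp_ld_prune(IntegerVector ord, IntegerVector adj_start,
                           IntegerVector adj_idx) {
  const int n = ord.size();
  std::vector<char> kept(n, 0);
  LogicalVector out(n);
  for (int v = 0; v < n; ++v) {
    const int i = ord[v];
    bool ok = true;
    for (int e = adj_start[i]; e < adj_start[i + 1]; ++e) {
      if (kept[adj_idx[e]]) { ok = false; break; }
    }
    if (ok) kept[i] = 1;
    out[i] = kept[i] != 0;
  }
  return out;
}
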