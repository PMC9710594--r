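#include <Rcpp.h>
using namespace Rcpp;

// All receptor x ligand atom pairs with distance strictly below cutoff.
// Exact all-pairs scan; instance sizes here (<= a few thousand atoms per
// body) never justify a spatial index.
// [[Rcpp::export]]
IntegerMatrix cross_pairs_within(NumericMatrix a, NumericMatrix b,
                                 double cutoff) {
  const int n = a.nrow(), m = b.nrow();
  const double c2 = cutoff * cutoff;
  std::vector<int> ri, li;
  for (int i = 0; i < n; ++i) {
    const double ax = a(i, 0), ay = a(i, 1), az = a(i, 2);
    for (int j = 0; j < m; ++j) {
      const double dx = ax - b(j, 0), dy = ay - b(j, 1), dz = az - b(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < c2) { ri.push_back(i + 1); li.push_back(j + 1); }
    }
  }
  IntegerMatrix out(ri.size(), 2);
  for (size_t k = 0; k < ri.size(); ++k) { out(k, 0) = ri[k]; out(k, 1) = li[k]; }
  return out;
}
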