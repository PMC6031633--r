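#include <Rcpp.h>
using namespace Rcpp;

// Per-species triad position census. `a` is the 0/1 adjacency matrix
// (a(i,j) = 1 means link i -> j), `table` the 64 x 3 lookup giving, for every
// labelled 3-node code, the global catalog slot of each member node (0 when
// the code is not weakly connected). Row index of `table` is code + 1.
// [[Rcpp::export]]
IntegerMatrix triad_role_census(IntegerMatrix a, IntegerMatrix table,
                                int n_slots) {
  const int n = a.nrow();
  IntegerMatrix counts(n, n_slots);
  for (int i = 0; i < n - 2; ++i) {
    for (int j = i + 1; j < n - 1; ++j) {
      const int base = a(i, j) + 2 * a(j, i);
      for (int k = j + 1; k < n; ++k) {
        const int code = base + 4 * a(i, k) + 8 * a(k, i) +
                         16 * a(j, k) + 32 * a(k, j);
        if (code == 0) continue;
        const int s1 = table(code, 0);
        if (s1 == 0) continue;
        counts(i, s1 - 1) += 1;
        counts(j, table(code, 1) - 1) += 1;
        counts(k, table(code, 2) - 1) += 1;
      }
    }
  }
  return counts;
}
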