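#include <Rcpp.h>
using namespace Rcpp;

// Greedy non-overlapping interval selection. Candidates are visited in the
// order given by `ord` (0-based indices into start/end); a candidate is
// kept iff none of its positions is already covered by a kept candidate.
// start/end are 1-based inclusive and must lie within [span_lo, span_hi].
// [[Rcpp::export]]
LogicalVector greedy_select_cpp(IntegerVector start, IntegerVector end,
                                IntegerVector ord,
                                int span_lo, int span_hi) {
  int len = span_hi - span_lo + 1;
  std::vector<char> occ(len, 0);
  LogicalVector keep(start.size(), false);
  for (int u = 0; u < ord.size(); ++u) {
    int i = ord[u];
    int s = start[i] - span_lo, e = end[i] - span_lo;
    if (s < 0 || e >= len) stop("candidate outside span");
    bool free_ = true;
    for (int p = s; p <= e; ++p)
      if (occ[p]) { free_ = false; break; }
    if (free_) {
      for (int p = s; p <= e; ++p) occ[p] = 1;
      keep[i] = true;
    }
  }
  return keep;
}
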