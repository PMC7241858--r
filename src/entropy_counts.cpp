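#include <Rcpp.h>
using namespace Rcpp;

// Template-pattern match counting for sample entropy.
//
// Templates are the m-length windows that still admit an (m+1)-th
// continuation, i.e. start indices i = 0 .. N-m-1 (0-based), so that both
// the m-length and the (m+1)-length comparison run over the same template
// pairs and pm1 <= pm holds by construction.  Distance is the Chebyshev
// (max-abs) norm; a match is distance <= bound.  Ordered pairs, i != j,
// self-matches excluded.  Counts are returned as doubles: for N = 20000
// they exceed .Machine$integer.max but stay exactly representable.

// [[Rcpp::export]]
List count_matches_cpp(NumericVector x, int m, double bound) {
  const int n = x.size();
  const int nt = n - m; // templates admitting a continuation: i in [0, nt-1]
  if (nt < 2)
    stop("segment too short for counting (need length > m+1)");
  double pm = 0.0, pm1 = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      bool match_m = true;
      for (int k = 0; k < m; ++k) {
        if (std::abs(x[i + k] - x[j + k]) > bound) { match_m = false; break; }
      }
      if (!match_m) continue;
      pm += 2.0; // ordered pairs
      if (std::abs(x[i + m] - x[j + m]) <= bound) pm1 += 2.0;
    }
  }
  return List::create(_["pm"] = pm, _["pm1"] = pm1);
}
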