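#include <Rcpp.h>
using namespace Rcpp;

// Luria-Delbruck (Lea-Coulson) mutant-count pmf by the Ma-Sandri-Sarkar
// recursion:
//   p_0 = exp(-m)
//   p_n = (m / n) * sum_{i=0}^{n-1} p_i / (n - i + 1)
// Evaluated with precomputed reciprocals; O(n_max^2) but cheap in compiled
// code for the count ranges the estimator sees.
// [[Rcpp::export(name = ".ld_pmf_cpp")]]
NumericVector ld_pmf_cpp(double m, int n_max) {
  if (m < 0) stop("m must be >= 0");
  if (n_max < 0) stop("n_max must be >= 0");
  NumericVector p(n_max + 1);
  p[0] = std::exp(-m);
  if (n_max == 0 || m == 0.0) return p;
  std::vector<double> recip(n_max + 2);
  for (int k = 0; k <= n_max + 1; ++k) recip[k] = 1.0 / (k + 1.0);
  for (int n = 1; n <= n_max; ++n) {
    double s = 0.0;
    // accumulate small-to-large: late terms p_{n-1}/2 dominate
    for (int i = 0; i < n; ++i) s += p[i] * recip[n - i];
    p[n] = m * s / n;
  }
  return p;
}
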