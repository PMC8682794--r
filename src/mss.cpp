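#include <Rcpp.h>
using namespace Rcpp;

// Ma-Sandri-Sarkar recursion for the Luria-Delbruck mutant-count pmf:
// p_0 = exp(-m); p_r = (m / r) * sum_{i=0}^{r-1} p_i / (r - i + 1).
// [[Rcpp::export]]
NumericVector mss_pmf_cpp(double m, int r_max) {
  NumericVector p(r_max + 1);
  p[0] = std::exp(-m);
  if (m <= 0.0 || r_max < 1) return p;
  for (int r = 1; r <= r_max; ++r) {
    double s = 0.0;
    for (int i = 0; i < r; ++i) s += p[i] / (double)(r - i + 1);
    p[r] = (m / (double)r) * s;
  }
  return p;
}

// Binomial thinning of a latent count pmf with plating fraction f:
// q_k = sum_r p_r * dbinom(k, r, f), for k = 0..k_max. The inner sum is
// restricted to the latent window where the binomial kernel has mass.
// [[Rcpp::export]]
NumericVector mss_thin_cpp(NumericVector p, double f, int k_max) {
  int r_max = p.size() - 1;
  NumericVector q(k_max + 1);
  for (int k = 0; k <= k_max; ++k) {
    double centre = (k + 1.0) / f;
    double halfw = 10.0 * std::sqrt(centre * (1.0 - f)) / f + 20.0;
    int lo = std::max(k, (int)std::floor(centre - halfw));
    int hi = std::min(r_max, (int)std::ceil(centre + halfw));
    double s = 0.0;
    for (int r = lo; r <= hi; ++r) {
      s += p[r] * R::dbinom((double)k, (double)r, f, 0);
    }
    q[k] = s;
  }
  return q;
}
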