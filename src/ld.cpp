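#include <Rcpp.h>
using namespace Rcpp;

// Luria-Delbruck mutant-count pmf by the Ma-Sandri-Sarkar recursion:
//   p_0 = exp(-m);  p_k = (m/k) * sum_{i=0}^{k-1} p_i / (k - i + 1)
// [[Rcpp::export(name = ".ld_pmf_cpp")]]
NumericVector ld_pmf_cpp(double m, int k_max) {
  if (m < 0) stop("m must be >= 0");
  if (k_max < 0) stop("k_max must be >= 0");
  NumericVector p(k_max + 1);
  p[0] = std::exp(-m);
  for (int k = 1; k <= k_max; ++k) {
    double s = 0.0;
    for (int i = 0; i < k; ++i) s += p[i] / (double)(k - i + 1);
    p[k] = (m / (double)k) * s;
  }
  return p;
}

// pmf and its derivative dp/dm, for Newton/score iterations:
//   q_0 = -exp(-m);  q_k = p_k/m + (m/k) * sum q_i / (k - i + 1)
// [[Rcpp::export(name = ".ld_pmf_grad_cpp")]]
List ld_pmf_grad_cpp(double m, int k_max) {
  if (m <= 0) stop("m must be > 0 for the derivative recursion");
  NumericVector p(k_max + 1), q(k_max + 1);
  p[0] = std::exp(-m);
  q[0] = -p[0];
  for (int k = 1; k <= k_max; ++k) {
    double s = 0.0, t = 0.0;
    for (int i = 0; i < k; ++i) {
      double w = 1.0 / (double)(k - i + 1);
      s += p[i] * w;
      t += q[i] * w;
    }
    p[k] = (m / (double)k) * s;
    q[k] = p[k] / m + (m / (double)k) * t;
  }
  return List::create(_["p"] = p, _["dp"] = q);
}
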