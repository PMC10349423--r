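#include <Rcpp.h>
#include <cfloat>
using namespace Rcpp;

// Log-likelihood contribution of one quadrature-order group of blocks, and
// optionally its gradient in (alpha, gamma). Row i of Tn/logW holds the
// Gauss-Jacobi nodes/log-weights of block i; the mixture mean at node t is
// alpha*beta_t + gamma*beta_n + (1 - alpha - gamma)*t, which stays strictly
// inside (0, 1) for feasible (alpha, gamma), so all logs are finite.
// [[Rcpp::export]]
List cpp_group_loglik(const NumericMatrix& Tn, const NumericMatrix& logW,
                      const NumericVector& M, const NumericVector& NmM,
                      const NumericVector& beta_t, const NumericVector& beta_n,
                      double alpha, double gamma, bool grad) {
  const int nr = Tn.nrow(), nc = Tn.ncol();
  const double s = 1.0 - alpha - gamma;
  std::vector<double> ll(nc), bb(nc);
  double val = 0.0, ga = 0.0, gg = 0.0;
  for (int i = 0; i < nr; ++i) {
    const double ci = alpha * beta_t[i] + gamma * beta_n[i];
    const double mi = M[i], ni = NmM[i];
    // split loops so the compiler can vectorize the transcendentals;
    // all quantities stay finite (b is strictly inside (0,1))
    for (int j = 0; j < nc; ++j) {
      const double b = ci + s * Tn(i, j);
      bb[j] = b;
      ll[j] = logW(i, j) + mi * std::log(b) + ni * std::log1p(-b);
    }
    double mx = -DBL_MAX;
    for (int j = 0; j < nc; ++j) if (ll[j] > mx) mx = ll[j];
    double S = 0.0, sa = 0.0, sg = 0.0;
    for (int j = 0; j < nc; ++j) ll[j] = std::exp(ll[j] - mx);
    for (int j = 0; j < nc; ++j) S += ll[j];
    if (grad) {
      for (int j = 0; j < nc; ++j) {
        const double b = bb[j];
        const double wd = ll[j] * (mi / b - ni / (1.0 - b));
        sa += wd * (beta_t[i] - Tn(i, j));
        sg += wd * (beta_n[i] - Tn(i, j));
      }
    }
    val += mx + std::log(S);
    if (grad) {
      ga += sa / S;
      gg += sg / S;
    }
  }
  if (!grad) return List::create(Named("value") = val);
  return List::create(Named("value") = val,
                      Named("grad") = NumericVector::create(ga, gg));
}
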