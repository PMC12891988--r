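#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Fused in-place Adam step with bias correction. The fusion layer of the
// monogram network holds ~17M parameters; doing this update with R vector
// arithmetic would allocate several full-size temporaries per step, so it
// is a single C++ pass instead. The caller guarantees w/m/v are owned by
// the optimizer state and never aliased elsewhere.
// [[Rcpp::export]]
void adam_update_inplace(NumericVector w, NumericVector m, NumericVector v,
                         NumericVector g, double lr, double beta1,
                         double beta2, double eps, int t) {
  R_xlen_t n = w.size();
  if (m.size() != n || v.size() != n || g.size() != n)
    stop("adam_update_inplace: length mismatch");
  double c1 = 1.0 - std::pow(beta1, (double)t);
  double c2 = 1.0 - std::pow(beta2, (double)t);
  for (R_xlen_t i = 0; i < n; ++i) {
    double gi = g[i];
    double mi = beta1 * m[i] + (1.0 - beta1) * gi;
    double vi = beta2 * v[i] + (1.0 - beta2) * gi * gi;
    m[i] = mi;
    v[i] = vi;
    w[i] -= lr * (mi / c1) / (std::sqrt(vi / c2) + eps);
  }
}
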