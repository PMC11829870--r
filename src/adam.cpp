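// In-place Adam update for one parameter block. w, m, v are modified
// directly; the caller owns these buffers (they are never shared with
// user-visible objects until training finishes).
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".adam_step_inplace")]]
void adam_step_inplace(NumericVector w, NumericVector g, NumericVector m,
                       NumericVector v, double lr, double b1, double b2,
                       double eps, int step, double l2) {
  const int n = w.size();
  const double c1 = 1.0 - std::pow(b1, (double)step);
  const double c2 = 1.0 - std::pow(b2, (double)step);
  for (int i = 0; i < n; ++i) {
    double gi = g[i] + l2 * w[i];
    m[i] = b1 * m[i] + (1.0 - b1) * gi;
    v[i] = b2 * v[i] + (1.0 - b2) * gi * gi;
    w[i] -= lr * (m[i] / c1) / (std::sqrt(v[i] / c2) + eps);
  }
}

// [[Rcpp::export(name = ".sgd_step_inplace")]]
void sgd_step_inplace(NumericVector w, NumericVector g, double lr,
                      double l2) {
  const int n = w.size();
  for (int i = 0; i < n; ++i) w[i] -= lr * (g[i] + l2 * w[i]);
}
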