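// small in-place utilities for the optimiser
#include <Rcpp.h>
using namespace Rcpp;

// zero a numeric object in place (gradient buffers between steps)
// [[Rcpp::export]]
void k_zero(NumericVector x) {
  std::fill(x.begin(), x.end(), 0.0);
}

// in-place SGD with momentum: v = mom*v + g (+ wd*w); w -= lr*v
// [[Rcpp::export]]
void k_sgd_step(NumericVector w, NumericVector g, NumericVector v,
                double lr, double mom, double wd) {
  const int n = w.size();
  double *pw = w.begin(), *pv = v.begin();
  const double *pg = g.begin();
  for (int i = 0; i < n; ++i) {
    pv[i] = mom * pv[i] + pg[i] + wd * pw[i];
    pw[i] -= lr * pv[i];
  }
}
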