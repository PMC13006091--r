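// Single-pass tanh-GELU kernels; the forward caches tanh(u) so the
// backward avoids a second transcendental sweep.

#include <Rcpp.h>
#include "fastmath.h"
using namespace Rcpp;

static const double C0 = 0.7978845608028654;  // sqrt(2/pi)
static const double C1 = 0.044715;

// [[Rcpp::export]]
List gelu_fwd_cpp(NumericVector x) {
  R_xlen_t n = x.size();
  NumericVector out(n), th(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double xi = x[i];
    double t = fast_tanh(C0 * (xi + C1 * xi * xi * xi));
    th[i] = t;
    out[i] = 0.5 * xi * (1.0 + t);
  }
  out.attr("dim") = x.attr("dim");
  return List::create(_["out"] = out, _["tanh_u"] = th);
}

// [[Rcpp::export]]
NumericVector gelu_bwd_cpp(NumericVector x, NumericVector th, NumericVector dout) {
  R_xlen_t n = x.size();
  NumericVector dx(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double xi = x[i], t = th[i];
    double g = 0.5 * (1.0 + t) +
      0.5 * xi * (1.0 - t * t) * C0 * (1.0 + 3.0 * C1 * xi * xi);
    dx[i] = dout[i] * g;
  }
  dx.attr("dim") = dout.attr("dim");
  return dx;
}
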