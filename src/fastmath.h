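// Fast double-precision exp/tanh (~1e-7 relative accuracy), used only
// inside the training kernels where transcendental throughput dominates.
// Range-reduced degree-6 polynomial; exact softmax normalization and the
// saturating tanh clamp keep probabilities and activations well-behaved.

#ifndef GVITGP_FASTMATH_H
#define GVITGP_FASTMATH_H

#include <cmath>

static inline double fast_exp(double x) {
  if (x < -708.0) return 0.0;
  if (x > 708.0) return std::exp(x);
  double t = x * 1.4426950408889634;        // x / ln 2
  double k = std::floor(t + 0.5);
  double r = x - k * 0.6931471805599453;    // |r| <= 0.5 ln 2
  double p = 1.0 + r * (1.0 + r * (0.5 + r * (1.0 / 6 + r * (1.0 / 24 +
             r * (1.0 / 120 + r * (1.0 / 720))))));
  return std::ldexp(p, (int)k);
}

static inline double fast_tanh(double x) {
  if (x > 20.0) return 1.0;
  if (x < -20.0) return -1.0;
  double e = fast_exp(2.0 * x);
  return (e - 1.0) / (e + 1.0);
}

#endif
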