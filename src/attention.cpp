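// Batched multi-head attention core (forward + backward).
//
// Token batches arrive as R arrays [B, S, D] (column-major, D last); they
// are repacked once into contiguous per-sample S x D slices so the
// per-(sample, head) score/softmax/context algebra runs on cache-friendly
// submatrices. Attention probabilities are returned with layout
// [Sq, Sk, nh, B]. Dense projections stay in R where BLAS handles them.

#include <RcppArmadillo.h>
#include "fastmath.h"
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// repack [B, S, D] R array -> cube(S, D, B)
static arma::cube repack_in(const NumericVector& A, int B, int S, int D) {
  arma::cube C(S, D, B);
  const double* a = A.begin();
  for (int d = 0; d < D; ++d)
    for (int s = 0; s < S; ++s) {
      const double* col = a + (long)B * (s + (long)S * d);
      for (int b = 0; b < B; ++b) C(s, d, b) = col[b];
    }
  return C;
}

// repack cube(S, D, B) -> [B, S, D] R array
static NumericVector repack_out(const arma::cube& C, int B, int S, int D) {
  NumericVector A((long)B * S * D);
  double* a = A.begin();
  for (int d = 0; d < D; ++d)
    for (int s = 0; s < S; ++s) {
      double* col = a + (long)B * (s + (long)S * d);
      for (int b = 0; b < B; ++b) col[b] = C(s, d, b);
    }
  A.attr("dim") = IntegerVector::create(B, S, D);
  return A;
}

// [[Rcpp::export]]
List attn_core_fwd(NumericVector Q, NumericVector K, NumericVector V,
                   int nh, Nullable<NumericMatrix> relb,
                   Nullable<IntegerMatrix> RI) {
  IntegerVector dq = Q.attr("dim");
  IntegerVector dkv = K.attr("dim");
  int B = dq[0], Sq = dq[1], D = dq[2], Sk = dkv[1];
  int dk = D / nh;
  double scale = 1.0 / std::sqrt((double)dk);

  arma::cube Qc = repack_in(Q, B, Sq, D);
  arma::cube Kc = repack_in(K, B, Sk, D);
  arma::cube Vc = repack_in(V, B, Sk, D);
  arma::cube Cx(Sq, D, B, arma::fill::zeros);
  arma::cube Pc(Sq, Sk, (long)B * nh);

  bool has_bias = relb.isNotNull() && RI.isNotNull();
  arma::mat bias;
  if (has_bias) {
    NumericMatrix rb(relb.get());
    IntegerMatrix ri(RI.get());
    bias.set_size(Sq, (long)Sk * nh);
    for (int h = 0; h < nh; ++h)
      for (int k2 = 0; k2 < Sk; ++k2)
        for (int j = 0; j < Sq; ++j)
          bias(j, (long)h * Sk + k2) = rb(ri(j, k2) - 1, h);
  }

  for (int b = 0; b < B; ++b) {
    for (int h = 0; h < nh; ++h) {
      int c0 = h * dk;
      arma::mat Sc = Qc.slice(b).cols(c0, c0 + dk - 1) *
        Kc.slice(b).cols(c0, c0 + dk - 1).t() * scale;
      if (has_bias) Sc += bias.cols((long)h * Sk, (long)h * Sk + Sk - 1);
      arma::vec mx = arma::max(Sc, 1);
      Sc.each_col() -= mx;
      Sc.for_each([](arma::mat::elem_type& v) { v = fast_exp(v); });
      arma::vec rs = arma::sum(Sc, 1);
      Sc.each_col() /= rs;
      Pc.slice((long)b * nh + h) = Sc;
      Cx.slice(b).cols(c0, c0 + dk - 1) = Sc * Vc.slice(b).cols(c0, c0 + dk - 1);
    }
  }
  NumericVector P(Pc.begin(), Pc.end());
  P.attr("dim") = IntegerVector::create(Sq, Sk, nh, B);
  return List::create(_["ctx"] = repack_out(Cx, B, Sq, D), _["P"] = P);
}

// [[Rcpp::export]]
List attn_core_bwd(NumericVector Q, NumericVector K, NumericVector V,
                   NumericVector P, NumericVector dctx, int nh,
                   bool has_bias, int relb_rows,
                   Nullable<IntegerMatrix> RI) {
  IntegerVector dq = Q.attr("dim");
  IntegerVector dkv = K.attr("dim");
  int B = dq[0], Sq = dq[1], D = dq[2], Sk = dkv[1];
  int dk = D / nh;
  double scale = 1.0 / std::sqrt((double)dk);

  arma::cube Qc = repack_in(Q, B, Sq, D);
  arma::cube Kc = repack_in(K, B, Sk, D);
  arma::cube Vc = repack_in(V, B, Sk, D);
  arma::cube dCx = repack_in(dctx, B, Sq, D);
  const arma::cube Pc(const_cast<double*>(P.begin()), Sq, Sk, (long)B * nh, false);

  arma::cube dQc(Sq, D, B, arma::fill::zeros);
  arma::cube dKc(Sk, D, B, arma::fill::zeros);
  arma::cube dVc(Sk, D, B, arma::fill::zeros);
  arma::mat drelb(relb_rows > 0 ? relb_rows : 1, nh, arma::fill::zeros);
  IntegerMatrix ri = (has_bias && RI.isNotNull()) ? IntegerMatrix(RI.get())
                                                  : IntegerMatrix(0, 0);

  for (int b = 0; b < B; ++b) {
    for (int h = 0; h < nh; ++h) {
      int c0 = h * dk;
      const arma::mat& Pb = Pc.slice((long)b * nh + h);
      arma::mat dCxh = dCx.slice(b).cols(c0, c0 + dk - 1);
      arma::mat Vb = Vc.slice(b).cols(c0, c0 + dk - 1);
      arma::mat dP = dCxh * Vb.t();
      dVc.slice(b).cols(c0, c0 + dk - 1) = Pb.t() * dCxh;
      arma::vec dot = arma::sum(dP % Pb, 1);
      arma::mat dS = Pb % (dP.each_col() - dot);
      if (has_bias)
        for (int k2 = 0; k2 < Sk; ++k2)
          for (int j = 0; j < Sq; ++j)
            drelb(ri(j, k2) - 1, h) += dS(j, k2);
      dQc.slice(b).cols(c0, c0 + dk - 1) =
        dS * Kc.slice(b).cols(c0, c0 + dk - 1) * scale;
      dKc.slice(b).cols(c0, c0 + dk - 1) =
        dS.t() * Qc.slice(b).cols(c0, c0 + dk - 1) * scale;
    }
  }
  return List::create(_["dQ"] = repack_out(dQc, B, Sq, D),
                      _["dK"] = repack_out(dKc, B, Sk, D),
                      _["dV"] = repack_out(dVc, B, Sk, D),
                      _["drelb"] = has_bias ? wrap(drelb) : R_NilValue);
}
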