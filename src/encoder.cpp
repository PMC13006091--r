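// Fused transformer encoder: all Pre-LN self-attention blocks plus the
// optional cross-attention fusion module run in a single forward call;
// intermediates live in C++ memory (external-pointer cache) so the
// backward pass can run without round-tripping large arrays through the
// R heap. Token tensors use cube layout (S, D, B): one contiguous S x D
// matrix per sample.

#include <RcppArmadillo.h>
#include "fastmath.h"
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::cube;
using arma::mat;
using arma::vec;

static cube repack_in3(const NumericVector& A) {
  IntegerVector d = A.attr("dim");
  int B = d[0], S = d[1], D = d[2];
  cube C(S, D, B);
  const double* a = A.begin();
  for (int dd = 0; dd < D; ++dd)
    for (int s = 0; s < S; ++s) {
      const double* col = a + (long)B * (s + (long)S * dd);
      for (int b = 0; b < B; ++b) C(s, dd, b) = col[b];
    }
  return C;
}

static NumericVector repack_out3(const cube& C) {
  int S = C.n_rows, D = C.n_cols, B = C.n_slices;
  NumericVector A((long)B * S * D);
  double* a = A.begin();
  for (int dd = 0; dd < D; ++dd)
    for (int s = 0; s < S; ++s) {
      double* col = a + (long)B * (s + (long)S * dd);
      for (int b = 0; b < B; ++b) col[b] = C(s, dd, b);
    }
  A.attr("dim") = IntegerVector::create(B, S, D);
  return A;
}

static mat as_arma(SEXP x) {
  NumericMatrix m(x);
  return mat(m.begin(), m.nrow(), m.ncol());  // copy (params are small)
}

static vec as_vec(SEXP x) {
  NumericVector v(x);
  return vec(v.begin(), v.size());
}

static mat affine(const mat& X, const mat& W, const vec& b) {
  mat T = X * W;
  T.each_row() += b.t();
  return T;
}

struct LNCache {
  cube xhat;        // (S, D, B)
  mat istd;         // (S, B)
};

// LayerNorm over D within each (token, sample); gain g, bias b length D.
static void ln_fwd(const cube& X, const vec& g, const vec& b, cube& out,
                   LNCache& c, double eps = 1e-5) {
  int S = X.n_rows, D = X.n_cols, B = X.n_slices;
  c.xhat.set_size(S, D, B);
  c.istd.set_size(S, B);
  out.set_size(S, D, B);
  for (int bb = 0; bb < B; ++bb) {
    const mat& Xb = X.slice(bb);
    vec mu = arma::mean(Xb, 1);
    mat xc = Xb.each_col() - mu;
    vec v = arma::mean(arma::square(xc), 1);
    vec istd = 1.0 / arma::sqrt(v + eps);
    mat xhat = xc.each_col() % istd;
    c.xhat.slice(bb) = xhat;
    c.istd.col(bb) = istd;
    mat o = xhat.each_row() % g.t();
    o.each_row() += b.t();
    out.slice(bb) = o;
  }
}

// returns dX; accumulates dg, db
static void ln_bwd(const LNCache& c, const vec& g, const cube& dout,
                   cube& dX, vec& dg, vec& db) {
  int S = c.xhat.n_rows, D = c.xhat.n_cols, B = c.xhat.n_slices;
  dX.set_size(S, D, B);
  for (int bb = 0; bb < B; ++bb) {
    const mat& xh = c.xhat.slice(bb);
    const mat& do_ = dout.slice(bb);
    dg += arma::sum(do_ % xh, 0).t();
    db += arma::sum(do_, 0).t();
    mat dxhat = do_.each_row() % g.t();
    vec m1 = arma::mean(dxhat, 1);
    vec m2 = arma::mean(dxhat % xh, 1);
    mat t = dxhat;
    t.each_col() -= m1;
    t -= xh.each_col() % m2;
    dX.slice(bb) = t.each_col() % c.istd.col(bb);
  }
}

struct AttnParams {
  mat Wq, Wk, Wv, Wo;
  vec bq, bk, bv, bo;
};

static AttnParams attn_params(const List& p) {
  AttnParams a;
  a.Wq = as_arma(p["Wq"]); a.Wk = as_arma(p["Wk"]);
  a.Wv = as_arma(p["Wv"]); a.Wo = as_arma(p["Wo"]);
  a.bq = as_vec(p["bq"]); a.bk = as_vec(p["bk"]);
  a.bv = as_vec(p["bv"]); a.bo = as_vec(p["bo"]);
  return a;
}

struct AttnCache {
  cube M;           // LN'd input fed to Q/K/V (self) or query side (cross)
  cube Q, K, V;     // projections (Sq/Sk, D, B)
  cube P;           // probabilities (Sq, Sk, nh*B)
  cube ctx;         // pre-output-projection context
};

struct BlockCache {
  LNCache ln1, ln2;
  AttnCache att;
  cube X1;          // after attention residual
  cube M2;          // LN2 output
  cube H1, th, A;   // FFN pre-activation, tanh cache, activation
};

struct FFNParams {
  mat W1, W2;
  vec b1, b2;
};

static FFNParams ffn_params(const List& p) {
  FFNParams f;
  f.W1 = as_arma(p["W1"]); f.W2 = as_arma(p["W2"]);
  f.b1 = as_vec(p["b1"]); f.b2 = as_vec(p["b2"]);
  return f;
}

// attention: Q from Mq, K/V from Mkv; bias optional (self-attention only)
static void attn_fwd(const cube& Mq, const cube& Mkv, const AttnParams& ap,
                     int nh, const mat* bias, AttnCache& c, cube& out) {
  int Sq = Mq.n_rows, D = Mq.n_cols, B = Mq.n_slices, Sk = Mkv.n_rows;
  int dk = D / nh;
  double scale = 1.0 / std::sqrt((double)dk);
  c.Q.set_size(Sq, D, B); c.K.set_size(Sk, D, B); c.V.set_size(Sk, D, B);
  c.P.set_size(Sq, Sk, (long)nh * B);
  c.ctx.set_size(Sq, D, B);
  out.set_size(Sq, D, B);
  for (int b = 0; b < B; ++b) {
    c.Q.slice(b) = affine(Mq.slice(b), ap.Wq, ap.bq);
    c.K.slice(b) = affine(Mkv.slice(b), ap.Wk, ap.bk);
    c.V.slice(b) = affine(Mkv.slice(b), ap.Wv, ap.bv);
    for (int h = 0; h < nh; ++h) {
      int c0 = h * dk;
      mat Sc = c.Q.slice(b).cols(c0, c0 + dk - 1) *
        c.K.slice(b).cols(c0, c0 + dk - 1).t() * scale;
      if (bias) Sc += bias->cols((long)h * Sk, (long)h * Sk + Sk - 1);
      vec mx = arma::max(Sc, 1);
      Sc.each_col() -= mx;
      Sc.for_each([](mat::elem_type& v) { v = fast_exp(v); });
      vec rs = arma::sum(Sc, 1);
      Sc.each_col() /= rs;
      c.P.slice((long)b * nh + h) = Sc;
      c.ctx.slice(b).cols(c0, c0 + dk - 1) =
        Sc * c.V.slice(b).cols(c0, c0 + dk - 1);
    }
    out.slice(b) = affine(c.ctx.slice(b), ap.Wo, ap.bo);
  }
}

struct AttnGrads {
  mat Wq, Wk, Wv, Wo;
  vec bq, bk, bv, bo;
  mat relb;
  void init(int D, int relb_rows, int nh) {
    Wq.zeros(D, D); Wk.zeros(D, D); Wv.zeros(D, D); Wo.zeros(D, D);
    bq.zeros(D); bk.zeros(D); bv.zeros(D); bo.zeros(D);
    if (relb_rows > 0) relb.zeros(relb_rows, nh);
  }
};

// returns dMq and dMkv
static void attn_bwd(const cube& Mq, const cube& Mkv, const AttnParams& ap,
                     int nh, const IntegerMatrix* RI, AttnCache& c,
                     const cube& dout, AttnGrads& g, cube& dMq, cube& dMkv) {
  int Sq = Mq.n_rows, D = Mq.n_cols, B = Mq.n_slices, Sk = Mkv.n_rows;
  int dk = D / nh;
  double scale = 1.0 / std::sqrt((double)dk);
  dMq.zeros(Sq, D, B);
  dMkv.zeros(Sk, D, B);
  mat dQ(Sq, D), dK(Sk, D), dV(Sk, D), dctx(Sq, D);
  for (int b = 0; b < B; ++b) {
    const mat& dob = dout.slice(b);
    g.Wo += c.ctx.slice(b).t() * dob;
    g.bo += arma::sum(dob, 0).t();
    dctx = dob * ap.Wo.t();
    for (int h = 0; h < nh; ++h) {
      int c0 = h * dk;
      const mat& Pb = c.P.slice((long)b * nh + h);
      mat dCxh = dctx.cols(c0, c0 + dk - 1);
      mat Vb = c.V.slice(b).cols(c0, c0 + dk - 1);
      mat dP = dCxh * Vb.t();
      dV.cols(c0, c0 + dk - 1) = Pb.t() * dCxh;
      vec dot = arma::sum(dP % Pb, 1);
      mat dS = Pb % (dP.each_col() - dot);
      if (RI)
        for (int k2 = 0; k2 < Sk; ++k2)
          for (int j = 0; j < Sq; ++j)
            g.relb((*RI)(j, k2) - 1, h) += dS(j, k2);
      dQ.cols(c0, c0 + dk - 1) =
        dS * c.K.slice(b).cols(c0, c0 + dk - 1) * scale;
      dK.cols(c0, c0 + dk - 1) =
        dS.t() * c.Q.slice(b).cols(c0, c0 + dk - 1) * scale;
    }
    g.Wq += Mq.slice(b).t() * dQ;
    g.bq += arma::sum(dQ, 0).t();
    g.Wk += Mkv.slice(b).t() * dK;
    g.bk += arma::sum(dK, 0).t();
    g.Wv += Mkv.slice(b).t() * dV;
    g.bv += arma::sum(dV, 0).t();
    dMq.slice(b) = dQ * ap.Wq.t();
    dMkv.slice(b) += dK * ap.Wk.t() + dV * ap.Wv.t();
  }
}

static void gelu_fwd_cube(const cube& X, cube& out, cube& th) {
  out.set_size(arma::size(X));
  th.set_size(arma::size(X));
  const double C0 = 0.7978845608028654, C1 = 0.044715;
  const double* x = X.memptr();
  double* o = out.memptr();
  double* t = th.memptr();
  long n = X.n_elem;
  for (long i = 0; i < n; ++i) {
    double xi = x[i];
    double tt = fast_tanh(C0 * (xi + C1 * xi * xi * xi));
    t[i] = tt;
    o[i] = 0.5 * xi * (1.0 + tt);
  }
}

static void gelu_bwd_cube(const cube& X, const cube& th, cube& d) {
  const double C0 = 0.7978845608028654, C1 = 0.044715;
  const double* x = X.memptr();
  const double* t = th.memptr();
  double* dd = d.memptr();
  long n = X.n_elem;
  for (long i = 0; i < n; ++i) {
    double xi = x[i], tt = t[i];
    dd[i] *= 0.5 * (1.0 + tt) +
      0.5 * xi * (1.0 - tt * tt) * C0 * (1.0 + 3.0 * C1 * xi * xi);
  }
}

// one Pre-LN block: X -> X + MHSA(LN1(X)) -> (+ FFN(LN2(.)))
static void block_fwd_c(const cube& X, const List& bp, const AttnParams& ap,
                        const FFNParams& fp, int nh, const mat* bias,
                        BlockCache& c, cube& out) {
  vec g1 = as_vec(bp["ln1g"]), b1 = as_vec(bp["ln1b"]);
  vec g2 = as_vec(bp["ln2g"]), b2 = as_vec(bp["ln2b"]);
  cube M1, atto;
  ln_fwd(X, g1, b1, M1, c.ln1);
  c.att.M = M1;
  attn_fwd(M1, M1, ap, nh, bias, c.att, atto);
  c.X1 = X + atto;
  ln_fwd(c.X1, g2, b2, c.M2, c.ln2);
  int B = X.n_slices;
  int Hf = fp.W1.n_cols;
  c.H1.set_size(X.n_rows, Hf, B);
  for (int b = 0; b < B; ++b)
    c.H1.slice(b) = affine(c.M2.slice(b), fp.W1, fp.b1);
  gelu_fwd_cube(c.H1, c.A, c.th);
  out.set_size(arma::size(X));
  for (int b = 0; b < B; ++b)
    out.slice(b) = c.X1.slice(b) + affine(c.A.slice(b), fp.W2, fp.b2);
}

struct BlockGrads {
  vec ln1g, ln1b, ln2g, ln2b;
  AttnGrads att;
  mat W1, W2;
  vec b1, b2;
  void init(int D, int Hf, int relb_rows, int nh) {
    ln1g.zeros(D); ln1b.zeros(D); ln2g.zeros(D); ln2b.zeros(D);
    att.init(D, relb_rows, nh);
    W1.zeros(D, Hf); W2.zeros(Hf, D);
    b1.zeros(Hf); b2.zeros(D);
  }
};

static void block_bwd_c(const List& bp, const AttnParams& ap,
                        const FFNParams& fp, int nh, const IntegerMatrix* RI,
                        BlockCache& c, const cube& dout, BlockGrads& g,
                        cube& dX) {
  vec g1 = as_vec(bp["ln1g"]);
  vec g2 = as_vec(bp["ln2g"]);
  int B = dout.n_slices;
  // FFN branch
  cube dA(arma::size(c.A)), dM2(arma::size(c.M2));
  for (int b = 0; b < B; ++b) {
    const mat& dob = dout.slice(b);
    g.W2 += c.A.slice(b).t() * dob;
    g.b2 += arma::sum(dob, 0).t();
    dA.slice(b) = dob * fp.W2.t();
  }
  gelu_bwd_cube(c.H1, c.th, dA);       // dA now holds dH1
  for (int b = 0; b < B; ++b) {
    g.W1 += c.M2.slice(b).t() * dA.slice(b);
    g.b1 += arma::sum(dA.slice(b), 0).t();
    dM2.slice(b) = dA.slice(b) * fp.W1.t();
  }
  cube dX1;
  ln_bwd(c.ln2, g2, dM2, dX1, g.ln2g, g.ln2b);
  dX1 += dout;
  // attention branch
  cube dM1, dM1kv;
  attn_bwd(c.att.M, c.att.M, ap, nh, RI, c.att, dX1, g.att, dM1, dM1kv);
  dM1 += dM1kv;
  ln_bwd(c.ln1, g1, dM1, dX, g.ln1g, g.ln1b);
  dX += dX1;
}

struct FusionCache {
  LNCache lnq, lnf;
  AttnCache att;
  cube Hg;          // (mg, D, B) GRM tokens as given
  cube X1, M2, H1, th, A;
};

struct EncoderCache {
  std::vector<BlockCache> blocks;
  FusionCache fusion;
  bool has_fusion = false;
};

static List attn_grads_list(const AttnGrads& g) {
  return List::create(_["Wq"] = wrap(g.Wq), _["bq"] = wrap(g.bq),
                      _["Wk"] = wrap(g.Wk), _["bk"] = wrap(g.bk),
                      _["Wv"] = wrap(g.Wv), _["bv"] = wrap(g.bv),
                      _["Wo"] = wrap(g.Wo), _["bo"] = wrap(g.bo));
}

// [[Rcpp::export]]
List encoder_fwd_cpp(NumericVector X, List blocks, Nullable<List> fusion,
                     Nullable<NumericVector> Hg, NumericMatrix relb,
                     IntegerMatrix RI, int nh, int L_pre,
                     bool record_attention, bool want_cache,
                     SEXP cache_in = R_NilValue) {
  std::unique_ptr<EncoderCache> local;
  EncoderCache* cache = nullptr;
  RObject cache_holder = R_NilValue;
  if (want_cache) {
    if (TYPEOF(cache_in) == EXTPTRSXP && R_ExternalPtrAddr(cache_in) != nullptr) {
      cache = static_cast<EncoderCache*>(R_ExternalPtrAddr(cache_in));
      cache_holder = cache_in;                       // reuse buffers
    } else {
      XPtr<EncoderCache> xp(new EncoderCache(), true);
      cache = xp.get();
      cache_holder = xp;
    }
  } else {
    local.reset(new EncoderCache());
    cache = local.get();
  }
  cube Xc = repack_in3(X);
  int S = Xc.n_rows, B = Xc.n_slices;
  int nb = blocks.size();
  cache->blocks.resize(nb);

  // bias matrices per head laid side by side
  mat bias(S, (long)S * nh);
  for (int h = 0; h < nh; ++h)
    for (int k2 = 0; k2 < S; ++k2)
      for (int j = 0; j < S; ++j)
        bias(j, (long)h * S + k2) = relb(RI(j, k2) - 1, h);

  bool fuse = fusion.isNotNull() && Hg.isNotNull();
  cache->has_fusion = fuse;
  List attn_records;
  cube cur = Xc;

  auto record_cls = [&](const cube& P, int Sk) {
    // P: (S(q), Sk, nh*B) -> CLS row [B, nh, Sk]
    NumericVector A((long)B * nh * Sk);
    for (int k2 = 0; k2 < Sk; ++k2)
      for (int h = 0; h < nh; ++h)
        for (int b = 0; b < B; ++b)
          A[b + (long)B * h + (long)B * nh * k2] = P(0, k2, (long)b * nh + h);
    A.attr("dim") = IntegerVector::create(B, nh, Sk);
    return A;
  };

  for (int i = 0; i < nb; ++i) {
    if (fuse && i == L_pre) {
      List fp(fusion.get());
      AttnParams ap = attn_params(fp["attn"]);
      FFNParams ffp = ffn_params(fp["ffn"]);
      vec gq = as_vec(fp["lnqg"]), bq = as_vec(fp["lnqb"]);
      vec gf = as_vec(fp["lnfg"]), bf = as_vec(fp["lnfb"]);
      FusionCache& fc = cache->fusion;
      fc.Hg = repack_in3(NumericVector(Hg.get()));
      cube Mq, atto;
      ln_fwd(cur, gq, bq, Mq, fc.lnq);
      fc.att.M = Mq;
      attn_fwd(Mq, fc.Hg, ap, nh, nullptr, fc.att, atto);
      fc.X1 = cur + atto;
      ln_fwd(fc.X1, gf, bf, fc.M2, fc.lnf);
      int Hf = ffp.W1.n_cols;
      fc.H1.set_size(S, Hf, B);
      for (int b = 0; b < B; ++b)
        fc.H1.slice(b) = affine(fc.M2.slice(b), ffp.W1, ffp.b1);
      gelu_fwd_cube(fc.H1, fc.A, fc.th);
      cube out(arma::size(cur));
      for (int b = 0; b < B; ++b)
        out.slice(b) = fc.X1.slice(b) +
          affine(fc.A.slice(b), ffp.W2, ffp.b2);
      cur = out;
      if (record_attention)
        attn_records.push_back(record_cls(fc.att.P, fc.Hg.n_rows), "fusion");
    }
    List bp(blocks[i]);
    AttnParams ap = attn_params(bp["attn"]);
    FFNParams ffp = ffn_params(bp["ffn"]);
    cube out;
    block_fwd_c(cur, bp, ap, ffp, nh, &bias, cache->blocks[i], out);
    cur = out;
    if (record_attention)
      attn_records.push_back(record_cls(cache->blocks[i].att.P, S),
                             std::string("self") + std::to_string(i + 1));
  }
  return List::create(_["out"] = repack_out3(cur),
                      _["cache"] = cache_holder,
                      _["attention"] = attn_records);
}

// [[Rcpp::export]]
List encoder_bwd_cpp(SEXP cache_xp, NumericVector dout, List blocks,
                     Nullable<List> fusion, IntegerMatrix RI, int nh,
                     int L_pre) {
  XPtr<EncoderCache> cache(cache_xp);
  cube dcur = repack_in3(dout);
  int nb = blocks.size();
  int D = dcur.n_cols;
  int relb_rows = 0;
  {
    IntegerVector riv(RI);
    relb_rows = Rcpp::max(riv);
  }
  List block_grads(nb);
  mat drelb_total;
  drelb_total.zeros(relb_rows, nh);
  List fusion_grads = R_NilValue;
  NumericVector dHg_out;

  for (int i = nb - 1; i >= 0; --i) {
    List bp(blocks[i]);
    AttnParams ap = attn_params(bp["attn"]);
    FFNParams ffp = ffn_params(bp["ffn"]);
    BlockGrads g;
    g.init(D, ffp.W1.n_cols, relb_rows, nh);
    cube dX;
    block_bwd_c(bp, ap, ffp, nh, &RI, cache->blocks[i], dcur, g, dX);
    dcur = dX;
    drelb_total += g.att.relb;
    block_grads[i] = List::create(
      _["ln1g"] = wrap(g.ln1g), _["ln1b"] = wrap(g.ln1b),
      _["attn"] = attn_grads_list(g.att),
      _["ln2g"] = wrap(g.ln2g), _["ln2b"] = wrap(g.ln2b),
      _["ffn"] = List::create(_["W1"] = wrap(g.W1), _["b1"] = wrap(g.b1),
                              _["W2"] = wrap(g.W2), _["b2"] = wrap(g.b2)));
    if (cache->has_fusion && i == L_pre) {
      List fp(fusion.get());
      AttnParams fap = attn_params(fp["attn"]);
      FFNParams ffp2 = ffn_params(fp["ffn"]);
      vec gq = as_vec(fp["lnqg"]);
      vec gf = as_vec(fp["lnfg"]);
      FusionCache& fc = cache->fusion;
      int B = dcur.n_slices;
      // FFN branch
      cube dA(arma::size(fc.A)), dM2(arma::size(fc.M2));
      mat gW1, gW2;
      vec gb1, gb2, glnfg, glnfb, glnqg, glnqb;
      gW1.zeros(ffp2.W1.n_rows, ffp2.W1.n_cols);
      gW2.zeros(ffp2.W2.n_rows, ffp2.W2.n_cols);
      gb1.zeros(ffp2.b1.n_elem); gb2.zeros(ffp2.b2.n_elem);
      glnfg.zeros(D); glnfb.zeros(D); glnqg.zeros(D); glnqb.zeros(D);
      for (int b = 0; b < B; ++b) {
        const mat& dob = dcur.slice(b);
        gW2 += fc.A.slice(b).t() * dob;
        gb2 += arma::sum(dob, 0).t();
        dA.slice(b) = dob * ffp2.W2.t();
      }
      gelu_bwd_cube(fc.H1, fc.th, dA);
      for (int b = 0; b < B; ++b) {
        gW1 += fc.M2.slice(b).t() * dA.slice(b);
        gb1 += arma::sum(dA.slice(b), 0).t();
        dM2.slice(b) = dA.slice(b) * ffp2.W1.t();
      }
      cube dX1;
      ln_bwd(fc.lnf, gf, dM2, dX1, glnfg, glnfb);
      dX1 += dcur;
      AttnGrads ga;
      ga.init(D, 0, nh);
      cube dMq, dHg;
      attn_bwd(fc.att.M, fc.Hg, fap, nh, nullptr, fc.att, dX1, ga, dMq, dHg);
      cube dXq;
      ln_bwd(fc.lnq, gq, dMq, dXq, glnqg, glnqb);
      dcur = dX1 + dXq;
      fusion_grads = List::create(
        _["lnqg"] = wrap(glnqg), _["lnqb"] = wrap(glnqb),
        _["attn"] = attn_grads_list(ga),
        _["lnfg"] = wrap(glnfg), _["lnfb"] = wrap(glnfb),
        _["ffn"] = List::create(_["W1"] = wrap(gW1), _["b1"] = wrap(gb1),
                                _["W2"] = wrap(gW2), _["b2"] = wrap(gb2)));
      dHg_out = repack_out3(dHg);
    }
  }
  return List::create(_["dX"] = repack_out3(dcur),
                      _["blocks"] = block_grads,
                      _["relb"] = wrap(drelb_total),
                      _["fusion"] = fusion_grads,
                      _["dHg"] = dHg_out.size() ? (SEXP)dHg_out : R_NilValue);
}
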