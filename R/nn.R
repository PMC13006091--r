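# Neural-network primitives: forward passes with caches and hand-derived
# backward passes. Token batches are [B, S, D] arrays; most dense algebra
# runs on the flattened (B*S) x D matrix view (R arrays are column-major
# with D last, so the flatten/unflatten is a plain dim change).

as_mat <- function(A) {
  d <- dim(A)
  matrix(A, d[1] * d[2], d[3])
}

from_mat <- function(M, B, S) array(M, c(B, S, ncol(M)))

add_rowvec <- function(M, v) M + matrix(v, nrow(M), length(v), byrow = TRUE)

#' Tanh approximation of the GELU activation
#'
#' `0.5 * x * (1 + tanh(sqrt(2/pi) * (x + 0.044715 x^3)))` — the standard
#' fast approximation to `x * pnorm(x)`.
#'
#' @param x numeric vector/matrix.
#' @return same shape as `x`.
#' @export
gelu_approx <- function(x) {
  0.5 * x * (1 + tanh(sqrt(2 / pi) * (x + 0.044715 * x^3)))
}

gelu_grad <- function(x) {
  c0 <- sqrt(2 / pi)
  u <- c0 * (x + 0.044715 * x^3)
  t <- tanh(u)
  0.5 * (1 + t) + 0.5 * x * (1 - t^2) * c0 * (1 + 3 * 0.044715 * x^2)
}

softmax_rows <- function(S) {
  S <- S - apply(S, 1, max)
  E <- exp(S)
  E / rowSums(E)
}

# d/dS of softmax given row-probabilities P and upstream dP
softmax_rows_bwd <- function(P, dP) {
  P * (dP - rowSums(dP * P))
}

layernorm_fwd <- function(M, g, b, eps = 1e-5) {
  mu <- rowMeans(M)
  xc <- M - mu
  v <- rowMeans(xc * xc)
  istd <- 1 / sqrt(v + eps)
  xhat <- xc * istd
  out <- add_rowvec(xhat * matrix(g, nrow(M), length(g), byrow = TRUE), b)
  list(out = out, xhat = xhat, istd = istd, g = g)
}

layernorm_bwd <- function(cache, dout) {
  g <- cache$g
  xhat <- cache$xhat
  dxhat <- dout * matrix(g, nrow(dout), length(g), byrow = TRUE)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- cache$istd * (dxhat - m1 - xhat * m2)
  list(dx = dx, dg = colSums(dout * xhat), db = colSums(dout))
}

linear_fwd <- function(M, W, b) add_rowvec(M %*% W, b)

linear_bwd <- function(M, W, dout) {
  list(dx = dout %*% t(W), dW = crossprod(M, dout), db = colSums(dout))
}

# ---------------------------------------------------------------------------
# Multi-head self-attention with learnable relative positional bias.
# relb: (2*S_max - 1) x n_heads lookup table; RI: S x S matrix of relative
# indices k - j + S_max (precomputed).

head_cols <- function(h, dk) ((h - 1L) * dk + 1L):(h * dk)

mhsa_fwd <- function(X, p, relb, RI, nh) {
  B <- dim(X)[1]; S <- dim(X)[2]
  M <- as_mat(X)
  Qa <- from_mat(linear_fwd(M, p$Wq, p$bq), B, S)
  Ka <- from_mat(linear_fwd(M, p$Wk, p$bk), B, S)
  Va <- from_mat(linear_fwd(M, p$Wv, p$bv), B, S)
  RIm <- if (!is.null(relb)) matrix(as.integer(RI), S, S) else NULL
  core <- attn_core_fwd(Qa, Ka, Va, nh, relb, RIm)
  out <- linear_fwd(as_mat(core$ctx), p$Wo, p$bo)
  list(out = from_mat(out, B, S),
       cache = list(M = M, Qa = Qa, Ka = Ka, Va = Va, P = core$P,
                    ctx = core$ctx, B = B, S = S, nh = nh, RI = RIm,
                    has_bias = !is.null(relb),
                    relb_rows = if (!is.null(relb)) nrow(relb) else 0L))
}

mhsa_bwd <- function(p, cache, dout) {
  B <- cache$B; S <- cache$S
  lo <- linear_bwd(as_mat(cache$ctx), p$Wo, as_mat(dout))
  dctx <- from_mat(lo$dx, B, S)
  core <- attn_core_bwd(cache$Qa, cache$Ka, cache$Va, cache$P, dctx,
                        cache$nh, cache$has_bias, cache$relb_rows, cache$RI)
  lq <- linear_bwd(cache$M, p$Wq, as_mat(core$dQ))
  lk <- linear_bwd(cache$M, p$Wk, as_mat(core$dK))
  lv <- linear_bwd(cache$M, p$Wv, as_mat(core$dV))
  list(dx = lq$dx + lk$dx + lv$dx,
       grads = list(Wq = lq$dW, bq = lq$db, Wk = lk$dW, bk = lk$db,
                    Wv = lv$dW, bv = lv$db, Wo = lo$dW, bo = lo$db),
       drelb = core$drelb)
}

# ---------------------------------------------------------------------------
# Cross-attention: queries from the (LN'd) SNP tokens, keys/values from the
# GRM representation; no positional term.

cross_attn_fwd <- function(Xq_mat, Hg, p, nh, B, S) {
  mg <- dim(Hg)[2]
  Gm <- as_mat(Hg)
  Qa <- from_mat(linear_fwd(Xq_mat, p$Wq, p$bq), B, S)
  Ka <- from_mat(linear_fwd(Gm, p$Wk, p$bk), B, mg)
  Va <- from_mat(linear_fwd(Gm, p$Wv, p$bv), B, mg)
  core <- attn_core_fwd(Qa, Ka, Va, nh, NULL, NULL)
  out <- linear_fwd(as_mat(core$ctx), p$Wo, p$bo)
  list(out = from_mat(out, B, S),
       cache = list(Xq_mat = Xq_mat, Gm = Gm, Qa = Qa, Ka = Ka, Va = Va,
                    P = core$P, ctx = core$ctx, B = B, S = S, mg = mg, nh = nh))
}

cross_attn_bwd <- function(p, cache, dout) {
  B <- cache$B; S <- cache$S
  lo <- linear_bwd(as_mat(cache$ctx), p$Wo, as_mat(dout))
  dctx <- from_mat(lo$dx, B, S)
  core <- attn_core_bwd(cache$Qa, cache$Ka, cache$Va, cache$P, dctx,
                        cache$nh, FALSE, 0L, NULL)
  lq <- linear_bwd(cache$Xq_mat, p$Wq, as_mat(core$dQ))
  lk <- linear_bwd(cache$Gm, p$Wk, as_mat(core$dK))
  lv <- linear_bwd(cache$Gm, p$Wv, as_mat(core$dV))
  list(dXq = lq$dx, dHg_mat = lk$dx + lv$dx,
       grads = list(Wq = lq$dW, bq = lq$db, Wk = lk$dW, bk = lk$db,
                    Wv = lv$dW, bv = lv$db, Wo = lo$dW, bo = lo$db))
}

# ---------------------------------------------------------------------------
# FFN: affine -> GELU -> affine

ffn_fwd <- function(M, p) {
  H1 <- linear_fwd(M, p$W1, p$b1)
  gf <- gelu_fwd_cpp(H1)
  out <- linear_fwd(gf$out, p$W2, p$b2)
  list(out = out, cache = list(M = M, H1 = H1, th = gf$tanh_u, A = gf$out))
}

ffn_bwd <- function(p, cache, dout) {
  l2 <- linear_bwd(cache$A, p$W2, dout)
  dH1 <- gelu_bwd_cpp(cache$H1, cache$th, l2$dx)
  l1 <- linear_bwd(cache$M, p$W1, dH1)
  list(dx = l1$dx,
       grads = list(W1 = l1$dW, b1 = l1$db, W2 = l2$dW, b2 = l2$db))
}

# [CLS] attention rows: P has layout [Sq, Sk, nh, B]; returns [B, nh, Sk]
cls_rows <- function(P) {
  d <- dim(P)
  A <- array(P[1, , , ], c(d[2], d[3], d[4]))
  aperm(A, c(3, 2, 1))
}
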