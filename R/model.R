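# The dual-pathway transformer for genomic prediction.
#
# SNP tokens (patch or per-marker embeddings plus a [CLS] token) pass
# through Pre-LN self-attention blocks with a learnable relative positional
# bias; midway, a cross-attention module lets every SNP token query a
# kinship representation produced by the GRM pathway (two affine layers
# with GELU, layer-normalized per token). The [CLS] state feeds an MLP
# regression head. Ablation variants: `gvit_base` (no GRM), `grm_mlp`
# (GRM pathway + head only), `gvit_concat` (static concatenation instead
# of cross-attention).

#' Model configuration
#'
#' @param variant one of `"gvit_gp"`, `"gvit_base"`, `"grm_mlp"`,
#'   `"gvit_concat"`.
#' @param embed token embedding kind: `"spe"`, `"fpe"` (patch) or `"sie"`
#'   (per-marker scalar).
#' @param S token-sequence length including `[CLS]` (N_p + 1 for patching,
#'   k + 1 for SIE).
#' @param P patch width in markers (required for patch embeddings).
#' @param D embedding dimension (divisible by `n_heads`).
#' @param n_heads attention heads.
#' @param L_pre,L_post encoder depth before/after the fusion point.
#' @param ffn_mult FFN width multiplier.
#' @param n_ref GRM reference-cohort size (input width of the GRM pathway).
#' @param grm_hidden hidden width of the GRM pathway.
#' @param m_g number of GRM tokens produced by the pathway.
#' @param dropout dropout rate in the regression head (training only).
#' @param seed initialization seed.
#' @return a `gvit_config` list.
#' @export
gvit_config <- function(variant = c("gvit_gp", "gvit_base", "grm_mlp", "gvit_concat"),
                        embed = c("spe", "fpe", "sie"), S, P = NULL, D = 128,
                        n_heads = 8, L_pre = 2, L_post = 2, ffn_mult = 4,
                        n_ref = NULL, grm_hidden = 512, m_g = 1,
                        dropout = 0.1, seed = 1) {
  variant <- match.arg(variant)
  embed <- match.arg(embed)
  if (D %% n_heads != 0) gv_config_error("D must be divisible by n_heads")
  needs_grm <- variant %in% c("gvit_gp", "grm_mlp", "gvit_concat")
  needs_encoder <- variant != "grm_mlp"
  if (needs_grm && (is.null(n_ref) || n_ref < 1)) gv_config_error("n_ref required for GRM variants")
  if (needs_encoder && embed != "sie" && is.null(P)) gv_config_error("P required for patch embeddings")
  if (m_g < 1) gv_config_error("m_g must be >= 1")
  structure(list(variant = variant, embed = embed, S = as.integer(S), P = P,
                 D = as.integer(D), n_heads = as.integer(n_heads),
                 L_pre = as.integer(L_pre), L_post = as.integer(L_post),
                 ffn_mult = ffn_mult, n_ref = n_ref, grm_hidden = grm_hidden,
                 m_g = as.integer(m_g), dropout = dropout, seed = as.integer(seed),
                 needs_grm = needs_grm, needs_encoder = needs_encoder),
            class = "gvit_config")
}

init_block_params <- function(D, ffn_mult, rn) {
  H <- ffn_mult * D
  list(ln1g = rep(1, D), ln1b = rep(0, D),
       attn = list(Wq = rn(D, D), bq = rep(0, D), Wk = rn(D, D), bk = rep(0, D),
                   Wv = rn(D, D), bv = rep(0, D), Wo = rn(D, D), bo = rep(0, D)),
       ln2g = rep(1, D), ln2b = rep(0, D),
       ffn = list(W1 = rn(D, H), b1 = rep(0, H), W2 = rn(H, D), b2 = rep(0, D)))
}

#' Initialize a model
#'
#' Weights ~ N(0, 0.02^2), biases 0, LayerNorm gains 1, relative-bias table
#' 0 (so a fresh model's attention is position-agnostic until trained).
#'
#' @param cfg a [gvit_config()].
#' @return object of class `gvit_model`: list with `cfg` and `params`.
#' @export
init_gvit <- function(cfg) {
  set.seed(cfg$seed)
  rn <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = 0.02), nr, nc)
  D <- cfg$D
  p <- list()
  if (cfg$needs_encoder) {
    p$embed <- if (cfg$embed == "sie") {
      list(w = stats::rnorm(D, sd = 0.02), b = rep(0, D),
           cls = stats::rnorm(D, sd = 0.02))
    } else {
      list(We = rn(cfg$P, D), be = rep(0, D), cls = stats::rnorm(D, sd = 0.02))
    }
    p$relb <- matrix(0, 2 * cfg$S - 1, cfg$n_heads)
    p$blocks <- lapply(seq_len(cfg$L_pre + cfg$L_post),
                       function(i) init_block_params(D, cfg$ffn_mult, rn))
  }
  if (cfg$needs_grm) {
    p$grm <- list(W1 = rn(cfg$n_ref, cfg$grm_hidden), b1 = rep(0, cfg$grm_hidden),
                  W2 = rn(cfg$grm_hidden, cfg$m_g * D), b2 = rep(0, cfg$m_g * D),
                  lng = rep(1, D), lnb = rep(0, D))
  }
  if (cfg$variant == "gvit_gp") {
    p$fusion <- list(lnqg = rep(1, D), lnqb = rep(0, D),
                     attn = list(Wq = rn(D, D), bq = rep(0, D), Wk = rn(D, D),
                                 bk = rep(0, D), Wv = rn(D, D), bv = rep(0, D),
                                 Wo = rn(D, D), bo = rep(0, D)),
                     lnfg = rep(1, D), lnfb = rep(0, D),
                     ffn = list(W1 = rn(D, cfg$ffn_mult * D),
                                b1 = rep(0, cfg$ffn_mult * D),
                                W2 = rn(cfg$ffn_mult * D, D), b2 = rep(0, D)))
  }
  din <- switch(cfg$variant,
                gvit_gp = D, gvit_base = D,
                grm_mlp = cfg$m_g * D,
                gvit_concat = D + cfg$m_g * D)
  dh <- max(1L, din %/% 2L)
  p$head <- list(W1 = rn(din, dh), b1 = rep(0, dh), W2 = rn(dh, 1), b2 = 0)
  structure(list(cfg = cfg, params = p,
                 RI = if (cfg$needs_encoder) {
                   matrix(as.integer(outer(seq_len(cfg$S), seq_len(cfg$S),
                                           function(j, k) k - j) + cfg$S),
                          cfg$S, cfg$S)
                 } else NULL),
            class = "gvit_model")
}

#' Total trainable parameter count
#' @param model a `gvit_model`.
#' @return integer.
#' @export
n_params <- function(model) {
  sum(rapply(model$params, length, how = "unlist"))
}

#' @export
print.gvit_model <- function(x, ...) {
  cat(sprintf("gvit_model[%s/%s]: D = %d, heads = %d, depth = %d+%d, %s parameters\n",
              x$cfg$variant, x$cfg$embed, x$cfg$D, x$cfg$n_heads, x$cfg$L_pre,
              x$cfg$L_post, format(n_params(x), big.mark = ",")))
  invisible(x)
}

# ---------------------------------------------------------------------------
# composite blocks

block_fwd <- function(X, bp, relb, RI, nh) {
  B <- dim(X)[1]; S <- dim(X)[2]
  ln1 <- layernorm_fwd(as_mat(X), bp$ln1g, bp$ln1b)
  att <- mhsa_fwd(from_mat(ln1$out, B, S), bp$attn, relb, RI, nh)
  X1 <- X + att$out
  ln2 <- layernorm_fwd(as_mat(X1), bp$ln2g, bp$ln2b)
  ff <- ffn_fwd(ln2$out, bp$ffn)
  X2 <- X1 + from_mat(ff$out, B, S)
  list(out = X2, cache = list(ln1 = ln1, att = att$cache, ln2 = ln2,
                              ff = ff$cache, B = B, S = S))
}

block_bwd <- function(bp, cache, dX2) {
  B <- cache$B; S <- cache$S
  dff <- ffn_bwd(bp$ffn, cache$ff, as_mat(dX2))
  dln2 <- layernorm_bwd(cache$ln2, dff$dx)
  dX1 <- dX2 + from_mat(dln2$dx, B, S)
  datt <- mhsa_bwd(bp$attn, cache$att, dX1)
  dln1 <- layernorm_bwd(cache$ln1, datt$dx)
  dX <- dX1 + from_mat(dln1$dx, B, S)
  list(dx = dX,
       grads = list(ln1g = dln1$dg, ln1b = dln1$db, attn = datt$grads,
                    ln2g = dln2$dg, ln2b = dln2$db, ffn = dff$grads),
       drelb = datt$drelb)
}

fusion_fwd <- function(X, Hg, fp, nh) {
  B <- dim(X)[1]; S <- dim(X)[2]
  lnq <- layernorm_fwd(as_mat(X), fp$lnqg, fp$lnqb)
  ca <- cross_attn_fwd(lnq$out, Hg, fp$attn, nh, B, S)
  X1 <- X + ca$out
  lnf <- layernorm_fwd(as_mat(X1), fp$lnfg, fp$lnfb)
  ff <- ffn_fwd(lnf$out, fp$ffn)
  X2 <- X1 + from_mat(ff$out, B, S)
  list(out = X2, cache = list(lnq = lnq, ca = ca$cache, lnf = lnf,
                              ff = ff$cache, B = B, S = S))
}

fusion_bwd <- function(fp, cache, dX2) {
  B <- cache$B; S <- cache$S
  dff <- ffn_bwd(fp$ffn, cache$ff, as_mat(dX2))
  dlnf <- layernorm_bwd(cache$lnf, dff$dx)
  dX1 <- dX2 + from_mat(dlnf$dx, B, S)
  dca <- cross_attn_bwd(fp$attn, cache$ca, dX1)
  dlnq <- layernorm_bwd(cache$lnq, dca$dXq)
  dX <- dX1 + from_mat(dlnq$dx, B, S)
  dHg <- from_mat(dca$dHg_mat, B, dim(cache$ca$Ka)[2])
  list(dx = dX, dHg = dHg,
       grads = list(lnqg = dlnq$dg, lnqb = dlnq$db, attn = dca$grads,
                    lnfg = dlnf$dg, lnfb = dlnf$db, ffn = dff$grads))
}

grm_fwd <- function(Gv, pg, mg, D) {
  B <- nrow(Gv)
  Z1 <- linear_fwd(Gv, pg$W1, pg$b1)
  gf <- gelu_fwd_cpp(Z1)
  Z2 <- linear_fwd(gf$out, pg$W2, pg$b2)               # B x (mg*D)
  H <- aperm(array(Z2, c(B, D, mg)), c(1, 3, 2))       # B x mg x D
  ln <- layernorm_fwd(as_mat(H), pg$lng, pg$lnb)
  list(out = from_mat(ln$out, B, mg),
       cache = list(Gv = Gv, Z1 = Z1, th1 = gf$tanh_u, A1 = gf$out, ln = ln,
                    B = B, mg = mg, D = D))
}

grm_bwd <- function(pg, cache, dH) {
  dln <- layernorm_bwd(cache$ln, as_mat(dH))
  dHpre <- from_mat(dln$dx, cache$B, cache$mg)
  dZ2 <- matrix(aperm(dHpre, c(1, 3, 2)), cache$B, cache$mg * cache$D)
  l2 <- linear_bwd(cache$A1, pg$W2, dZ2)
  dZ1 <- gelu_bwd_cpp(cache$Z1, cache$th1, l2$dx)
  l1 <- linear_bwd(cache$Gv, pg$W1, dZ1)
  list(grads = list(W1 = l1$dW, b1 = l1$db, W2 = l2$dW, b2 = l2$db,
                    lng = dln$dg, lnb = dln$db))
}

flatten_grm_tokens <- function(H) {
  # [B, mg, D] -> [B, mg*D], inverse layout of grm_fwd's reshape
  matrix(aperm(H, c(1, 3, 2)), dim(H)[1], dim(H)[2] * dim(H)[3])
}

unflatten_grm_tokens <- function(M, mg, D) {
  aperm(array(M, c(nrow(M), D, mg)), c(1, 3, 2))
}

head_fwd <- function(U, hp, dropout, train) {
  H1 <- linear_fwd(U, hp$W1, hp$b1)
  gf <- gelu_fwd_cpp(H1)
  A <- gf$out
  mask <- NULL
  Ad <- A
  if (train && dropout > 0) {
    mask <- matrix(stats::rbinom(length(A), 1, 1 - dropout), nrow(A)) / (1 - dropout)
    Ad <- A * mask
  }
  out <- linear_fwd(Ad, hp$W2, hp$b2)
  list(pred = drop(out), cache = list(U = U, H1 = H1, th = gf$tanh_u, A = A,
                                      Ad = Ad, mask = mask))
}

head_bwd <- function(hp, cache, dpred) {
  dout <- matrix(dpred, ncol = 1)
  l2 <- linear_bwd(cache$Ad, hp$W2, dout)
  dAd <- l2$dx
  dA <- if (is.null(cache$mask)) dAd else dAd * cache$mask
  dH1 <- gelu_bwd_cpp(cache$H1, cache$th, dA)
  l1 <- linear_bwd(cache$U, hp$W1, dH1)
  list(dU = l1$dx,
       grads = list(W1 = l1$dW, b1 = l1$db, W2 = l2$dW, b2 = drop(l2$db)))
}

embed_fwd <- function(p_embed, cfg, X_embed) {
  if (cfg$embed == "sie") {
    tokens <- embed_scalars(X_embed, p_embed$w, p_embed$b, p_embed$cls)
    list(tokens = tokens, cache = list(X = X_embed))
  } else {
    d <- dim(X_embed)
    Xp_mat <- matrix(X_embed, d[1] * d[2], d[3])
    tokens <- embed_patches(X_embed, p_embed$We, p_embed$be, p_embed$cls)
    list(tokens = tokens, cache = list(Xp_mat = Xp_mat, B = d[1], Np = d[2]))
  }
}

embed_bwd <- function(p_embed, cfg, cache, dT) {
  B <- dim(dT)[1]
  dcls <- colSums(matrix(dT[, 1, ], B))
  if (cfg$embed == "sie") {
    k <- dim(dT)[2] - 1L
    dTm <- matrix(dT[, -1, , drop = FALSE], B * k, dim(dT)[3])
    Xv <- as.vector(cache$X)
    list(w = colSums(dTm * Xv), b = colSums(dTm), cls = dcls)
  } else {
    Np <- dim(dT)[2] - 1L
    dTm <- matrix(dT[, -1, , drop = FALSE], B * Np, dim(dT)[3])
    list(We = crossprod(cache$Xp_mat, dTm), be = colSums(dTm), cls = dcls)
  }
}

# ---------------------------------------------------------------------------
# full forward / backward

#' Forward pass (prediction)
#'
#' @param model a `gvit_model`.
#' @param inputs list with `X_embed` (patch tensor `[B, N_p, P]` for
#'   spe/fpe, matrix `[B, k]` for sie; ignored by `grm_mlp`) and `grm`
#'   (matrix `[B, n_ref]`; required by GRM variants).
#' @param record_attention record `[CLS]` attention rows per layer.
#' @param train internal flag (enables head dropout; used by the trainer).
#' @param want_cache internal flag (keep caches for backprop).
#' @return list with `pred` (length-B numeric) and `attention` (NULL or
#'   list with `self` = per-block `[B, heads, S]` CLS rows and `fusion` =
#'   `[B, heads, m_g]` or NULL).
#' @export
gvit_forward <- function(model, inputs, record_attention = FALSE,
                         train = FALSE, want_cache = FALSE) {
  cfg <- model$cfg
  p <- model$params
  cache <- list()
  attn <- if (record_attention) list(self = list(), fusion = NULL) else NULL

  Hg <- NULL
  if (cfg$needs_grm) {
    if (is.null(inputs$grm)) gv_contract_error("variant requires GRM relationship vectors")
    if (ncol(inputs$grm) != cfg$n_ref) {
      gv_contract_error(sprintf("GRM vector length %d does not match the model's reference cohort size %d",
                                ncol(inputs$grm), cfg$n_ref))
    }
    gfw <- grm_fwd(inputs$grm, p$grm, cfg$m_g, cfg$D)
    Hg <- gfw$out
    cache$grm <- gfw$cache
  }

  if (!cfg$needs_encoder) {                 # grm_mlp
    U <- flatten_grm_tokens(Hg)
    hf <- head_fwd(U, p$head, cfg$dropout, train)
    cache$head <- hf$cache
    return(list(pred = hf$pred, attention = attn,
                cache = if (want_cache) cache else NULL, Hg = Hg))
  }

  ef <- embed_fwd(p$embed, cfg, inputs$X_embed)
  X <- ef$tokens
  if (dim(X)[2] != cfg$S) {
    gv_contract_error(sprintf("token sequence length %d exceeds/mismatches the bias table capacity S = %d",
                              dim(X)[2], cfg$S))
  }
  cache$embed <- ef$cache

  use_fusion <- cfg$variant == "gvit_gp"
  enc <- encoder_fwd_cpp(X, p$blocks,
                         if (use_fusion) p$fusion else NULL,
                         if (use_fusion) Hg else NULL,
                         p$relb, model$RI, cfg$n_heads, cfg$L_pre,
                         record_attention, want_cache, model$scratch)
  cache$enc <- enc$cache
  Xout <- enc$out
  if (record_attention) {
    rec <- enc$attention
    nms <- names(rec)
    attn$self <- unname(rec[grepl("^self", nms)])
    if ("fusion" %in% nms) attn$fusion <- rec[["fusion"]]
  }

  cls_state <- matrix(Xout[, 1, ], dim(Xout)[1])
  U <- switch(cfg$variant,
              gvit_gp = cls_state,
              gvit_base = cls_state,
              gvit_concat = cbind(cls_state, flatten_grm_tokens(Hg)))
  hf <- head_fwd(U, p$head, cfg$dropout, train)
  cache$head <- hf$cache
  list(pred = hf$pred, attention = attn,
       cache = if (want_cache) c(cache, list(B = dim(Xout)[1], S = cfg$S)) else NULL,
       Hg = Hg)
}

#' Predict phenotypes (eval mode)
#'
#' Deterministic given fixed weights: no dropout, no hidden state.
#'
#' @inheritParams gvit_forward
#' @return list with `pred` and `attention`.
#' @export
gvit_predict <- function(model, inputs, record_attention = FALSE) {
  out <- gvit_forward(model, inputs, record_attention = record_attention,
                      train = FALSE, want_cache = FALSE)
  list(pred = out$pred, attention = out$attention)
}

# loss + gradients for one minibatch (training mode)
gvit_loss_grad <- function(model, inputs, y) {
  cfg <- model$cfg
  p <- model$params
  fw <- gvit_forward(model, inputs, train = TRUE, want_cache = TRUE)
  pred <- fw$pred
  B <- length(pred)
  resid <- pred - y
  loss <- mean(resid^2)
  if (!is.finite(loss)) {
    gv_numeric_error("non-finite training loss (divergence)")
  }
  dpred <- 2 * resid / B
  cache <- fw$cache
  g <- list()

  hb <- head_bwd(p$head, cache$head, dpred)
  g$head <- hb$grads

  if (!cfg$needs_encoder) {                 # grm_mlp
    dHg <- unflatten_grm_tokens(hb$dU, cfg$m_g, cfg$D)
    g$grm <- grm_bwd(p$grm, cache$grm, dHg)$grads
    return(list(loss = loss, grads = g, pred = pred))
  }

  D <- cfg$D
  dcls <- hb$dU[, seq_len(D), drop = FALSE]
  dHg_accum <- NULL
  if (cfg$variant == "gvit_concat") {
    dHg_accum <- unflatten_grm_tokens(hb$dU[, -seq_len(D), drop = FALSE], cfg$m_g, D)
  }

  S <- cfg$S
  dX <- array(0, c(B, S, D))
  dX[, 1, ] <- dcls

  use_fusion <- cfg$variant == "gvit_gp"
  eb <- encoder_bwd_cpp(cache$enc, dX, p$blocks,
                        if (use_fusion) p$fusion else NULL,
                        model$RI, cfg$n_heads, cfg$L_pre)
  g$blocks <- eb$blocks
  g$relb <- eb$relb
  if (use_fusion) {
    g$fusion <- eb$fusion
    dHg_accum <- if (is.null(dHg_accum)) eb$dHg else dHg_accum + eb$dHg
  }

  g$embed <- embed_bwd(p$embed, cfg, cache$embed, eb$dX)
  if (cfg$needs_grm) {
    g$grm <- grm_bwd(p$grm, cache$grm, dHg_accum)$grads
  }
  list(loss = loss, grads = g, pred = pred, scratch = cache$enc)
}

# ---------------------------------------------------------------------------
# thin single-sample wrappers matching the architectural operations

#' GRM pathway representation for relationship vectors
#'
#' affine(n_ref -> grm_hidden) -> GELU -> affine(-> m_g * D) -> reshape to
#' m_g tokens -> per-token LayerNorm.
#'
#' @param grm_vectors matrix `[B, n_ref]` (a single vector is accepted).
#' @param model a `gvit_model` with a GRM pathway.
#' @return array `[B, m_g, D]` (or `[m_g, D]` for a single vector).
#' @export
grm_pathway <- function(grm_vectors, model) {
  single <- is.null(dim(grm_vectors))
  Gv <- if (single) matrix(grm_vectors, 1) else grm_vectors
  if (is.null(model$params$grm)) gv_contract_error("model has no GRM pathway")
  if (ncol(Gv) != model$cfg$n_ref) {
    gv_contract_error(sprintf("relationship vector length %d != n_ref %d",
                              ncol(Gv), model$cfg$n_ref))
  }
  H <- grm_fwd(Gv, model$params$grm, model$cfg$m_g, model$cfg$D)$out
  if (single) {
    out <- matrix(H[1, , ], model$cfg$m_g, model$cfg$D)
    out
  } else H
}

#' Multi-head self-attention with relative positional bias (single sequence)
#'
#' `softmax(Q K' / sqrt(d_k) + B) V` per head, where the bias matrix entry
#' (j, k) is looked up by the relative position k - j; heads concatenated
#' and output-projected.
#'
#' @param X `S x D` token matrix.
#' @param params attention parameter list (`Wq,bq,...,Wo,bo`).
#' @param relb `(2 S_max - 1) x n_heads` bias table (or NULL for none).
#' @param n_heads head count.
#' @return list with `out` (`S x D`) and `attn` (`[heads, S, S]` rows).
#' @export
mhsa_relpos <- function(X, params, relb = NULL, n_heads = 1) {
  S <- nrow(X)
  if (!is.null(relb)) {
    S_max <- (nrow(relb) + 1) / 2
    if (S > S_max) gv_contract_error("sequence exceeds the bias-table capacity")
    RI <- outer(seq_len(S), seq_len(S), function(j, k) k - j) + S_max
  } else RI <- NULL
  Xa <- array(X, c(1, S, ncol(X)))
  fw <- mhsa_fwd(Xa, params, relb, RI, n_heads)
  A <- aperm(array(fw$cache$P, c(S, S, n_heads)), c(3, 1, 2))
  list(out = matrix(fw$out[1, , ], S), attn = A)
}

#' One Pre-LN encoder block (single sequence)
#'
#' `x' = x + MHSA(LN(x)); out = x' + FFN(LN(x'))`.
#'
#' @param x `S x D` input.
#' @param params block parameter list (as produced by [init_gvit()]).
#' @param relb,n_heads as in [mhsa_relpos()].
#' @return `S x D` output.
#' @export
pre_ln_block <- function(x, params, relb = NULL, n_heads = 1) {
  S <- nrow(x)
  if (!is.null(relb)) {
    S_max <- (nrow(relb) + 1) / 2
    RI <- outer(seq_len(S), seq_len(S), function(j, k) k - j) + S_max
  } else RI <- NULL
  out <- block_fwd(array(x, c(1, S, ncol(x))), params, relb, RI, n_heads)$out
  matrix(out[1, , ], S)
}

#' Cross-attention fusion (single sequence)
#'
#' Queries from the layer-normalized SNP tokens; keys and values from the
#' GRM tokens; no positional term; residual + FFN wrapping.
#'
#' @param H_snp `S x D` SNP token matrix.
#' @param H_grm `m_g x D` GRM token matrix.
#' @param params fusion parameter list (as produced by [init_gvit()]).
#' @param n_heads head count.
#' @return list with `out` (`S x D`) and `attn` (`[heads, S, m_g]`).
#' @export
cross_attention_fuse <- function(H_snp, H_grm, params, n_heads = 1) {
  S <- nrow(H_snp); mg <- nrow(H_grm)
  X <- array(H_snp, c(1, S, ncol(H_snp)))
  Hg <- array(H_grm, c(1, mg, ncol(H_grm)))
  fw <- fusion_fwd(X, Hg, params, n_heads)
  A <- aperm(array(fw$cache$ca$P, c(S, mg, n_heads)), c(3, 1, 2))
  list(out = matrix(fw$out[1, , ], S), attn = A)
}

#' Regression head
#'
#' affine(D -> D/2) -> GELU -> dropout -> affine(-> 1). Deterministic in
#' eval mode (`train = FALSE`, the default).
#'
#' @param cls_state matrix `[B, D_in]` (a single vector is accepted).
#' @param params head parameter list.
#' @param dropout dropout rate (training mode only).
#' @param train enable dropout.
#' @return numeric predictions, one per row.
#' @export
regression_head <- function(cls_state, params, dropout = 0, train = FALSE) {
  U <- if (is.null(dim(cls_state))) matrix(cls_state, 1) else cls_state
  head_fwd(U, params, dropout, train)$pred
}
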