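# Tokenization of SNP sequences for the transformer.
#
# Three strategies: selective patch embedding (SPE: select loci, then patch
# the selected sequence), full-sequence patch embedding (FPE: patch the
# whole post-QC panel), and selective independent embedding (SIE: one token
# per selected locus). Patching uses a fixed patch COUNT N_p; the patch
# size adapts as P = ceil(L / N_p), with zero padding on the final patch.

#' Build a fixed-patch-count plan
#'
#' `P = ceiling(L / N_p)`, `pad = N_p * P - L`. When `L < N_p` the plan is
#' degenerate but legal: trailing patches are all padding, kept so the
#' token-sequence shape is constant across folds and datasets.
#'
#' @param L sequence length in markers.
#' @param N_p number of patches (default 400).
#' @return object of class `patch_plan`: list with `L`, `N_p`, `P`, `pad`,
#'   and `patch_ranges` (data.frame `start`,`end`, 1-based inclusive marker
#'   indices into the sequence; `end < start` marks an all-padding patch).
#' @export
make_patch_plan <- function(L, N_p = 400) {
  if (L < 1 || N_p < 1) gv_contract_error("L and N_p must be >= 1")
  P <- ceiling(L / N_p)
  pad <- N_p * P - L
  start <- (seq_len(N_p) - 1L) * P + 1L
  end <- pmin(seq_len(N_p) * P, L)
  structure(list(L = as.integer(L), N_p = as.integer(N_p), P = as.integer(P),
                 pad = as.integer(pad),
                 patch_ranges = data.frame(start = start, end = end)),
            class = "patch_plan")
}

#' @export
print.patch_plan <- function(x, ...) {
  cat(sprintf("patch_plan: L = %d markers -> N_p = %d patches of size P = %d (pad = %d)\n",
              x$L, x$N_p, x$P, x$pad))
  invisible(x)
}

#' Training-fold dosage preprocessing statistics
#'
#' Missing dosages are filled with `2 p_j` estimated on the training fold,
#' then each marker is standardized by its training-fold mean and sd
#' (constant markers get sd = 1). Applying training-fold statistics to
#' held-out rows keeps the embedding leakage-free.
#'
#' @param g a `genotype_matrix`.
#' @param train_ids training-fold sample ids.
#' @param marker_idx marker column indices the model will consume.
#' @return list with `marker_idx`, `fill` (2p), `center`, `scale`.
#' @export
dosage_stats <- function(g, train_ids, marker_idx) {
  freqs <- estimate_freqs(subset_genotypes(g, markers = marker_idx), train_ids)
  fill <- 2 * unname(freqs$p)
  rows <- match(train_ids, g$sample_ids)
  X <- g$dosages[rows, marker_idx, drop = FALSE]
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- fill[j]
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  list(marker_idx = marker_idx, fill = fill, center = ctr, scale = scl)
}

#' Preprocess dosage rows with training-fold statistics
#'
#' @param g a `genotype_matrix`.
#' @param sample_ids rows to transform (any cohort).
#' @param stats statistics from [dosage_stats()].
#' @return numeric matrix |samples| x |markers|, filled and standardized.
#' @export
prep_dosages <- function(g, sample_ids, stats) {
  rows <- match(sample_ids, g$sample_ids)
  if (anyNA(rows)) gv_validation_error("unknown sample id")
  X <- g$dosages[rows, stats$marker_idx, drop = FALSE]
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- stats$fill[j]
  X <- sweep(sweep(X, 2, stats$center), 2, stats$scale, "/")
  rownames(X) <- sample_ids
  X
}

# [B, L] -> [B, N_p, P] with zero padding beyond L.
build_patch_tensor <- function(X, plan) {
  B <- nrow(X)
  A <- array(0, c(B, plan$N_p, plan$P))
  pr <- plan$patch_ranges
  for (i in seq_len(plan$N_p)) {
    if (pr$end[i] >= pr$start[i]) {
      len <- pr$end[i] - pr$start[i] + 1L
      A[, i, seq_len(len)] <- X[, pr$start[i]:pr$end[i]]
    }
  }
  A
}

# shared embedding used by the tokenizers and the model forward pass
embed_patches <- function(Xp, W, b, cls) {
  d <- dim(Xp)                         # B x N_p x P
  D <- ncol(W)
  Tm <- matrix(Xp, d[1] * d[2], d[3]) %*% W +
    matrix(b, d[1] * d[2], D, byrow = TRUE)
  tokens <- array(0, c(d[1], d[2] + 1L, D))
  tokens[, 1, ] <- matrix(cls, d[1], D, byrow = TRUE)
  tokens[, -1, ] <- array(Tm, c(d[1], d[2], D))
  tokens
}

embed_scalars <- function(X, w, b, cls) {
  B <- nrow(X); k <- ncol(X); D <- length(w)
  tokens <- array(0, c(B, k + 1L, D))
  tokens[, 1, ] <- matrix(cls, B, D, byrow = TRUE)
  tokens[, -1, ] <- outer(X, w) + array(rep(b, each = B * k), c(B, k, D))
  tokens
}

new_token_batch <- function(tokens, plan, kind, marker_idx) {
  structure(list(tokens = tokens, plan = plan, kind = kind,
                 marker_idx = marker_idx, cls_index = 1L),
            class = "token_batch")
}

#' Selective patch embedding
#'
#' Gathers the selected markers in genomic order, splits them by the patch
#' plan (zero-padding the final patch), applies one shared affine map
#' `P -> D` to every flattened patch, and prepends the learnable `[CLS]`
#' token. Rows must already be preprocessed ([prep_dosages()]).
#'
#' @param g_rows preprocessed matrix (samples x selected markers).
#' @param selection a `selection_result` (its `k` must equal `plan$L`).
#' @param plan a `patch_plan`.
#' @param projection_params list with `W` (P x D) and `b` (length D).
#' @param cls_params length-D `[CLS]` vector.
#' @return a `token_batch` with `tokens` of shape (batch, N_p + 1, D).
#' @export
spe_tokenize <- function(g_rows, selection, plan, projection_params, cls_params) {
  if (plan$L != selection$k) {
    gv_contract_error(sprintf("plan length %d != selection k %d", plan$L, selection$k))
  }
  if (ncol(g_rows) != plan$L) gv_contract_error("g_rows/plan length mismatch")
  Xp <- build_patch_tensor(g_rows, plan)
  tokens <- embed_patches(Xp, projection_params$W, projection_params$b, cls_params)
  new_token_batch(tokens, plan, "spe", selection$selected)
}

#' Full-sequence patch embedding
#'
#' As [spe_tokenize()] but over the entire (post-QC) marker panel with no
#' selection stage; at fixed `N_p` the patch size grows with the panel.
#'
#' @param g_rows preprocessed matrix (samples x all markers).
#' @param plan a `patch_plan` with `L == ncol(g_rows)`.
#' @inheritParams spe_tokenize
#' @return a `token_batch` with `tokens` of shape (batch, N_p + 1, D).
#' @export
fpe_tokenize <- function(g_rows, plan, projection_params, cls_params) {
  if (ncol(g_rows) != plan$L) gv_contract_error("g_rows/plan length mismatch")
  Xp <- build_patch_tensor(g_rows, plan)
  tokens <- embed_patches(Xp, projection_params$W, projection_params$b, cls_params)
  new_token_batch(tokens, plan, "fpe", seq_len(plan$L))
}

#' Selective independent embedding
#'
#' Each selected marker's scalar dosage is mapped by a shared `1 -> D`
#' affine map to its own token; sequence length is `k + 1` with `[CLS]`.
#'
#' @param g_rows preprocessed matrix (samples x selected markers).
#' @param selection a `selection_result`.
#' @param projection_params list with `w` (length D) and `b` (length D).
#' @param cls_params length-D `[CLS]` vector.
#' @return a `token_batch` with `tokens` of shape (batch, k + 1, D).
#' @export
sie_tokenize <- function(g_rows, selection, projection_params, cls_params) {
  if (ncol(g_rows) != selection$k) gv_contract_error("g_rows/selection length mismatch")
  tokens <- embed_scalars(g_rows, projection_params$w, projection_params$b, cls_params)
  new_token_batch(tokens, NULL, "sie", selection$selected)
}

#' Map every selected marker to its patch
#'
#' Bookkeeping used by the interpretability export: each selected marker
#' index appears in exactly one patch range.
#'
#' @param plan a `patch_plan`.
#' @param marker_idx selected marker indices in sequence order.
#' @return integer vector: patch number for each marker.
#' @export
patch_of_marker <- function(plan, marker_idx) {
  pos <- seq_along(marker_idx)
  (pos - 1L) %/% plan$P + 1L
}
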