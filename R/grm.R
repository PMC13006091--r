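# VanRaden genomic relationship matrix and fold-aware relationship features.
#
# G = M* M*' / (2 * sum_j p_j (1 - p_j)), where M* is the dosage matrix
# centered by twice the second-allele frequency. Frequencies always come
# from a declared reference cohort so that held-out individuals can be
# represented purely by their relationship vectors to that cohort — the
# leakage-free construction the training protocol depends on.

#' Estimate second-allele frequencies on a cohort
#'
#' `p_j = sum_i M_ij / (2 n_j)` over the non-missing entries of the cohort's
#' rows only. Frequencies are cohort-specific by design: enlarging or
#' changing the cohort changes `p`.
#'
#' @param g a `genotype_matrix`.
#' @param cohort sample ids to estimate on (subset of `g$sample_ids`).
#' @return object of class `allele_freqs`: list with `p`, `n_used` (both
#'   named by marker id) and `source_cohort`.
#' @export
estimate_freqs <- function(g, cohort) {
  if (!length(cohort)) gv_contract_error("empty cohort")
  rows <- match(cohort, g$sample_ids)
  if (anyNA(rows)) gv_validation_error("cohort contains unknown sample ids")
  d <- g$dosages[rows, , drop = FALSE]
  n_used <- colSums(!is.na(d))
  if (any(n_used == 0)) {
    gv_stop(sprintf("markers all-missing within cohort: %s",
                    paste(g$map$id[n_used == 0], collapse = ", ")),
            "gvitgp_undefined_marker")
  }
  p <- colSums(d, na.rm = TRUE) / (2 * n_used)
  structure(list(p = stats::setNames(p, g$map$id),
                 n_used = stats::setNames(n_used, g$map$id),
                 source_cohort = as.character(cohort)),
            class = "allele_freqs")
}

# centered dosage rows for the given cohort: missing -> 2p (neutral after
# centering); markers monomorphic in the reference cohort are zeroed so they
# contribute nothing to the numerator (they already contribute nothing to
# the denominator).
centered_dosages <- function(g, freqs, cohort) {
  rows <- match(cohort, g$sample_ids)
  if (anyNA(rows)) gv_validation_error("cohort contains unknown sample ids")
  d <- g$dosages[rows, , drop = FALSE]
  p <- freqs$p
  miss <- is.na(d)
  d[miss] <- 0
  M <- d + miss * matrix(2 * p, nrow(d), ncol(d), byrow = TRUE)
  Mc <- M - matrix(2 * p, nrow(M), ncol(M), byrow = TRUE)
  mono <- p <= 0 | p >= 1
  if (any(mono)) Mc[, mono] <- 0
  rownames(Mc) <- cohort
  Mc
}

#' Compute a VanRaden relationship block
#'
#' Returns `M*_A M*_B' / denom` with `denom = 2 * sum_j p_j (1 - p_j)`.
#' With `rows == cols == freqs$source_cohort` this is the within-training
#' GRM; with `rows` a held-out cohort and `cols` the training cohort it
#' yields the held-out individuals' relationship vectors. Missing dosages
#' are filled with `2 p_j` before centering, so they contribute zero.
#'
#' @param g a `genotype_matrix`.
#' @param freqs an `allele_freqs` from [estimate_freqs()].
#' @param rows,cols sample-id vectors (default: the frequency source cohort).
#' @return |rows| x |cols| numeric matrix with sample-id dimnames.
#' @export
compute_grm <- function(g, freqs, rows = freqs$source_cohort,
                        cols = freqs$source_cohort) {
  p <- freqs$p
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) {
    gv_stop("all markers monomorphic in the reference cohort: GRM undefined",
            "gvitgp_degenerate_panel_error")
  }
  if (!length(rows)) {
    out <- matrix(0, 0, length(cols))
    colnames(out) <- cols
    return(out)
  }
  Ma <- centered_dosages(g, freqs, rows)
  Mb <- if (identical(as.character(rows), as.character(cols))) Ma else centered_dosages(g, freqs, cols)
  G <- Ma %*% t(Mb) / denom
  dimnames(G) <- list(rows, cols)
  G
}

#' Fold-aware GRM features
#'
#' Frequencies and the reference GRM come exclusively from `train_ids`;
#' evaluation individuals are represented only by their relationship vectors
#' to the training cohort and never influence frequency estimation.
#' Overlapping cohorts are a hard leakage failure.
#'
#' @param g a `genotype_matrix`.
#' @param train_ids reference (training) cohort sample ids.
#' @param eval_ids held-out sample ids (may be empty).
#' @return object of class `grm_features`: list with `G_ref`
#'   (n_ref x n_ref), `ref_ids`, `freqs`, `denom`, and `eval_vectors`
#'   (|eval| x n_ref).
#' @export
fold_grm_features <- function(g, train_ids, eval_ids = character(0)) {
  if (length(intersect(train_ids, eval_ids))) {
    gv_leakage_error("train and eval cohorts overlap: fold-aware GRM refused")
  }
  freqs <- estimate_freqs(g, train_ids)
  G_ref <- compute_grm(g, freqs, train_ids, train_ids)
  eval_vectors <- compute_grm(g, freqs, eval_ids, train_ids)
  structure(list(G_ref = G_ref, ref_ids = as.character(train_ids),
                 freqs = freqs, denom = 2 * sum(freqs$p * (1 - freqs$p)),
                 eval_vectors = eval_vectors),
            class = "grm_features")
}

#' Write / read a GRM block as TSV with sample-id headers
#' @param G relationship matrix with dimnames.
#' @param path file path.
#' @export
write_grm <- function(G, path) {
  utils::write.table(data.frame(sample_id = rownames(G), G, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_grm
#' @export
read_grm <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  G <- as.matrix(x[, -1, drop = FALSE])
  rownames(G) <- x[[1]]
  G
}
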