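# Interpretability: map [CLS] attention back to genomic coordinates
# (Manhattan-style export) and predicted-vs-observed summaries.

#' Manhattan-style table of [CLS] attention per patch
#'
#' Takes the `[CLS]` attention row of a chosen self-attention layer,
#' averages over heads and evaluation samples, drops the `[CLS]`-to-`[CLS]`
#' entry without renormalizing, and maps every non-padding patch to a
#' chromosome label (majority chromosome of its member markers) and a
#' representative position (median member bp). The significance threshold
#' is `mean + 3 sd` of the patch scores.
#'
#' @param report a `protocol_report` (with attention recorded), or a list
#'   with `attention`, `plan`, `selection`, `genotypes_map`.
#' @param layer self-attention layer index, or `"last"`.
#' @param head_agg aggregation over heads (only `"mean"`).
#' @param threshold_sd multiplier for the threshold rule.
#' @return data.frame (class `attention_manhattan`) with one row per
#'   non-padding patch: `patch`, `chrom`, `pos`, `score`,
#'   `above_threshold`, `members`; attributes `threshold` and
#'   `cls_self_weight`.
#' @export
attention_manhattan <- function(report, layer = "last", head_agg = "mean",
                                threshold_sd = 3) {
  head_agg <- match.arg(head_agg, "mean")
  attn <- report$attention
  if (is.null(attn) || !length(attn$self)) {
    gv_contract_error("no attention recorded: re-run prediction with record_attention = TRUE")
  }
  L <- length(attn$self)
  li <- if (identical(layer, "last")) L else as.integer(layer)
  if (li < 1 || li > L) gv_contract_error(sprintf("layer %s out of 1..%d", layer, L))
  A <- attn$self[[li]]                       # [B, heads, S]
  row <- apply(A, 3, mean)                   # average over samples and heads
  cls_self <- row[1]
  scores <- row[-1]

  plan <- report$plan
  sel_idx <- if (!is.null(report$selection)) report$selection$selected else seq_len(plan$L)
  map <- report$genotypes_map
  patch_id <- patch_of_marker(plan, sel_idx)
  nonpad <- which(plan$patch_ranges$end >= plan$patch_ranges$start)
  rows <- lapply(nonpad, function(i) {
    members <- sel_idx[patch_id == i]
    chroms <- map$chrom[members]
    maj <- names(sort(table(chroms), decreasing = TRUE))[1]
    data.frame(patch = i, chrom = maj,
               pos = stats::median(map$pos[members][chroms == maj]),
               score = scores[i],
               members = paste(map$id[members], collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  thr <- mean(out$score) + threshold_sd * stats::sd(out$score)
  out$above_threshold <- out$score > thr
  attr(out, "threshold") <- thr
  attr(out, "cls_self_weight") <- cls_self
  class(out) <- c("attention_manhattan", "data.frame")
  out
}

#' Write an attention Manhattan table as TSV
#' @param am an `attention_manhattan`.
#' @param path output path.
#' @export
write_attention_manhattan <- function(am, path) {
  utils::write.table(as.data.frame(am), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Plot an attention Manhattan table
#' @param am an `attention_manhattan`.
#' @param path output image path (png/svg by extension).
#' @return the ggplot object, invisibly.
#' @export
plot_attention_manhattan <- function(am, path = NULL) {
  df <- as.data.frame(am)
  df$chrom <- factor(df$chrom, levels = unique(df$chrom))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = patch, y = score, colour = chrom)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = attr(am, "threshold"),
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "patch (genomic order)", y = "[CLS] attention score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
  if (!is.null(path)) ggplot2::ggsave(path, p, width = 8, height = 3, dpi = 150)
  invisible(p)
}

#' Predicted-vs-observed density and scatter plots
#'
#' Writes a 2-D kernel-density plot with the y = x reference line and a
#' scatter plot with the fitted regression line and annotated Pearson r.
#' With fewer than 5 points the KDE is refused and only the scatter is
#' written.
#'
#' @param y_true,y_pred equal-length numeric vectors.
#' @param out_prefix path prefix; writes `<prefix>_density.png` and
#'   `<prefix>_scatter.png`.
#' @return list with written `files`, the fitted `slope`/`intercept`, and
#'   the annotated `r` (identical to [compute_metrics()]).
#' @export
prediction_density <- function(y_true, y_pred, out_prefix) {
  if (length(y_true) != length(y_pred)) gv_contract_error("length mismatch")
  df <- data.frame(pred = y_pred, obs = y_true)
  fitc <- stats::coef(stats::lm(obs ~ pred, data = df))
  r <- compute_metrics(y_true, y_pred)$r
  files <- character(0)

  scatter <- ggplot2::ggplot(df, ggplot2::aes(pred, obs)) +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "blue", linewidth = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "red") +
    ggplot2::annotate("text", x = min(df$pred), y = max(df$obs),
                      label = sprintf("r = %.3f", r), hjust = 0) +
    ggplot2::labs(x = "predicted", y = "observed") +
    ggplot2::theme_minimal()
  f_sc <- paste0(out_prefix, "_scatter.png")
  ggplot2::ggsave(f_sc, scatter, width = 4, height = 4, dpi = 150)
  files <- c(files, f_sc)

  if (length(y_true) >= 5 && stats::sd(y_pred) > 0 && stats::sd(y_true) > 0) {
    kde <- MASS::kde2d(df$pred, df$obs, n = 50)
    kdf <- expand.grid(pred = kde$x, obs = kde$y)
    kdf$density <- as.vector(kde$z)
    dens <- ggplot2::ggplot(kdf, ggplot2::aes(pred, obs, fill = density)) +
      ggplot2::geom_raster() +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                           colour = "red") +
      ggplot2::scale_fill_viridis_c() +
      ggplot2::labs(x = "predicted", y = "observed") +
      ggplot2::theme_minimal()
    f_de <- paste0(out_prefix, "_density.png")
    ggplot2::ggsave(f_de, dens, width = 4.5, height = 4, dpi = 150)
    files <- c(files, f_de)
  }
  list(files = files, slope = unname(fitc[2]), intercept = unname(fitc[1]), r = r)
}
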