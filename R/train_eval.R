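# Training and evaluation protocol: 80/20 hold-out, 5-fold nested CV with
# fold-nested locus selection and fold-aware GRM features, AdamW + cosine
# annealing + early stopping, standardized-scale metrics, a GBLUP-style
# kernel-ridge baseline, and the three ablation harnesses.

#' Training configuration
#'
#' @param lr peak learning rate (cosine-annealed to `lr_min`).
#' @param weight_decay decoupled AdamW weight decay (weight matrices only).
#' @param batch_size minibatch size.
#' @param max_epochs epoch budget.
#' @param patience early-stopping patience in epochs (must be < max_epochs);
#'   training stops after `patience + 1` consecutive non-improving epochs.
#' @param t_max cosine period (default `max_epochs`).
#' @param lr_min floor of the cosine schedule.
#' @param seed seed controlling shuffling and dropout.
#' @return a `train_config` list.
#' @export
train_config <- function(lr = 1e-4, weight_decay = 0.01, batch_size = 64,
                         max_epochs = 300, patience = 20, t_max = max_epochs,
                         lr_min = 0, seed = 1) {
  if (patience >= max_epochs) gv_config_error("patience must be < max_epochs")
  structure(list(lr = lr, weight_decay = weight_decay, batch_size = batch_size,
                 max_epochs = as.integer(max_epochs), patience = as.integer(patience),
                 t_max = t_max, lr_min = lr_min, seed = as.integer(seed)),
            class = "train_config")
}

# ---------------------------------------------------------------------------
# AdamW over the nested parameter tree

tree_zero <- function(p) if (is.list(p)) lapply(p, tree_zero) else p * 0

DECAY_NAMES <- c("We", "w", "Wq", "Wk", "Wv", "Wo", "W1", "W2")

adamw_step <- function(p, g, m, v, lr, wd, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  walk <- function(p, g, m, v, name) {
    if (is.list(p)) {
      keys <- if (is.null(names(p))) seq_along(p) else names(p)
      for (k in keys) {
        res <- walk(p[[k]], g[[k]], m[[k]], v[[k]], if (is.character(k)) k else name)
        p[[k]] <- res$p; m[[k]] <- res$m; v[[k]] <- res$v
      }
      list(p = p, m = m, v = v)
    } else {
      m <- b1 * m + (1 - b1) * g
      v <- b2 * v + (1 - b2) * g * g
      upd <- (m / (1 - b1^t)) / (sqrt(v / (1 - b2^t)) + eps)
      if (name %in% DECAY_NAMES) upd <- upd + wd * p
      list(p = p - lr * upd, m = m, v = v)
    }
  }
  walk(p, g, m, v, "")
}

cosine_lr <- function(epoch, tc) {
  tc$lr_min + 0.5 * (tc$lr - tc$lr_min) * (1 + cos(pi * min(epoch - 1, tc$t_max) / tc$t_max))
}

slice_inputs <- function(inputs, idx) {
  out <- list()
  if (!is.null(inputs$X_embed)) {
    out$X_embed <- if (length(dim(inputs$X_embed)) == 3) {
      inputs$X_embed[idx, , , drop = FALSE]
    } else inputs$X_embed[idx, , drop = FALSE]
  }
  if (!is.null(inputs$grm)) out$grm <- inputs$grm[idx, , drop = FALSE]
  out
}

n_inputs <- function(inputs) {
  if (!is.null(inputs$X_embed)) dim(inputs$X_embed)[1] else nrow(inputs$grm)
}

#' Train a model with AdamW, cosine annealing and early stopping
#'
#' Minimizes MSE. When a validation set is supplied, training stops after
#' `patience + 1` consecutive epochs without validation improvement and the
#' best-validation weights are restored; without one it runs the full
#' epoch budget. Fully deterministic given `tc$seed` (single-threaded
#' numerics; shuffling and dropout are seeded per epoch).
#'
#' @param model an initialized `gvit_model`.
#' @param train_inputs,y_train model inputs (see [gvit_forward()]) and
#'   standardized phenotypes for the training rows.
#' @param val_inputs,y_val optional validation set for early stopping.
#' @param tc a [train_config()].
#' @return a `gvit_fit`: list with `model` (best weights), `history`
#'   (per-epoch data.frame), `best_epoch`, `best_val_mse`.
#' @export
train_model <- function(model, train_inputs, y_train, val_inputs = NULL,
                        y_val = NULL, tc = train_config()) {
  n <- n_inputs(train_inputs)
  if (n != length(y_train)) gv_contract_error("y_train length mismatch")
  has_val <- !is.null(val_inputs)
  m_state <- tree_zero(model$params)
  v_state <- tree_zero(model$params)
  model$scratch <- NULL   # per-run encoder scratch buffers, reused across steps
  best_val <- Inf
  best_epoch <- 0L
  best_params <- model$params
  bad <- 0L
  t_step <- 0L
  hist <- list()
  for (epoch in seq_len(tc$max_epochs)) {
    lr_e <- cosine_lr(epoch, tc)
    set.seed(derive_seed(tc$seed, epoch))
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / tc$batch_size))
    ep_loss <- 0
    for (idx in batches) {
      lg <- tryCatch(
        gvit_loss_grad(model, slice_inputs(train_inputs, idx), y_train[idx]),
        error = function(e) {
          if (inherits(e, "gvitgp_numeric_error")) {
            gv_numeric_error(sprintf("training diverged at epoch %d (lr = %.3g)", epoch, lr_e))
          }
          stop(e)
        })
      model$scratch <- lg$scratch
      t_step <- t_step + 1L
      st <- adamw_step(model$params, lg$grads, m_state, v_state,
                       lr_e, tc$weight_decay, t_step)
      model$params <- st$p; m_state <- st$m; v_state <- st$v
      ep_loss <- ep_loss + lg$loss * length(idx)
    }
    ep_loss <- ep_loss / n
    val_mse <- NA_real_
    if (has_val) {
      pv <- gvit_predict(model, val_inputs)$pred
      val_mse <- mean((pv - y_val)^2)
      if (val_mse < best_val) {
        best_val <- val_mse
        best_epoch <- epoch
        best_params <- model$params
        bad <- 0L
      } else {
        bad <- bad + 1L
      }
    }
    hist[[epoch]] <- data.frame(epoch = epoch, lr = lr_e,
                                train_loss = ep_loss, val_mse = val_mse)
    if (has_val && bad > tc$patience) break
  }
  if (!has_val) {
    best_params <- model$params
    best_epoch <- tc$max_epochs
    best_val <- NA_real_
  }
  model$params <- best_params
  structure(list(model = model, history = do.call(rbind, hist),
                 best_epoch = best_epoch, best_val_mse = best_val,
                 train_config = tc),
            class = "gvit_fit")
}

# ---------------------------------------------------------------------------
# splits and metrics

#' 80/20 split with k validation folds
#'
#' Seeded shuffle; the test set never intersects the training/validation
#' set, and the folds partition the training/validation set exactly.
#'
#' @param ids sample ids (>= 10).
#' @param seed integer seed.
#' @param n_folds validation fold count (default 5).
#' @param test_frac hold-out fraction (default 0.2).
#' @return a `split_plan`: list with `train_val_ids`, `test_ids`, `folds`
#'   (list of id vectors), `seed`.
#' @export
make_split <- function(ids, seed, n_folds = 5, test_frac = 0.2) {
  n <- length(ids)
  if (n < 10) gv_config_error("need >= 10 samples to split")
  set.seed(seed)
  ids <- sample(ids)
  n_test <- round(test_frac * n)
  test_ids <- ids[seq_len(n_test)]
  train_val <- ids[-seq_len(n_test)]
  if (length(train_val) < n_folds) gv_config_error("too few samples for the fold count")
  fold_of <- rep(seq_len(n_folds), length.out = length(train_val))
  folds <- split(train_val, fold_of)
  structure(list(train_val_ids = train_val, test_ids = test_ids,
                 folds = unname(folds), seed = as.integer(seed)),
            class = "split_plan")
}

#' Train/test phenotype distribution consistency
#'
#' Mirrors the routine check that the hold-out split did not distort the
#' phenotype distribution: means, sds and the two-sample KS statistic.
#'
#' @param split a `split_plan`.
#' @param y named phenotype vector.
#' @return one-row data.frame.
#' @export
split_consistency <- function(split, y) {
  a <- y[split$train_val_ids]; b <- y[split$test_ids]
  ks <- suppressWarnings(stats::ks.test(a, b))
  data.frame(train_mean = mean(a), train_sd = stats::sd(a),
             test_mean = mean(b), test_sd = stats::sd(b),
             ks_stat = unname(ks$statistic), ks_p = ks$p.value)
}

#' Prediction metrics: Pearson r, R-squared, MSE
#'
#' `r` is the sample Pearson correlation (0 by convention, flagged, when
#' either side is constant); `R2 = 1 - SS_res / SS_tot` (can be negative);
#' `mse` the mean squared residual.
#'
#' @param y_true,y_pred equal-length numeric vectors (length >= 2).
#' @return list with `r`, `R2`, `mse` and attribute `constant_prediction`.
#' @export
compute_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) gv_contract_error("length mismatch")
  if (length(y_true) < 2) gv_contract_error("need >= 2 observations")
  constant <- stats::sd(y_pred) == 0 || stats::sd(y_true) == 0
  r <- if (constant) 0 else stats::cor(y_true, y_pred)
  ss_res <- sum((y_true - y_pred)^2)
  ss_tot <- sum((y_true - mean(y_true))^2)
  out <- list(r = r, R2 = 1 - ss_res / ss_tot, mse = mean((y_true - y_pred)^2))
  attr(out, "constant_prediction") <- constant
  out
}

#' One-sided permutation p-value for r > 0
#'
#' Permutes `y_true` against the fixed predictions; p is the fraction of
#' permuted correlations at least as large as the observed one (with the
#' +1 correction).
#'
#' @param y_true,y_pred numeric vectors.
#' @param n_perm number of shuffles.
#' @param seed integer seed.
#' @return p-value.
#' @export
permutation_pvalue <- function(y_true, y_pred, n_perm = 200, seed = 1) {
  r_obs <- stats::cor(y_true, y_pred)
  set.seed(seed)
  r_perm <- replicate(n_perm, stats::cor(sample(y_true), y_pred))
  (1 + sum(r_perm >= r_obs)) / (n_perm + 1)
}

# ---------------------------------------------------------------------------
# fold assembly

#' Assemble model inputs for one fold (leakage-free)
#'
#' Selection, allele frequencies, dosage standardization and phenotype
#' standardization all come from the training rows only; evaluation rows
#' are transformed with the training statistics and represented in the GRM
#' pathway by their relationship vectors to the training cohort.
#'
#' @param g a `genotype_matrix`.
#' @param y named phenotype vector.
#' @param train_ids,eval_ids disjoint cohorts.
#' @param selection a `selection_result`, or NULL for the full panel (FPE).
#' @param N_p patch count.
#' @param embed `"spe"`, `"fpe"` or `"sie"`.
#' @return list with `train`/`eval` input lists, standardized `y_train` /
#'   `y_eval`, `plan`, `stats`, `grmf`, `y_center`, `y_scale`.
#' @export
build_fold_inputs <- function(g, y, train_ids, eval_ids, selection, N_p = 400,
                              embed = "spe") {
  marker_idx <- if (is.null(selection)) seq_len(ncol(g$dosages)) else selection$selected
  stats <- dosage_stats(g, train_ids, marker_idx)
  Xtr <- prep_dosages(g, train_ids, stats)
  Xev <- if (length(eval_ids)) prep_dosages(g, eval_ids, stats) else NULL
  grmf <- fold_grm_features(g, train_ids, eval_ids)
  plan <- NULL
  if (embed %in% c("spe", "fpe")) {
    plan <- make_patch_plan(length(marker_idx), N_p)
    Xtr_e <- build_patch_tensor(Xtr, plan)
    Xev_e <- if (!is.null(Xev)) build_patch_tensor(Xev, plan) else NULL
  } else {
    Xtr_e <- Xtr
    Xev_e <- Xev
  }
  mu <- mean(y[train_ids]); sdv <- stats::sd(y[train_ids])
  if (sdv == 0) sdv <- 1
  list(train = list(X_embed = Xtr_e, grm = grmf$G_ref),
       eval = if (length(eval_ids)) list(X_embed = Xev_e, grm = grmf$eval_vectors) else NULL,
       y_train = (y[train_ids] - mu) / sdv,
       y_eval = if (length(eval_ids)) (y[eval_ids] - mu) / sdv else NULL,
       plan = plan, stats = stats, grmf = grmf,
       y_center = mu, y_scale = sdv)
}

model_config_for <- function(variant, embed, fold, n_train, model_args) {
  S <- if (embed == "sie") ncol(fold$train$X_embed) + 1L else fold$plan$N_p + 1L
  P <- if (embed == "sie") NULL else fold$plan$P
  defaults <- list(variant = variant, embed = embed, S = S, P = P,
                   n_ref = n_train)
  do.call(gvit_config, utils::modifyList(defaults, model_args))
}

#' Run the full nested protocol on one dataset
#'
#' Per fold: locus selection on the fold-training rows, fold-aware GRM,
#' training with early stopping on the fold-validation rows, validation
#' metrics. Then the selector and model are refit on the whole
#' training/validation split (for the median of the folds' best epochs,
#' with no early stopping, so the test set influences nothing) and
#' evaluated once on the untouched test set.
#'
#' @param g a `genotype_matrix`.
#' @param pheno phenotype data.frame.
#' @param trait trait column name.
#' @param variant model variant (see [gvit_config()]).
#' @param strategy selection strategy (`"gbdt"`, `"linear_svr"`,
#'   `"gwas_ld"`); baselines are run at the gbdt-matched k unless
#'   `select_args$k` is given.
#' @param embed embedding strategy.
#' @param seed protocol seed (split + selection + training).
#' @param n_folds validation folds.
#' @param N_p patch count.
#' @param model_args overrides for [gvit_config()].
#' @param train_args overrides for [train_config()].
#' @param select_args extra selector arguments.
#' @param record_attention record test-set `[CLS]` attention.
#' @return a `protocol_report`: list with `fold_metrics` (one row per
#'   fold), `test_metrics`, `consistency`, `split`, `selection`, `plan`,
#'   `fit`, `predictions`, `y_test`, `attention`.
#' @export
run_protocol <- function(g, pheno, trait = "trait", variant = "gvit_gp",
                         strategy = "gbdt", embed = "spe", seed = 1,
                         n_folds = 5, N_p = 400, model_args = list(),
                         train_args = list(), select_args = list(),
                         record_attention = TRUE) {
  y <- pheno_vector(pheno, trait)
  ids <- intersect(g$sample_ids, names(y))
  split <- make_split(ids, seed, n_folds)
  consistency <- split_consistency(split, y)

  select_for <- function(train_ids) {
    if (strategy == "gbdt") {
      do.call(run_selection, c(list("gbdt", g, y, train_ids, seed = seed,
                                    allowed_ids = train_ids), select_args))
    } else {
      k <- select_args$k
      sa <- select_args; sa$k <- NULL
      if (is.null(k)) {
        k <- select_gbdt(g, y, train_ids, seed = seed, allowed_ids = train_ids)$k
      }
      do.call(run_selection, c(list(strategy, g, y, train_ids, k = k,
                                    allowed_ids = train_ids), sa))
    }
  }

  fold_rows <- list()
  best_epochs <- integer(0)
  for (f in seq_along(split$folds)) {
    val_ids <- split$folds[[f]]
    train_ids <- setdiff(split$train_val_ids, val_ids)
    sel <- if (embed == "fpe") NULL else select_for(train_ids)
    fold <- build_fold_inputs(g, y, train_ids, val_ids, sel, N_p, embed)
    cfg <- model_config_for(variant, embed, fold, length(train_ids), model_args)
    model <- init_gvit(cfg)
    tc <- do.call(train_config, utils::modifyList(list(seed = derive_seed(seed, f)),
                                                  train_args))
    fit <- train_model(model, fold$train, fold$y_train, fold$eval, fold$y_eval, tc)
    pv <- gvit_predict(fit$model, fold$eval)$pred
    mets <- compute_metrics(fold$y_eval, pv)
    fold_rows[[f]] <- data.frame(fold = f, n_train = length(train_ids),
                                 n_val = length(val_ids),
                                 k = if (is.null(sel)) ncol(g$dosages) else sel$k,
                                 best_epoch = fit$best_epoch,
                                 r = mets$r, R2 = mets$R2, mse = mets$mse)
    best_epochs <- c(best_epochs, fit$best_epoch)
  }

  # refit on the full 80% for the median fold-best epoch; test untouched
  train_ids <- split$train_val_ids
  sel <- if (embed == "fpe") NULL else select_for(train_ids)
  fold <- build_fold_inputs(g, y, train_ids, split$test_ids, sel, N_p, embed)
  cfg <- model_config_for(variant, embed, fold, length(train_ids), model_args)
  model <- init_gvit(cfg)
  refit_epochs <- max(1L, as.integer(stats::median(best_epochs)))
  tc <- do.call(train_config, utils::modifyList(list(seed = derive_seed(seed, 97L)),
                                                train_args))
  tc$max_epochs <- refit_epochs
  tc$patience <- min(tc$patience, refit_epochs - 1L)
  if (tc$patience < 0) tc$patience <- 0L
  fit <- train_model(model, fold$train, fold$y_train, NULL, NULL, tc)
  pr <- gvit_predict(fit$model, fold$eval, record_attention = record_attention)
  test_metrics <- compute_metrics(fold$y_eval, pr$pred)

  structure(list(fold_metrics = do.call(rbind, fold_rows),
                 test_metrics = test_metrics, consistency = consistency,
                 split = split, selection = sel, plan = fold$plan,
                 stats = fold$stats, fit = fit,
                 predictions = stats::setNames(pr$pred, split$test_ids),
                 y_test = fold$y_eval, attention = pr$attention,
                 variant = variant, strategy = strategy, embed = embed,
                 seed = seed, genotypes_map = g$map),
            class = "protocol_report")
}

#' @export
print.protocol_report <- function(x, ...) {
  cat(sprintf("protocol_report[%s/%s/%s]: test r = %.3f, R2 = %.3f, mse = %.3f (%d folds)\n",
              x$variant, x$embed, x$strategy, x$test_metrics$r,
              x$test_metrics$R2, x$test_metrics$mse, nrow(x$fold_metrics)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# linear baseline

#' GBLUP-style kernel-ridge baseline on the GRM
#'
#' Solves `(G + lambda I) alpha = y - mean(y)` on the training cohort with
#' `lambda` chosen by inner cross-validation, and predicts evaluation
#' individuals through their relationship vectors: `G_eval alpha + mean`.
#'
#' @param G_train n x n training GRM.
#' @param y_train training phenotypes (same order).
#' @param G_eval_train |eval| x n relationship vectors.
#' @param lambdas candidate ridge penalties.
#' @param n_folds inner CV folds.
#' @param seed fold-assignment seed.
#' @return list with `pred`, `lambda`, `cv_mse`.
#' @export
gblup_ridge_baseline <- function(G_train, y_train, G_eval_train,
                                 lambdas = 10^seq(-3, 3, length.out = 13),
                                 n_folds = 5, seed = 1) {
  n <- nrow(G_train)
  if (length(y_train) != n) gv_contract_error("y_train length mismatch")
  set.seed(seed)
  fold_of <- sample(rep(seq_len(n_folds), length.out = n))
  cv_mse <- vapply(lambdas, function(lam) {
    errs <- 0
    for (f in seq_len(n_folds)) {
      tr <- which(fold_of != f); va <- which(fold_of == f)
      mu <- mean(y_train[tr])
      a <- tryCatch(solve(G_train[tr, tr] + diag(lam, length(tr)), y_train[tr] - mu),
                    error = function(e) gv_numeric_error("singular kernel system"))
      pred <- drop(G_train[va, tr, drop = FALSE] %*% a) + mu
      errs <- errs + sum((pred - y_train[va])^2)
    }
    errs / n
  }, numeric(1))
  lam <- lambdas[which.min(cv_mse)]
  mu <- mean(y_train)
  a <- tryCatch(solve(G_train + diag(lam, n), y_train - mu),
                error = function(e) gv_numeric_error("singular kernel system"))
  pred <- drop(G_eval_train %*% a) + mu
  list(pred = pred, lambda = lam, cv_mse = stats::setNames(cv_mse, lambdas))
}

# ---------------------------------------------------------------------------
# ablation harness

train_one_arm <- function(g, y, split, variant, embed, selection, N_p,
                          model_args, train_args, seed) {
  # train on folds 2..K, early-stop on fold 1, evaluate once on the test set
  val_ids <- split$folds[[1]]
  train_ids <- setdiff(split$train_val_ids, val_ids)
  sel_use <- if (embed == "fpe") NULL else selection
  fold <- build_fold_inputs(g, y, train_ids, val_ids, sel_use, N_p, embed)
  cfg <- model_config_for(variant, embed, fold, length(train_ids), model_args)
  model <- init_gvit(cfg)
  tc <- do.call(train_config, utils::modifyList(list(seed = seed), train_args))
  fit <- train_model(model, fold$train, fold$y_train, fold$eval, fold$y_eval, tc)
  test_fold <- build_fold_inputs(g, y, train_ids, split$test_ids, sel_use, N_p, embed)
  pv <- gvit_predict(fit$model, test_fold$eval)$pred
  compute_metrics(test_fold$y_eval, pv)
}

#' Run an ablation study
#'
#' Arms share the identical split, selection (where applicable), seeds and
#' backbone per repetition, so differences isolate the ablated component:
#' `embedding` compares SPE/SIE/FPE; `fusion` compares gvit_base, grm_mlp,
#' gvit_concat and gvit_gp; `selection` compares gbdt, linear_svr and
#' gwas_ld at the gbdt-matched k (fixed-k contract).
#'
#' @param which `"embedding"`, `"fusion"` or `"selection"`.
#' @param g a `genotype_matrix`.
#' @param pheno phenotype data.frame.
#' @param trait trait column.
#' @param seeds one repetition per seed.
#' @param N_p patch count.
#' @param model_args,train_args,select_args configuration overrides.
#' @param arms optional subset of arm labels to run (default: all arms of
#'   the chosen study); the shared split/selection discipline is unchanged.
#' @return list with `records` (one row per seed x arm) and `table`
#'   (per-arm means of r, R2, mse).
#' @export
run_ablation <- function(which = c("embedding", "fusion", "selection"), g, pheno,
                         trait = "trait", seeds = 1:5, N_p = 400,
                         model_args = list(), train_args = list(),
                         select_args = list(), arms = NULL) {
  which <- match.arg(which)
  y <- pheno_vector(pheno, trait)
  ids <- intersect(g$sample_ids, names(y))
  records <- list()
  for (seed in seeds) {
    split <- make_split(ids, seed)
    val_ids <- split$folds[[1]]
    train_ids <- setdiff(split$train_val_ids, val_ids)
    gb <- do.call(select_gbdt, c(list(g, y, train_ids, seed = seed,
                                      allowed_ids = train_ids), select_args))
    arms_all <- switch(which,
      embedding = list(list(arm = "spe", variant = "gvit_gp", embed = "spe", sel = gb),
                       list(arm = "sie", variant = "gvit_gp", embed = "sie", sel = gb),
                       list(arm = "fpe", variant = "gvit_gp", embed = "fpe", sel = NULL)),
      fusion = lapply(c("gvit_base", "grm_mlp", "gvit_concat", "gvit_gp"),
                      function(v) list(arm = v, variant = v, embed = "spe", sel = gb)),
      selection = {
        k <- gb$k
        svr <- select_linear_svr(g, y, train_ids, k = k, allowed_ids = train_ids)
        gl <- select_gwas_ld(g, y, train_ids, k = min(k, length(ld_prune(g, train_ids))),
                             allowed_ids = train_ids)
        if (gl$k != k) {
          gv_contract_error(sprintf("fixed-k contract violated: gwas_ld k = %d != gbdt k = %d",
                                    gl$k, k))
        }
        list(list(arm = "gbdt", variant = "gvit_gp", embed = "spe", sel = gb),
             list(arm = "linear_svr", variant = "gvit_gp", embed = "spe", sel = svr),
             list(arm = "gwas_ld", variant = "gvit_gp", embed = "spe", sel = gl))
      })
    if (!is.null(arms)) {
      labels <- vapply(arms_all, function(a) a$arm, character(1))
      unknown <- setdiff(arms, labels)
      if (length(unknown)) gv_config_error(sprintf("unknown arm(s): %s", paste(unknown, collapse = ", ")))
      arms_run <- arms_all[labels %in% arms]
    } else arms_run <- arms_all
    for (a in arms_run) {
      mets <- train_one_arm(g, y, split, a$variant, a$embed, a$sel, N_p,
                            model_args, train_args, derive_seed(seed, 11L))
      records[[length(records) + 1L]] <-
        data.frame(seed = seed, arm = a$arm, r = mets$r, R2 = mets$R2,
                   mse = mets$mse)
    }
  }
  records <- do.call(rbind, records)
  tab <- stats::aggregate(records[c("r", "R2", "mse")],
                          by = list(arm = records$arm), FUN = mean)
  list(records = records, table = tab)
}
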