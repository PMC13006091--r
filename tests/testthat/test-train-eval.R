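test_that("splits are reproducible 80/20 partitions with exact folds", {
  ids <- sprintf("s%03d", 1:100)
  sp <- make_split(ids, 5)
  expect_length(sp$test_ids, 20)
  expect_length(sp$train_val_ids, 80)
  expect_equal(sort(unlist(sp$folds)), sort(sp$train_val_ids))
  expect_equal(lengths(sp$folds), rep(16L, 5))
  expect_length(intersect(sp$test_ids, sp$train_val_ids), 0)
  expect_identical(make_split(ids, 5), sp)
  expect_false(identical(make_split(ids, 6)$test_ids, sp$test_ids))
  expect_error(make_split(ids[1:5], 1), class = "gvitgp_config_error")
})

test_that("compute_metrics matches independent closed forms", {
  y <- c(0, 1, 2, 3); yp <- c(0, 2, 1, 3)
  m <- compute_metrics(y, yp)
  # independent oracles: cor(), lm() R-squared of residuals, mean residual^2
  expect_equal(m$r, cor(y, yp), tolerance = 1e-12)
  expect_equal(m$mse, mean((y - yp)^2), tolerance = 1e-12)
  expect_equal(m$R2, 1 - sum((y - yp)^2) / sum((y - mean(y))^2), tolerance = 1e-12)

  expect_equal(compute_metrics(y, y), list(r = 1, R2 = 1, mse = 0),
               ignore_attr = TRUE)
  mc <- compute_metrics(y, rep(mean(y), 4))
  expect_equal(mc$r, 0)                       # constant-prediction convention
  expect_equal(mc$R2, 0)
  expect_equal(mc$mse, mean((y - mean(y))^2))
  expect_true(attr(mc, "constant_prediction"))
  expect_error(compute_metrics(1:3, 1:4), class = "gvitgp_contract_error")

  set.seed(6)
  for (i in 1:10) {
    a <- rnorm(20); b <- rnorm(20)
    mm <- compute_metrics(a, b)
    expect_equal(mm$r, cor(a, b), tolerance = 1e-12)
    expect_equal(mm$R2, 1 - sum((a - b)^2) / sum((a - mean(a))^2), tolerance = 1e-12)
  }
})

tiny_train_setup <- function(seed = 1, n = 60, L = 30, N_p = 6, D = 8) {
  set.seed(seed)
  X <- matrix(rnorm(n * L), n)
  beta <- c(rep(1.5, 3), rep(0, L - 3))
  y <- drop(X %*% beta) + rnorm(n, sd = 0.3)
  y <- (y - mean(y)) / sd(y)
  plan <- make_patch_plan(L, N_p)
  Xp <- gvitgp:::build_patch_tensor(X, plan)
  G <- tcrossprod(X) / L
  tr <- 1:45; va <- 46:60
  cfg <- gvit_config("gvit_gp", "spe", S = N_p + 1, P = plan$P, D = D,
                     n_heads = 2, L_pre = 1, L_post = 1, ffn_mult = 2,
                     n_ref = length(tr), grm_hidden = 16, dropout = 0, seed = seed)
  list(model = init_gvit(cfg),
       train = list(X_embed = Xp[tr, , , drop = FALSE], grm = G[tr, tr]),
       val = list(X_embed = Xp[va, , , drop = FALSE], grm = G[va, tr]),
       y_train = y[tr], y_val = y[va])
}

test_that("training reduces the loss on a learnable trait and is deterministic", {
  st <- tiny_train_setup()
  tc <- train_config(lr = 3e-3, batch_size = 16, max_epochs = 15, patience = 14, seed = 2)
  fit <- train_model(st$model, st$train, st$y_train, st$val, st$y_val, tc)
  expect_lt(min(fit$history$train_loss), fit$history$train_loss[1])
  expect_lte(fit$best_epoch, nrow(fit$history))
  expect_equal(fit$best_val_mse, min(fit$history$val_mse))

  fit2 <- train_model(tiny_train_setup()$model, st$train, st$y_train,
                      st$val, st$y_val, tc)
  expect_identical(fit$history, fit2$history)
  expect_equal(fit$model$params, fit2$model$params)
})

test_that("patience = 0 stops at the first non-improving epoch", {
  st <- tiny_train_setup(seed = 3)
  tc <- train_config(lr = 3e-3, batch_size = 16, max_epochs = 30, patience = 0, seed = 2)
  fit <- train_model(st$model, st$train, st$y_train, st$val, st$y_val, tc)
  h <- fit$history
  stopped <- nrow(h)
  if (stopped < tc$max_epochs) {
    # the stopping epoch is exactly one past the last improvement
    expect_equal(fit$best_epoch, stopped - 1L)
  }
  # restored weights reproduce the best validation mse
  pv <- gvit_predict(fit$model, st$val)$pred
  expect_equal(mean((pv - st$y_val)^2), fit$best_val_mse, tolerance = 1e-12)
})

test_that("gblup ridge behaves like a kernel ridge at its limits", {
  ds <- small_sim(seed = 111)
  g <- ds$genotypes
  y <- pheno_vector(ds$phenotypes, "trait")
  train <- g$sample_ids[1:48]
  evalc <- g$sample_ids[49:64]
  ff <- fold_grm_features(g, train, evalc)
  # lambda -> infinity: predictions collapse to the training mean
  big <- gblup_ridge_baseline(ff$G_ref, y[train], ff$eval_vectors, lambdas = 1e8)
  expect_equal(unname(big$pred), rep(mean(y[train]), 16), tolerance = 1e-3)
  # an eval duplicate of a training individual approaches its fitted value
  g2 <- g
  g2$dosages[49, ] <- g$dosages[1, ]
  ff2 <- fold_grm_features(g2, train, evalc)
  small <- gblup_ridge_baseline(ff2$G_ref, y[train], ff2$eval_vectors, lambdas = 1e-6)
  fitted1 <- drop(ff2$G_ref[1, ] %*% solve(ff2$G_ref + diag(1e-6, 48), y[train] - mean(y[train]))) + mean(y[train])
  expect_equal(unname(small$pred[1]), fitted1, tolerance = 1e-6)
})

test_that("the ridge baseline predicts an additive kinship-structured trait", {
  cfg <- sim_config(n_families = 15, offspring_per_family = 12, n_markers = 400,
                    n_chromosomes = 4, n_causal_additive = 20,
                    n_causal_epistatic_pairs = 0, h2 = 0.8, missing_rate = 0,
                    seed = 131)
  ds <- simulate_dataset(cfg)      # n = 210
  g <- ds$genotypes
  y <- pheno_vector(ds$phenotypes, "trait")
  train <- g$sample_ids[1:160]
  evalc <- g$sample_ids[161:210]
  ff <- fold_grm_features(g, train, evalc)
  cv <- gblup_ridge_baseline(ff$G_ref, y[train], ff$eval_vectors)
  expect_gt(cor(cv$pred, y[evalc]), 0)
})

test_that("the full protocol emits 5 fold records and 1 test record", {
  cfg <- sim_config(n_families = 10, offspring_per_family = 6, n_markers = 150,
                    n_chromosomes = 3, seed = 121, missing_rate = 0.01)
  ds <- simulate_dataset(cfg)      # n = 80
  rep <- run_protocol(ds$genotypes, ds$phenotypes, "trait",
                      variant = "gvit_gp", strategy = "gbdt", seed = 5, N_p = 10,
                      model_args = list(D = 16, n_heads = 2, L_pre = 1, L_post = 1,
                                        ffn_mult = 2, grm_hidden = 16, dropout = 0),
                      train_args = list(lr = 2e-3, batch_size = 16, max_epochs = 4,
                                        patience = 3),
                      select_args = list(nrounds = 50))
  expect_equal(nrow(rep$fold_metrics), 5L)
  expect_true(all(c("r", "R2", "mse") %in% names(rep$fold_metrics)))
  expect_length(rep$predictions, length(rep$split$test_ids))
  expect_s3_class(rep$consistency, "data.frame")
  expect_false(is.null(rep$attention))
  # determinism of the whole pipeline under an identical seed
  rep2 <- run_protocol(ds$genotypes, ds$phenotypes, "trait",
                       variant = "gvit_gp", strategy = "gbdt", seed = 5, N_p = 10,
                       model_args = list(D = 16, n_heads = 2, L_pre = 1, L_post = 1,
                                         ffn_mult = 2, grm_hidden = 16, dropout = 0),
                       train_args = list(lr = 2e-3, batch_size = 16, max_epochs = 4,
                                         patience = 3),
                       select_args = list(nrounds = 50))
  expect_identical(rep2$test_metrics, rep$test_metrics)
  expect_identical(rep2$fold_metrics, rep$fold_metrics)
})

test_that("permutation p-value is calibrated at its extremes", {
  set.seed(9)
  y <- rnorm(100)
  expect_lt(permutation_pvalue(y, y + rnorm(100, sd = 0.1), 200, 1), 0.01)
  expect_gt(permutation_pvalue(y, rnorm(100), 200, 1), 0.05)
})
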