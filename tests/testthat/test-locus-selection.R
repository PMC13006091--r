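sim_sel <- function(seed = 17) {
  cfg <- sim_config(n_families = 10, offspring_per_family = 10, n_markers = 200,
                    n_chromosomes = 2, ld_rho = 0, missing_rate = 0,
                    n_causal_additive = 3, n_causal_epistatic_pairs = 0,
                    seed = seed)
  simulate_genotypes(cfg)$genotypes
}

test_that("gbdt selector finds a single causal marker and is deterministic", {
  g <- sim_sel()
  y <- g$dosages[, 7] + rnorm(nrow(g$dosages), sd = 0.01)
  names(y) <- g$sample_ids
  sel <- select_gbdt(g, y, g$sample_ids, seed = 3, nrounds = 100)
  expect_true(7 %in% sel$selected)
  expect_equal(unname(which.max(sel$scores)), match(7, sel$selected))
  sel2 <- select_gbdt(g, y, g$sample_ids, seed = 3, nrounds = 100)
  expect_identical(sel$selected, sel2$selected)
  # selection is sparse on pure noise
  set.seed(5)
  yn <- rnorm(nrow(g$dosages)); names(yn) <- g$sample_ids
  seln <- select_gbdt(g, yn, g$sample_ids, seed = 3, nrounds = 50)
  expect_lt(seln$k, ncol(g$dosages))
  # genomic order
  expect_true(!is.unsorted(sel$selected))
})

test_that("linear SVR selector recovers planted effects and honors k", {
  g <- sim_sel(seed = 23)
  y <- 3 * g$dosages[, 5] - 3 * g$dosages[, 9] + rnorm(nrow(g$dosages), sd = 0.01)
  names(y) <- g$sample_ids
  sel <- select_linear_svr(g, y, g$sample_ids, k = 2)
  expect_setequal(sel$selected, c(5, 9))
  all_sel <- select_linear_svr(g, y, g$sample_ids, k = ncol(g$dosages))
  expect_equal(all_sel$selected, seq_len(ncol(g$dosages)))
  expect_error(select_linear_svr(g, y, g$sample_ids, k = ncol(g$dosages) + 1),
               class = "gvitgp_config_error")
})

test_that("GWAS p-values match the lm() oracle and obey conventions", {
  g <- sim_sel(seed = 29)
  set.seed(1)
  y <- g$dosages[, 3] * 0.5 + rnorm(nrow(g$dosages))
  names(y) <- g$sample_ids
  p <- gwas_single_marker(g, y, g$sample_ids)
  for (j in c(1, 3, 10, 50)) {
    o <- summary(lm(y ~ g$dosages[, j]))$coefficients[2, 4]
    expect_equal(unname(p[j]), o, tolerance = 1e-10)
  }
  # perfect fit -> essentially zero; monomorphic -> 1
  y2 <- g$dosages[, 3]; names(y2) <- g$sample_ids
  p2 <- gwas_single_marker(g, y2, g$sample_ids)
  expect_lt(p2[3], 1e-10)
  g2 <- tiny_genotypes(cbind(rep(1, 10), rbinom(10, 2, 0.4)))
  y3 <- rnorm(10); names(y3) <- g2$sample_ids
  expect_equal(unname(gwas_single_marker(g2, y3, g2$sample_ids)[1]), 1)
})

test_that("LD pruning removes duplicates by MAF and respects chromosomes", {
  set.seed(3)
  a <- rbinom(60, 2, 0.25)        # lower MAF
  b <- rbinom(60, 2, 0.45)
  g <- genotype_matrix(cbind(a, a, b),
                       data.frame(id = c("x1", "x2", "x3"),
                                  chrom = c("1", "1", "2"),
                                  pos = c(1000, 2000, 1000)),
                       sprintf("s%02d", 1:60))
  surv <- ld_prune(g)
  expect_equal(sum(surv %in% 1:2), 1L)      # exactly one of the duplicates
  expect_true(3 %in% surv)                  # other chromosome untouched
  # identical duplicated columns tie on MAF -> the later-position one is removed
  expect_true(1 %in% surv)

  # cross-chromosome duplicates are never pruned against each other
  g2 <- genotype_matrix(cbind(a, a),
                        data.frame(id = c("y1", "y2"), chrom = c("1", "2"),
                                   pos = c(1000, 1000)),
                        sprintf("s%02d", 1:60))
  expect_equal(ld_prune(g2), c(1L, 2L))
})

test_that("independent markers mostly survive pruning", {
  cfg <- sim_config(n_families = 125, offspring_per_family = 0,
                    n_founders_per_family = 4, n_markers = 500,
                    n_chromosomes = 2, ld_rho = 0, missing_rate = 0,
                    n_causal_additive = 3, n_causal_epistatic_pairs = 0, seed = 37)
  g <- simulate_genotypes(cfg)$genotypes
  surv <- ld_prune(g)
  expect_gte(length(surv) / ncol(g$dosages), 0.95)
})

test_that("gwas_ld selection keeps the strongest signal and returns genomic order", {
  g <- sim_sel(seed = 43)
  y <- 2 * g$dosages[, 150] + rnorm(nrow(g$dosages), sd = 0.5)
  names(y) <- g$sample_ids
  sel <- select_gwas_ld(g, y, g$sample_ids, k = 10)
  expect_true(150 %in% sel$selected)
  expect_true(!is.unsorted(sel$selected))
  surv <- ld_prune(g)
  all_surv <- select_gwas_ld(g, y, g$sample_ids, k = length(surv))
  expect_equal(all_surv$selected, surv)
  expect_error(select_gwas_ld(g, y, g$sample_ids, k = length(surv) + 1),
               "survivors", class = "gvitgp_config_error")
})

test_that("all selectors refuse ids outside the declared training fold", {
  g <- sim_sel(seed = 47)
  y <- rnorm(nrow(g$dosages)); names(y) <- g$sample_ids
  fold <- g$sample_ids[1:50]
  outside <- g$sample_ids[1:60]
  expect_error(select_gbdt(g, y, outside, allowed_ids = fold),
               class = "gvitgp_leakage_error")
  expect_error(select_linear_svr(g, y, outside, k = 5, allowed_ids = fold),
               class = "gvitgp_leakage_error")
  expect_error(select_gwas_ld(g, y, outside, k = 5, allowed_ids = fold),
               class = "gvitgp_leakage_error")
  expect_error(gwas_single_marker(g, y, outside, allowed_ids = fold),
               class = "gvitgp_leakage_error")
})

test_that("selection serializes to TSV + JSON sidecar", {
  g <- sim_sel(seed = 53)
  y <- g$dosages[, 2] + rnorm(nrow(g$dosages), sd = 0.1)
  names(y) <- g$sample_ids
  sel <- select_gbdt(g, y, g$sample_ids, seed = 1, nrounds = 50)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_selection(sel, g, f)
  tab <- read.table(f, header = TRUE, sep = "\t")
  expect_equal(nrow(tab), sel$k)
  side <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(side$strategy, "gbdt")
  expect_equal(side$k, sel$k)
})
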