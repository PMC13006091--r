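test_that("allele frequencies are cohort-specific and error on all-missing markers", {
  g <- tiny_genotypes(rbind(c(0, 2), c(1, 2), c(2, NA), c(2, NA)))
  fr_a <- estimate_freqs(g, c("s01", "s02", "s03"))
  expect_equal(unname(fr_a$p), c(0.5, 1))
  fr_b <- estimate_freqs(g, g$sample_ids)             # enlarging the cohort moves p
  expect_false(isTRUE(all.equal(fr_a$p[["m01"]], fr_b$p[["m01"]])))
  expect_equal(unname(fr_a$n_used), c(3, 2))
  expect_error(estimate_freqs(g, c("s03", "s04")), "m02",
               class = "gvitgp_undefined_marker")
})

test_that("compute_grm reproduces the worked 3x2 fixture", {
  g <- tiny_genotypes(rbind(c(0, 2), c(2, 0), c(1, 1)))
  fr <- estimate_freqs(g, g$sample_ids)
  expect_equal(unname(fr$p), c(0.5, 0.5))
  G <- compute_grm(g, fr)                              # denom = 2(0.25+0.25) = 1
  expect_equal(unname(G), rbind(c(2, -2, 0), c(-2, 2, 0), c(0, 0, 0)))
})

test_that("identical genotype rows give equal diagonal and off-diagonal entries", {
  g <- tiny_genotypes(rbind(c(0, 1, 2, 0), c(0, 1, 2, 0), c(2, 1, 0, 1)))
  fr <- estimate_freqs(g, g$sample_ids)
  G <- compute_grm(g, fr)
  expect_equal(G[1, 1], G[2, 2])
  expect_equal(G[1, 2], G[1, 1])
})

test_that("compute_grm matches the elementwise brute-force oracle on random panels", {
  set.seed(13)
  for (rep in 1:20) {
    dos <- matrix(rbinom(20 * 50, 2, runif(1, 0.1, 0.5)), 20, 50)
    dos[sample(length(dos), 30)] <- NA
    g <- tiny_genotypes(dos)
    cohort <- g$sample_ids[1:12]
    fr <- estimate_freqs(g, cohort)
    G <- compute_grm(g, fr, g$sample_ids[13:20], cohort)
    O <- grm_oracle(g$dosages, unname(fr$p), 13:20, 1:12)
    expect_equal(unname(G), O, tolerance = 1e-10)
  }
})

test_that("the training GRM is symmetric and positive semi-definite", {
  ds <- small_sim(seed = 81)
  fr <- estimate_freqs(ds$genotypes, ds$genotypes$sample_ids)
  G <- compute_grm(ds$genotypes, fr)
  expect_lt(max(abs(G - t(G))), 1e-10)
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)
})

test_that("monomorphic markers contribute nothing to the GRM", {
  dos <- rbind(c(0, 1, 2), c(2, 1, 0), c(1, 1, 1))
  g_with <- tiny_genotypes(cbind(dos, rep(2, 3)))      # monomorphic column
  g_without <- tiny_genotypes(dos)
  fr_w <- estimate_freqs(g_with, g_with$sample_ids)
  fr_o <- estimate_freqs(g_without, g_without$sample_ids)
  expect_equal(unname(compute_grm(g_with, fr_w)), unname(compute_grm(g_without, fr_o)))
  # an entirely monomorphic panel has no defined GRM
  g_mono <- tiny_genotypes(cbind(rep(2, 3), rep(0, 3)))
  fr_m <- estimate_freqs(g_mono, g_mono$sample_ids)
  expect_error(compute_grm(g_mono, fr_m), class = "gvitgp_degenerate_panel_error")
})

test_that("fold_grm_features is leakage-free", {
  ds <- small_sim(seed = 91)
  g <- ds$genotypes
  train <- g$sample_ids[1:40]
  evalc <- g$sample_ids[41:60]
  ff <- fold_grm_features(g, train, evalc)
  expect_equal(dim(ff$eval_vectors), c(20L, 40L))
  expect_identical(ff$freqs$source_cohort, train)

  # permuting eval genotypes leaves reference artifacts bit-identical
  g2 <- g
  perm <- sample(41:60)
  g2$dosages[41:60, ] <- g$dosages[perm, ]
  ff2 <- fold_grm_features(g2, train, evalc)
  expect_identical(ff2$G_ref, ff$G_ref)
  expect_identical(ff2$freqs$p, ff$freqs$p)

  expect_error(fold_grm_features(g, train, c(train[1], evalc)),
               class = "gvitgp_leakage_error")
  # empty eval cohort: valid reference, empty vectors
  ff0 <- fold_grm_features(g, train)
  expect_equal(nrow(ff0$eval_vectors), 0L)
})

test_that("a third copy of a duplicated training individual has equal eval entries", {
  base <- c(0, 1, 2, 1, 0, 2, 1, 1)
  other <- c(2, 1, 0, 1, 2, 0, 1, 2)
  g <- tiny_genotypes(rbind(base, base, other, base))
  ff <- fold_grm_features(g, c("s01", "s02", "s03"), "s04")
  expect_equal(ff$eval_vectors[1, "s01"], ff$eval_vectors[1, "s02"])
})

test_that("GRM TSV round-trips", {
  ds <- small_sim(seed = 101)
  fr <- estimate_freqs(ds$genotypes, ds$genotypes$sample_ids[1:10])
  G <- compute_grm(ds$genotypes, fr)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_grm(G, f)
  G2 <- read_grm(f)
  expect_equal(G2, G, tolerance = 1e-12)
})
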