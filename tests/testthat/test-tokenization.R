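test_that("patch-plan arithmetic follows P = ceil(L/N_p) with tail padding", {
  p1 <- make_patch_plan(10000, 400)
  expect_equal(c(p1$P, p1$pad), c(25L, 0L))
  p2 <- make_patch_plan(10001, 400)
  expect_equal(c(p2$P, p2$pad), c(26L, 399L))
  p3 <- make_patch_plan(300, 400)
  expect_equal(c(p3$P, p3$pad), c(1L, 100L))
  expect_equal(sum(p3$patch_ranges$end < p3$patch_ranges$start), 100L)

  # ranges are disjoint, ordered, and cover 1..L
  for (plan in list(p1, p2, p3, make_patch_plan(7, 3))) {
    pr <- plan$patch_ranges
    covered <- unlist(lapply(seq_len(plan$N_p), function(i) {
      if (pr$end[i] >= pr$start[i]) pr$start[i]:pr$end[i] else integer(0)
    }))
    expect_identical(covered, seq_len(plan$L))
  }
  expect_error(make_patch_plan(0, 10), class = "gvitgp_contract_error")
})

fake_selection <- function(idx) {
  structure(list(strategy = "gbdt", selected = idx, scores = rep(1, length(idx)),
                 k = length(idx), trained_on = "s", seed = 1L),
            class = "selection_result")
}

test_that("spe_tokenize has the contracted shape, locality and zero behavior", {
  set.seed(2)
  B <- 4; L <- 10; N_p <- 4; D <- 6
  plan <- make_patch_plan(L, N_p)              # P = 3, pad = 2
  proj <- list(W = matrix(rnorm(plan$P * D), plan$P), b = rep(0, D))
  cls <- rnorm(D)
  X <- matrix(rnorm(B * L), B)
  tb <- spe_tokenize(X, fake_selection(1:L), plan, proj, cls)
  expect_equal(dim(tb$tokens), c(B, N_p + 1, D))
  expect_equal(tb$tokens[2, 1, ], cls)         # [CLS] prepended for every row

  # all-zero input with zero bias -> zero patch tokens, [CLS] untouched
  tb0 <- spe_tokenize(matrix(0, B, L), fake_selection(1:L), plan, proj, cls)
  expect_true(all(tb0$tokens[, -1, ] == 0))
  expect_equal(tb0$tokens[1, 1, ], cls)

  # permuting two markers inside one patch changes only that patch's token
  X2 <- X
  X2[, c(1, 2)] <- X[, c(2, 1)]                # both in patch 1
  tb2 <- spe_tokenize(X2, fake_selection(1:L), plan, proj, cls)
  expect_false(isTRUE(all.equal(tb$tokens[, 2, ], tb2$tokens[, 2, ])))
  expect_equal(tb$tokens[, 3:5, ], tb2$tokens[, 3:5, ])

  expect_error(spe_tokenize(X, fake_selection(1:4), plan, proj, cls),
               class = "gvitgp_contract_error")
})

test_that("padding is neutral: it only zero-fills the final patch's tail", {
  set.seed(3)
  B <- 2; L <- 7; N_p <- 3
  plan <- make_patch_plan(L, N_p)              # P = 3, pad = 2
  X <- matrix(rnorm(B * L), B)
  Xp <- gvitgp:::build_patch_tensor(X, plan)
  expect_equal(Xp[, 3, 2:3], matrix(0, B, 2))  # padded tail
  expect_equal(as.vector(Xp[1, 1, ]), X[1, 1:3])
  expect_equal(as.vector(Xp[1, 3, 1]), X[1, 7])
})

test_that("fpe equals spe when the selection is the full panel", {
  set.seed(4)
  B <- 3; L <- 12; N_p <- 4; D <- 5
  plan <- make_patch_plan(L, N_p)
  proj <- list(W = matrix(rnorm(plan$P * D), plan$P), b = rnorm(D))
  cls <- rnorm(D)
  X <- matrix(rnorm(B * L), B)
  expect_equal(fpe_tokenize(X, plan, proj, cls)$tokens,
               spe_tokenize(X, fake_selection(1:L), plan, proj, cls)$tokens)
})

test_that("sie tokens share the 1->D map; equal dosages give equal tokens", {
  set.seed(5)
  B <- 3; k <- 5; D <- 4
  proj <- list(w = rnorm(D), b = rnorm(D))
  cls <- rnorm(D)
  X <- matrix(rnorm(B * k), B)
  X[1, 2] <- X[1, 4]                            # equal dosages in one row
  tb <- sie_tokenize(X, fake_selection(1:k), proj, cls)
  expect_equal(dim(tb$tokens), c(B, k + 1, D))
  expect_equal(tb$tokens[1, 3, ], tb$tokens[1, 5, ])
  # k = 1 degenerate sequence accepted
  tb1 <- sie_tokenize(X[, 1, drop = FALSE], fake_selection(1), proj, cls)
  expect_equal(dim(tb1$tokens), c(B, 2, D))
})

test_that("dosage preprocessing uses training-fold statistics only", {
  ds <- small_sim(seed = 103)
  g <- ds$genotypes
  train <- g$sample_ids[1:40]
  stats <- dosage_stats(g, train, 1:20)
  Xtr <- prep_dosages(g, train, stats)
  expect_lt(max(abs(colMeans(Xtr))), 1e-10)     # centered on the training fold
  # held-out rows transformed with the same statistics (not re-estimated)
  Xev <- prep_dosages(g, g$sample_ids[41:50], stats)
  expect_equal(ncol(Xev), 20L)
  expect_false(isTRUE(all.equal(max(abs(colMeans(Xev))), 0)))
})

test_that("every marker lands in exactly one patch", {
  plan <- make_patch_plan(11, 4)
  pm <- patch_of_marker(plan, seq_len(11))
  expect_equal(length(pm), 11L)
  expect_true(all(table(pm) <= plan$P))
  expect_equal(sort(unique(pm)), 1:4)           # pad shortens only the last patch
})
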