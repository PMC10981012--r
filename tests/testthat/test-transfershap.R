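test_that("TransferSHAP equals the double-loop oracle and its identities", {
  set.seed(61)
  src <- matrix(rnorm(15), 5, 3)
  tgt <- matrix(rnorm(15), 5, 3)
  res <- transfershap(fake_phi(src), fake_phi(tgt))
  expect_equal(unname(res$importance), oracle_transfershap(src, tgt))
  expect_true(all(res$normalized_importance >= 0 & res$normalized_importance <= 1))
  expect_equal(min(res$normalized_importance), 0)
  expect_equal(max(res$normalized_importance), 1)

  # identity input -> zero vector (an unchanged feature is unimportant to
  # the transfer, however important it is to both models)
  expect_warning(zero <- transfershap(fake_phi(src), fake_phi(src)), "constant")
  expect_equal(unname(zero$importance), rep(0, 3))
  expect_equal(unname(zero$normalized_importance), rep(0, 3))

  # single cell: |0.5 - 0.2| (length-1 vector is constant, hence the warning)
  expect_warning(
    one <- transfershap(fake_phi(matrix(0.2, 1, 1)), fake_phi(matrix(0.5, 1, 1))),
    "constant")
  expect_equal(unname(one$importance), 0.3)

  # |delta| symmetry and linear scaling
  ab <- transfershap(fake_phi(src), fake_phi(tgt))
  ba <- transfershap(fake_phi(tgt), fake_phi(src))
  expect_equal(ab$importance, ba$importance)
  sc <- transfershap(fake_phi(3 * src), fake_phi(3 * tgt))
  expect_equal(unname(sc$importance), unname(3 * ab$importance))
  # observation order invariance
  perm <- sample(5)
  pp <- transfershap(fake_phi(src[perm, , drop = FALSE], ids = sprintf("o%02d", perm)),
                     fake_phi(tgt[perm, , drop = FALSE], ids = sprintf("o%02d", perm)))
  expect_equal(pp$importance, ab$importance)

  expect_error(transfershap(fake_phi(src), fake_phi(tgt, ids = sprintf("x%02d", 1:5))),
               "misaligned")
})

test_that("exact Shapley values satisfy the dummy axiom and the additive closed form", {
  set.seed(62)
  X <- matrix(rnorm(12), 4, 3)
  bg <- matrix(rnorm(30), 10, 3)
  # additive model: phi_j = x_j - mean(bg_j); feature 3 is a dummy
  f <- function(M) M[, 1] + 2 * M[, 2]
  phi <- mirtransfer:::shapley_exact(f, X, bg)
  expect_equal(phi[, 1], X[, 1] - mean(bg[, 1]))
  expect_equal(phi[, 2], 2 * (X[, 2] - mean(bg[, 2])))
  expect_equal(phi[, 3], rep(0, 4))
})

test_that("exact Shapley on fitted models satisfies local accuracy", {
  w <- two_species_tables(n = 400L, n_features = 6L, seed = 63L)
  eval_tab <- feature_table(as.data.frame(w$tables$tgt)[1:12, ])
  for (fam in c("xgb", "ann")) {
    model <- if (fam == "xgb") train_xgb(w$tables$src, nrounds = 25L)
      else train_ann(w$tables$src, fast_ann_cfg())
    phi <- shapley_matrix(model, "source", eval_tab, method = "exact_small")
    pred <- predict(model, eval_tab, phase = "source")
    expect_equal(rowSums(phi$values) + phi$base_values, pred, tolerance = 1e-6)
  }
  big <- toy_feature_table(n = 20L, m = 14L)
  m14 <- train_xgb(big, nrounds = 5L)
  expect_error(shapley_matrix(m14, "source", big, method = "exact_small"),
               "at most 12")
})

test_that("sampling Shapley approximates the exact values", {
  w <- two_species_tables(n = 300L, n_features = 6L, seed = 64L)
  model <- train_ann(w$tables$src, fast_ann_cfg())
  eval_tab <- feature_table(as.data.frame(w$tables$tgt)[1:3, ])
  exact <- shapley_matrix(model, "source", eval_tab, method = "exact_small")
  approx <- shapley_matrix(model, "source", eval_tab, method = "sampling",
                           n_samples = 2000L, seed = 3L)
  expect_lt(max(abs(exact$values - approx$values)), 0.05)
})

test_that("TreeSHAP matrices align with the evaluation table and the sign convention", {
  w <- two_species_tables(n = 400L, seed = 65L)
  model <- train_xgb(w$tables$src, nrounds = 30L)
  eval_tab <- feature_table(as.data.frame(w$tables$tgt)[1:20, ])
  phi <- shapley_matrix(model, "source", eval_tab, method = "tree_exact")
  expect_equal(dim(phi$values), c(20L, length(feature_names(eval_tab))))
  expect_identical(phi$observation_ids, eval_tab$interaction_id)
  # local accuracy on the margin scale
  marg <- log(predict(model, eval_tab) / (1 - predict(model, eval_tab)))
  expect_equal(rowSums(phi$values) + phi$base_values, marg, tolerance = 1e-4)
})

test_that("pair comparison reproduces a rank-then-Pearson oracle", {
  set.seed(66)
  vs <- replicate(4, runif(12), simplify = FALSE)
  results <- lapply(seq_along(vs), function(i) {
    v <- vs[[i]]
    structure(list(importance = stats::setNames(v, paste0("f", 1:12)),
                   normalized_importance = stats::setNames(
                     (v - min(v)) / (max(v) - min(v)), paste0("f", 1:12)),
                   pair = c(paste0("s", i), paste0("t", i)), family = "xgb"),
              class = "transfershap_result")
  })
  cp <- compare_pairs(results)
  expect_equal(dim(cp$rho), c(4L, 4L))
  expect_equal(diag(cp$rho), rep(1, 4), ignore_attr = TRUE)
  # independent oracle: rank then Pearson
  for (i in 1:4) for (j in 1:4) {
    expect_equal(cp$rho[i, j],
                 stats::cor(rank(results[[i]]$normalized_importance),
                            rank(results[[j]]$normalized_importance)),
                 tolerance = 1e-12)
  }
  # monotone transforms have correlation 1
  r2 <- results
  r2[[2]]$normalized_importance <- results[[1]]$normalized_importance^3
  cp2 <- compare_pairs(r2[1:2])
  expect_equal(cp2$rho[1, 2], 1)
  expect_error(compare_pairs(results[1]), "length")
})

test_that("transfershap_for_model isolates the transfer step", {
  w <- two_species_tables(n = 500L, seed = 67L)
  model <- train_xgb(w$tables$src, nrounds = 30L)
  chunk <- feature_table(as.data.frame(w$tables$tgt)[1:100, ])
  tm <- transfer_xgb(model, chunk, n_new_trees = 10L)
  eval_tab <- feature_table(as.data.frame(w$tables$tgt)[101:140, ])
  res <- transfershap_for_model(tm, eval_tab, method = "tree_exact")
  expect_s3_class(res, "transfershap_result")
  expect_true(all(res$importance >= 0))
  # a model with no transfer state explains to a zero vector
  expect_warning(res0 <- transfershap_for_model(model, eval_tab,
                                                method = "tree_exact"),
                 "constant")
  expect_equal(unname(res0$importance), rep(0, length(res0$importance)))
  path <- tempfile(fileext = ".tsv")
  write_transfershap(res, path)
  back <- read.delim(path)
  expect_equal(nrow(back), length(res$importance))
})
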