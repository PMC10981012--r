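test_that("the ANN fits a linearly separable toy problem", {
  tab <- separable_table(n = 400L, seed = 1L)
  model <- train_ann(tab, fast_ann_cfg())
  p <- predict(model, tab)
  expect_true(all(p >= 0 & p <= 1))
  expect_gte(compute_metrics(table_labels(tab), p)$ACC, 0.95)
})

test_that("ANN training rejects degenerate inputs", {
  tab <- separable_table(n = 100L)
  d <- as.data.frame(tab)
  d$label <- 1L
  expect_error(train_ann(feature_table(d), fast_ann_cfg()), "all labels identical")
  val <- toy_feature_table(n = 20L, m = 5L)
  expect_error(train_ann(tab, fast_ann_cfg(), val), "schema")
})

test_that("ANN transfer freezes the requested layers bitwise", {
  w <- two_species_tables(n = 600L, seed = 2L)
  cfg <- fast_ann_cfg()
  model <- train_ann(w$tables$src, cfg)
  chunk <- feature_table(as.data.frame(w$tables$tgt)[1:100, ])
  tm <- transfer_ann(model, chunk)
  # default freeze: all dense layers except the last two (here: layer 1)
  expect_identical(tm$transfer_state$W[[1]], model$source_state$W[[1]])
  expect_identical(tm$transfer_state$b[[1]], model$source_state$b[[1]])
  expect_false(identical(tm$transfer_state$W[[2]], model$source_state$W[[2]]))
  # the source phase is retained untouched
  expect_identical(tm$source_state, model$source_state)
  # all-frozen transfer is rejected
  cfg_all <- cfg
  cfg_all$frozen_layers <- 1:3
  expect_error(transfer_ann(model, chunk, cfg_all), "all layers are frozen")
})

test_that("zero target observations reproduce source predictions exactly (ANN)", {
  w <- two_species_tables(n = 400L, seed = 3L)
  model <- train_ann(w$tables$src, fast_ann_cfg())
  empty <- feature_table(as.data.frame(w$tables$tgt)[0, ])
  tm <- transfer_ann(model, empty)
  expect_null(tm$transfer_state)
  test <- w$tables$tgt
  expect_identical(predict(tm, test), predict(model, test))
})

test_that("XGB fits XOR and a monotone single-feature rule", {
  xt <- xor_table(n = 400L, seed = 4L)
  m <- train_xgb(xt, params = list(max_depth = 3L), nrounds = 80L)
  expect_gte(compute_metrics(table_labels(xt), predict(m, xt))$ACC, 0.95)

  set.seed(5)
  n <- 600L
  x <- rnorm(n)
  mono <- feature_table(cbind(
    data.frame(interaction_id = sprintf("m%03d", 1:n), source = "mono",
               mirna_id = paste0("g", rep(1:30, each = 20)),
               label = as.integer(x > 0), stringsAsFactors = FALSE),
    data.frame(f1 = x)))
  sp <- stratified_split(mono, split_spec(n_repeats = 1L, rng_seed = 1L))[[1]]
  fit <- train_xgb(feature_table(as.data.frame(mono)[
    match(sp$train_ids, mono$interaction_id), ]), nrounds = 50L)
  test <- feature_table(as.data.frame(mono)[match(sp$test_ids, mono$interaction_id), ])
  p <- predict(fit, test)
  expect_true(all(p >= 0 & p <= 1))
  expect_gte(compute_metrics(table_labels(test), p)$ACC, 0.95)
})

test_that("XGB boosting continuation preserves the tree prefix verbatim", {
  w <- two_species_tables(n = 600L, seed = 6L)
  model <- train_xgb(w$tables$src, nrounds = 40L)
  chunk <- feature_table(as.data.frame(w$tables$tgt)[1:120, ])
  tm <- transfer_xgb(model, chunk, n_new_trees = 15L)
  n_src <- xgboost::xgb.get.num.boosted.rounds(model$source_state)
  n_tr <- xgboost::xgb.get.num.boosted.rounds(tm$transfer_state)
  expect_equal(n_tr, n_src + 15L)
  dump_src <- xgboost::xgb.dump(model$source_state)
  dump_tr <- xgboost::xgb.dump(tm$transfer_state)
  expect_identical(dump_tr[seq_along(dump_src)], dump_src)
  # continuation actually changes target predictions
  expect_gt(max(abs(predict(tm, w$tables$tgt) - predict(model, w$tables$tgt))), 0)

  # zero new trees -> identity
  tm0 <- transfer_xgb(model, chunk, n_new_trees = 0L)
  expect_identical(predict(tm0, w$tables$tgt), predict(model, w$tables$tgt))
  expect_error(transfer_xgb(model, chunk[0, ], n_new_trees = 5L), "empty")
})

test_that("grid search is exhaustive with a deterministic first-max tie-break", {
  tab <- separable_table(n = 200L, seed = 7L)
  val <- separable_table(n = 100L, seed = 8L)
  # 1-point grid returns that point
  g1 <- grid_search("xgb", tab, val, list(max_depth = 3L, nrounds = 20L))
  expect_equal(g1$best_params$max_depth, 3L)
  expect_equal(g1$n_fits, 1L)
  # 2x2 grid -> exactly 4 fits, counted through the hook
  n_calls <- 0L
  g4 <- grid_search("xgb", tab, val,
                    list(max_depth = c(2L, 4L), eta = c(0.1, 0.3)),
                    fit_hook = function(p) n_calls <<- n_calls + 1L)
  expect_equal(n_calls, 4L)
  expect_equal(nrow(g4$results), 4L)
  # the selected point attains the maximum validation accuracy
  expect_equal(g4$results$validation_accuracy[
    g4$results$max_depth == g4$best_params$max_depth &
    g4$results$eta == g4$best_params$eta],
    max(g4$results$validation_accuracy))
  expect_error(grid_search("xgb", tab, val, list()), "grid")
})

test_that("transfer on delta=0 species neither helps nor hurts beyond noise", {
  diffs <- c()
  for (sd in 1:6) {
    w <- two_species_tables(n = 600L, delta = 0, seed = 40L + sd)
    src_split <- stratified_split(w$tables$src, split_spec(rng_seed = sd))[[1]]
    tgt_split <- stratified_split(w$tables$tgt, split_spec(rng_seed = sd))[[1]]
    d_src <- as.data.frame(w$tables$src)
    d_tgt <- as.data.frame(w$tables$tgt)
    model <- train_xgb(feature_table(d_src[match(src_split$train_ids,
                                                 d_src$interaction_id), ]),
                       nrounds = 40L)
    chunk <- feature_table(d_tgt[match(tgt_split$train_ids[1:100],
                                       d_tgt$interaction_id), ])
    tm <- transfer_xgb(model, chunk, n_new_trees = 20L)
    test <- feature_table(d_tgt[match(tgt_split$test_ids, d_tgt$interaction_id), ])
    labs <- table_labels(test)
    diffs <- c(diffs, compute_metrics(labs, predict(tm, test))$ACC -
                 compute_metrics(labs, predict(model, test))$ACC)
  }
  expect_gt(stats::t.test(diffs)$p.value, 0.05)
})
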