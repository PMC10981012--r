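# TransferSHAP: per-feature importance of the transfer step. Shapley-value
# matrices (observations x features) are computed for the source-phase and
# transfer-phase models on the same evaluation observations; the column-wise
# sum of the absolute element-wise difference between the two matrices is the
# importance of each feature *to the transfer* — a feature important in both
# models but unchanged by fine-tuning scores zero.

#' Shapley value matrix of a transfer model phase
#'
#' Three estimators:
#' * `exact_small` — exact enumeration of all feature coalitions (2^m), with
#'   the coalition value defined as the mean model output over the background
#'   rows with the coalition's features set to the explained observation.
#'   Limited to at most 12 features. Satisfies local accuracy: row sums of
#'   phi plus the base value reproduce the model output.
#' * `sampling` — unbiased Monte-Carlo permutation estimator; draw count and
#'   seed are recorded in the attributes.
#' * `tree_exact` — the path-dependent TreeSHAP algorithm of xgboost
#'   (`predcontrib`), available for the xgb family; contributions are on the
#'   log-odds (margin) scale.
#'
#' The sign convention is fixed to the positive class: positive phi values
#' push the prediction towards a functional interaction.
#'
#' @param model a `transfer_model`.
#' @param which `"source"` or `"target"` phase. With no transfer state the
#'   target phase equals the source phase.
#' @param eval_table `feature_table` of observations to explain.
#' @param method `"auto"` picks `tree_exact` for xgb, `exact_small` for at
#'   most 12 features, else `sampling`.
#' @param background matrix of background rows (reference distribution);
#'   defaults to the background sample stored in the model (source training
#'   sample for the source phase, chunk-augmented for the target phase);
#'   pass the same matrix to both phases for a shared-background analysis.
#' @param n_samples permutations for `sampling`.
#' @param seed RNG seed for `sampling`.
#' @return A `shapley_matrix` object: list with `values` (observations x
#'   features), `base_values`, `observation_ids`, `feature_names`, `method`.
#' @export
shapley_matrix <- function(model, which = c("source", "target"), eval_table,
                           method = c("auto", "exact_small", "sampling", "tree_exact"),
                           background = NULL, n_samples = 200L, seed = 1L) {
  which <- match.arg(which)
  method <- match.arg(method)
  stopifnot(inherits(model, "transfer_model"))
  check_schema(model, eval_table)
  X <- feature_matrix(eval_table)
  m <- ncol(X)
  if (method == "auto") {
    method <- if (model$family == "xgb") "tree_exact"
      else if (m <= 12L) "exact_small" else "sampling"
  }
  state <- if (which == "source") model$source_state
    else model$transfer_state %||% model$source_state
  if (method == "tree_exact") {
    if (model$family != "xgb") stopf("tree_exact requires the xgb family")
    contrib <- predict(state, xgboost::xgb.DMatrix(X, nthread = 1L),
                       predcontrib = TRUE)
    phi <- contrib[, model$feature_names, drop = FALSE]
    base <- contrib[, ncol(contrib)] # bias/intercept column is last
    return(new_shapley(phi, base, eval_table$interaction_id,
                       model$feature_names, "tree_exact", model))
  }
  f <- function(M) { # raw-feature matrix -> model output for the phase
    if (model$family == "ann") ann_predict(state, model_scale(model, M))
    else as.numeric(predict(state, xgboost::xgb.DMatrix(M, nthread = 1L)))
  }
  bg <- background %||% model$background
  bg <- as.matrix(bg)[, model$feature_names, drop = FALSE]
  if (method == "exact_small") {
    if (m > 12L) {
      stopf("exact_small supports at most 12 features (got %d); use method='sampling'", m)
    }
    phi <- shapley_exact(f, X, bg)
    base <- rep(mean(f(bg)), nrow(X))
    return(new_shapley(phi, base, eval_table$interaction_id,
                       model$feature_names, "exact_small", model))
  }
  res <- shapley_sampling(f, X, bg, n_samples, seed)
  out <- new_shapley(res$phi, res$base, eval_table$interaction_id,
                     model$feature_names, "sampling", model)
  attr(out, "n_samples") <- n_samples
  attr(out, "seed") <- seed
  out
}

new_shapley <- function(values, base, ids, features, method, model) {
  dimnames(values) <- list(NULL, features)
  structure(list(values = values, base_values = as.numeric(base),
                 observation_ids = as.character(ids), feature_names = features,
                 method = method, family = model$family),
            class = "shapley_matrix")
}

# Exact Shapley values by coalition enumeration. v(S) for observation x is
# the mean of f over background rows with columns in S replaced by x.
shapley_exact <- function(f, X, bg) {
  m <- ncol(X)
  n <- nrow(X)
  nbg <- nrow(bg)
  n_sub <- 2L^m
  v <- matrix(0, n, n_sub)
  for (s in 0:(n_sub - 1L)) {
    members <- which(bitwAnd(s, bitwShiftL(1L, 0:(m - 1L))) != 0L)
    big <- bg[rep(seq_len(nbg), times = n), , drop = FALSE]
    if (length(members)) {
      xrep <- X[rep(seq_len(n), each = nbg), members, drop = FALSE]
      big[, members] <- xrep
    }
    pred <- f(big)
    v[, s + 1L] <- colMeans(matrix(pred, nbg, n))
  }
  fact <- factorial(0:m)
  phi <- matrix(0, n, m)
  for (s in 0:(n_sub - 1L)) {
    members <- which(bitwAnd(s, bitwShiftL(1L, 0:(m - 1L))) != 0L)
    k <- length(members)
    w <- fact[k + 1L] * fact[m - k] / fact[m + 1L] # |S|! (m-|S|-1)! / m!
    for (j in setdiff(seq_len(m), members)) {
      s_with <- s + bitwShiftL(1L, j - 1L)
      phi[, j] <- phi[, j] + w * (v[, s_with + 1L] - v[, s + 1L])
    }
  }
  phi
}

# Unbiased permutation-sampling estimator of Shapley values.
shapley_sampling <- function(f, X, bg, n_samples, seed) {
  m <- ncol(X)
  n <- nrow(X)
  with_local_seed(seed, {
    phi <- matrix(0, n, m)
    base_acc <- numeric(n)
    for (p in seq_len(n_samples)) {
      perm <- sample.int(m)
      b <- bg[sample.int(nrow(bg), n, replace = TRUE), , drop = FALSE]
      cur <- b
      v_prev <- f(cur)
      base_acc <- base_acc + v_prev
      for (j in perm) {
        cur[, j] <- X[, j]
        v_new <- f(cur)
        phi[, j] <- phi[, j] + (v_new - v_prev)
        v_prev <- v_new
      }
    }
    list(phi = phi / n_samples, base = base_acc / n_samples)
  })
}

#' TransferSHAP importance of a <source, target> model pair
#'
#' Subtracts the source-phase Shapley matrix from the target-phase matrix
#' element-wise, takes absolute values, and sums each feature column:
#' `importance_f = sum_i |target_phi[i, f] - source_phi[i, f]|`. The vector
#' is also MinMax-normalized to `[0, 1]`; a constant importance vector
#' normalizes to all zeros with a warning.
#'
#' @param source_phi,target_phi `shapley_matrix` objects computed on the same
#'   observations and features.
#' @param pair optional `c(source_species, target_species)` label.
#' @return A `transfershap_result`: list with `importance`,
#'   `normalized_importance`, `pair`, `family`.
#' @export
transfershap <- function(source_phi, target_phi, pair = NULL) {
  stopifnot(inherits(source_phi, "shapley_matrix"),
            inherits(target_phi, "shapley_matrix"))
  if (!identical(source_phi$observation_ids, target_phi$observation_ids)) {
    bad <- union(setdiff(source_phi$observation_ids, target_phi$observation_ids),
                 setdiff(target_phi$observation_ids, source_phi$observation_ids))
    stopf("observation ids are misaligned (e.g. %s)",
          paste(head(bad, 3), collapse = ", "))
  }
  if (!identical(source_phi$feature_names, target_phi$feature_names)) {
    stopf("feature names are misaligned")
  }
  imp <- colSums(abs(target_phi$values - source_phi$values))
  names(imp) <- source_phi$feature_names
  rng <- range(imp)
  if (rng[2] - rng[1] < .Machine$double.eps) {
    warning("constant importance vector; normalized importance set to 0",
            call. = FALSE)
    norm <- imp * 0
  } else {
    norm <- (imp - rng[1]) / (rng[2] - rng[1])
  }
  structure(list(importance = imp, normalized_importance = norm,
                 pair = pair %||% c(NA_character_, NA_character_),
                 family = source_phi$family),
            class = "transfershap_result")
}

#' TransferSHAP for a fitted transfer model
#'
#' Convenience wrapper: computes the Shapley matrices of both phases of
#' `model` on `eval_table` and applies [transfershap()]. By default each
#' phase uses its own stored background ("per_model"); `"shared"` uses the
#' source background for both.
#'
#' @inheritParams shapley_matrix
#' @param background_mode `"per_model"` or `"shared"`.
#' @export
transfershap_for_model <- function(model, eval_table, method = "auto",
                                   background_mode = c("per_model", "shared"),
                                   n_samples = 200L, seed = 1L) {
  background_mode <- match.arg(background_mode)
  bg_src <- model$background
  bg_tgt <- if (background_mode == "shared") bg_src else NULL
  src <- shapley_matrix(model, "source", eval_table, method,
                        background = bg_src, n_samples = n_samples, seed = seed)
  tgt <- shapley_matrix(model, "target", eval_table, method,
                        background = bg_tgt, n_samples = n_samples, seed = seed)
  transfershap(src, tgt, pair = c(model$provenance$source_species,
                                  model$provenance$target_species))
}

#' Compare TransferSHAP vectors across <source, target> pairs
#'
#' Spearman correlation (average ranks for ties) between the normalized
#' importance vectors of all pairs, and average-linkage hierarchical
#' clustering on the distance `1 - rho`. A constant vector yields missing
#' correlations (with a warning from [stats::cor()]).
#'
#' @param results list of `transfershap_result`s over a common feature set.
#' @return List with `rho` (symmetric correlation matrix labelled
#'   `"source->target"`), `hclust`, `dendrogram_order`, `labels`.
#' @export
compare_pairs <- function(results) {
  stopifnot(length(results) >= 2L)
  fn <- names(results[[1]]$importance)
  for (r in results) {
    if (!identical(names(r$importance), fn)) stopf("feature sets differ across results")
  }
  V <- vapply(results, function(r) r$normalized_importance, numeric(length(fn)))
  labels <- vapply(results, function(r) paste0(r$pair[1], "->", r$pair[2]),
                   character(1))
  colnames(V) <- labels
  rho <- suppressWarnings(cor(V, method = "spearman"))
  d <- as.dist(1 - rho)
  hc <- hclust(d, method = "average")
  list(rho = rho, hclust = hc, dendrogram_order = hc$order, labels = labels)
}

#' Planted-structure recovery experiment
#'
#' Generates feature-mode data for at least three synthetic species with
#' known shifted feature subsets, trains and fine-tunes a model for every
#' ordered <source, target> pair, applies TransferSHAP, and reports (a) the
#' top-k recall of each target species' true shifted subset in the pair's
#' importance vector and (b) whether cutting the dendrogram at the number of
#' species recovers the same-target partition (adjusted Rand index).
#'
#' @param rule a [ground_truth_rule()] with nonzero per-species shifts.
#' @param specs list of at least three [species_spec()]s.
#' @param family `"xgb"` or `"ann"`.
#' @param n_per_species rows per species table.
#' @param spec a [split_spec()] (repeat 0 is used).
#' @param chunk_total target observations used for fine-tuning.
#' @param n_transfer_repeats independent chunk draws (and transfer fits) per
#'   pair; the pair's importance vector is the mean over repeats, which
#'   averages out chunk-sampling noise without coupling different pairs.
#' @param n_eval evaluation observations per pair for the Shapley matrices.
#' @param model_args as in [run_transfer_curve()].
#' @param n_samples,seed sampling-estimator settings (ANN family).
#' @return List with `results` (per-pair `transfershap_result`s),
#'   `comparison` (from [compare_pairs()]), `ari`, `recall` (per pair),
#'   `mean_recall`, `pair_targets`.
#' @export
recovery_experiment <- function(rule, specs, family = c("xgb", "ann"),
                                n_per_species = 3000L, spec = split_spec(),
                                chunk_total = 500L, n_transfer_repeats = 3L,
                                n_eval = 100L,
                                model_args = list(), n_samples = 30L, seed = 1L) {
  family <- match.arg(family)
  stopifnot(length(specs) >= 3L)
  tables <- simulate_feature_tables(rule, specs, n_per_species)
  species <- names(tables)
  splits <- lapply(tables, function(t) stratified_split(t, spec)[[1]])
  models <- lapply(species, function(s) {
    fit_family(family, ft_by_ids(tables[[s]], splits[[s]]$train_ids),
               ft_by_ids(tables[[s]], splits[[s]]$validation_ids), model_args)
  })
  names(models) <- species
  pairs <- expand.grid(source = species, target = species,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, , drop = FALSE]
  # one fixed evaluation subset per *target* species (every model with that
  # target is explained on the same target test observations); chunk draws
  # are independent per pair
  eval_of <- lapply(species, function(tgt) {
    test_ids <- splits[[tgt]]$test_ids
    ids <- with_local_seed(child_seed(seed, 1000L + match(tgt, species)),
                           sample(test_ids, min(n_eval, length(test_ids))))
    ft_by_ids(tables[[tgt]], ids)
  })
  names(eval_of) <- species
  results <- vector("list", nrow(pairs))
  recall <- numeric(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    src <- pairs$source[i]; tgt <- pairs$target[i]
    tgt_train <- ft_by_ids(tables[[tgt]], splits[[tgt]]$train_ids)
    eval_tab <- eval_of[[tgt]]
    rep_imps <- vector("list", n_transfer_repeats)
    for (r in seq_len(n_transfer_repeats)) {
      chunk_ids <- sample_chunks(tgt_train, chunk_size = chunk_total,
                                 max_total = chunk_total,
                                 seed = child_seed(seed, 100L * i + r))[[1]]
      chunk <- ft_by_ids(tables[[tgt]], chunk_ids)
      attr(chunk, "species") <- tgt
      model <- models[[src]]
      model$provenance$source_species <- src
      model <- if (family == "xgb") {
        transfer_xgb(model, chunk, n_new_trees = model_args$n_new_trees %||% 50L)
      } else {
        transfer_ann(model, chunk, model_args$transfer_cfg)
      }
      model$provenance$target_species <- tgt
      rep_imps[[r]] <- transfershap_for_model(
        model, eval_tab,
        method = if (family == "xgb") "tree_exact" else "sampling",
        n_samples = n_samples,
        seed = child_seed(seed, 2000L + 100L * i + r))
    }
    imp <- Reduce(`+`, lapply(rep_imps, `[[`, "importance")) / n_transfer_repeats
    rng <- range(imp)
    norm <- if (rng[2] - rng[1] < .Machine$double.eps) imp * 0
      else (imp - rng[1]) / (rng[2] - rng[1])
    ts <- structure(list(importance = imp, normalized_importance = norm,
                         pair = c(src, tgt), family = family),
                    class = "transfershap_result")
    results[[i]] <- ts
    s_true <- shifted_features(rule, tgt)
    recall[i] <- if (!length(s_true)) NA_real_ else {
      top <- names(sort(ts$importance, decreasing = TRUE))[seq_along(s_true)]
      length(intersect(top, s_true)) / length(s_true)
    }
  }
  comparison <- compare_pairs(results)
  clusters <- cutree(comparison$hclust, k = length(species))
  ari <- mclust::adjustedRandIndex(clusters, factor(pairs$target))
  list(results = results, comparison = comparison, ari = ari,
       recall = stats::setNames(recall, comparison$labels),
       mean_recall = mean(recall), pair_targets = pairs$target)
}

#' Write a TransferSHAP importance vector as TSV
#'
#' @param result a `transfershap_result`.
#' @param path output file.
#' @export
write_transfershap <- function(result, path) {
  df <- data.frame(feature = names(result$importance),
                   raw = as.numeric(result$importance),
                   normalized = as.numeric(result$normalized_importance))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
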