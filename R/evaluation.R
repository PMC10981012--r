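# Metrics and experiment harnesses. Three experiment designs:
#   intra    — train and test on 80/20 splits of one species;
#   cross    — train on the source species' training split, test on the
#              target species' test split;
#   transfer — pre-train on the source, fine-tune on growing chunks of the
#              target training split, always evaluating on the fixed target
#              test split.

#' Confusion counts at a threshold
#'
#' @param labels 0/1 vector.
#' @param scores probabilities in `[0, 1]`.
#' @param threshold binarization threshold (scores `>= threshold` are called
#'   positive).
#' @return List with `TP`, `TN`, `FP`, `FN`, `threshold`.
#' @export
confusion_counts <- function(labels, scores, threshold = 0.5) {
  stopifnot(length(labels) == length(scores), length(labels) >= 1L,
            all(labels %in% c(0L, 1L)), all(scores >= 0 & scores <= 1))
  pred <- as.integer(scores >= threshold)
  list(TP = sum(pred == 1L & labels == 1L), TN = sum(pred == 0L & labels == 0L),
       FP = sum(pred == 1L & labels == 0L), FN = sum(pred == 0L & labels == 1L),
       threshold = threshold)
}

metrics_from_confusion <- function(cc) {
  TP <- cc$TP; TN <- cc$TN; FP <- cc$FP; FN <- cc$FN
  total <- TP + TN + FP + FN
  acc <- (TP + TN) / total
  f1 <- if (TP + 0.5 * (FP + FN) == 0) 0 else TP / (TP + 0.5 * (FP + FN))
  denom <- as.numeric(TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  mcc <- if (denom == 0) 0 else ((TP * TN) - (FP * FN)) / sqrt(denom)
  list(ACC = acc, F1 = f1, MCC = mcc)
}

auc_rank <- function(labels, scores) {
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    warning("AUC undefined for single-class labels; reporting NA", call. = FALSE)
    return(NA_real_)
  }
  r <- rank(scores) # average ranks => ties count 1/2
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Binary classification metrics: ACC, AUC, F1, MCC
#'
#' ACC = (TP+TN)/total; F1 = TP / (TP + 0.5 (FP+FN)); MCC = (TP*TN - FP*FN)
#' over the root of the product of the four marginal sums, with the
#' convention MCC = 0 when any factor of the denominator is 0; AUC is the
#' Mann-Whitney rank statistic (the probability that a positive outranks a
#' negative, ties counted one half), which makes it invariant under strictly
#' monotone transforms of the scores.
#'
#' @inheritParams confusion_counts
#' @return List with `ACC`, `AUC`, `F1`, `MCC` and attribute `confusion`.
#' @export
compute_metrics <- function(labels, scores, threshold = 0.5) {
  cc <- confusion_counts(labels, scores, threshold)
  m <- metrics_from_confusion(cc)
  out <- list(ACC = m$ACC, AUC = auc_rank(labels, scores), F1 = m$F1, MCC = m$MCC)
  attr(out, "confusion") <- cc
  out
}

result_row <- function(kind, source, target, config_name, chunk_size, repeat_index,
                       metrics, threshold = 0.5) {
  data.frame(experiment_kind = kind, source_species = source,
             target_species = target, config_name = config_name,
             chunk_size = chunk_size, repeat_index = repeat_index,
             ACC = metrics$ACC, AUC = metrics$AUC, F1 = metrics$F1,
             MCC = metrics$MCC, threshold = threshold,
             stringsAsFactors = FALSE)
}

fit_family <- function(family, train, validation, model_args) {
  if (family == "ann") {
    cfg <- model_args$cfg %||% ann_config()
    train_ann(train, cfg, validation)
  } else {
    train_xgb(train, params = model_args$params %||% list(),
              validation = validation,
              nrounds = model_args$nrounds %||% 200L)
  }
}

species_of <- function(table) attr(table, "species") %||% "dataset"

# Guard: no test id may enter any training-phase table.
assert_isolation <- function(test_ids, ...) {
  used <- unlist(list(...))
  leak <- intersect(test_ids, used)
  if (length(leak)) stopf("test-set leakage: %d test id(s) used in training",
                          length(leak))
  invisible(TRUE)
}

#' Intra-species experiment
#'
#' Trains and tests within one species over the ten stratified 80/10/20
#' splits and reports per-repeat metrics; aggregate by averaging over
#' repeats.
#'
#' @param table species `feature_table`.
#' @param spec a [split_spec()].
#' @param family `"ann"` or `"xgb"`.
#' @param model_args list of family arguments: `cfg` ([ann_config()]) for
#'   ANN; `params`, `nrounds` for XGB.
#' @return data.frame of experiment results, one row per repeat.
#' @export
run_intra <- function(table, spec = split_spec(), family = c("xgb", "ann"),
                      model_args = list()) {
  family <- match.arg(family)
  sp <- species_of(table)
  splits <- stratified_split(table, spec)
  do.call(rbind, lapply(splits, function(s) {
    assert_isolation(s$test_ids, s$train_ids, s$validation_ids)
    model <- fit_family(family, ft_by_ids(table, s$train_ids),
                        ft_by_ids(table, s$validation_ids), model_args)
    test <- ft_by_ids(table, s$test_ids)
    m <- compute_metrics(table_labels(test), predict(model, test))
    result_row("intra", sp, sp, paste0(family, "_intra"), 0L, s$repeat_index, m)
  }))
}

#' Cross-species experiment
#'
#' Trains on the source species' training split and tests on the target
#' species' test split, over the ten repeats; no target training row is ever
#' touched.
#'
#' @param source_table,target_table `feature_table`s with identical schemas.
#' @inheritParams run_intra
#' @export
run_cross <- function(source_table, target_table, spec = split_spec(),
                      family = c("xgb", "ann"), model_args = list()) {
  family <- match.arg(family)
  if (!identical(feature_names(source_table), feature_names(target_table))) {
    stopf("source and target schemas differ")
  }
  s_splits <- stratified_split(source_table, spec)
  t_splits <- stratified_split(target_table, spec)
  do.call(rbind, lapply(seq_along(s_splits), function(i) {
    ss <- s_splits[[i]]; ts <- t_splits[[i]]
    assert_isolation(ts$test_ids, ss$train_ids, ss$validation_ids)
    model <- fit_family(family, ft_by_ids(source_table, ss$train_ids),
                        ft_by_ids(source_table, ss$validation_ids), model_args)
    test <- ft_by_ids(target_table, ts$test_ids)
    m <- compute_metrics(table_labels(test), predict(model, test))
    result_row("cross", species_of(source_table), species_of(target_table),
               paste0(family, "_cross"), 0L, ss$repeat_index, m)
  }))
}

TRANSFER_CONFIGS <- c("ann_transfer", "ann_mix_no_transfer", "ann_target_only",
                      "ann_baseline_full", "xgb_transfer", "xgb_baseline_full")

#' Cross-species transfer-curve experiment
#'
#' For each requested configuration and cumulative chunk size (0, 100, ...,
#' 500 target observations) fits a model per the configuration's recipe and
#' evaluates it on the fixed target test split:
#' * `ann_transfer` / `xgb_transfer` — source model fine-tuned on the chunk
#'   (layer freezing / boosting continuation); at chunk 0 the source model
#'   itself is evaluated, so the curve starts at the cross-species result.
#' * `ann_mix_no_transfer` — retrained from scratch on source-train plus the
#'   chunk ("regular training without transfer").
#' * `ann_target_only` — trained from scratch on the chunk only (no model at
#'   chunk 0; metrics reported as NA there).
#' * `ann_baseline_full` / `xgb_baseline_full` — trained once on the complete
#'   target training split; constant across chunk sizes.
#'
#' @inheritParams run_cross
#' @param configs subset of the six configuration names.
#' @param chunk_sizes cumulative chunk sizes (multiples of the step).
#' @param repeats which repeat indices (0-based) of the ten splits to run;
#'   the default uses repeat 0.
#' @param model_args list with optional `cfg` (ANN source/retrain),
#'   `transfer_cfg` (ANN fine-tune), `params`/`nrounds` (XGB),
#'   `n_new_trees` (XGB transfer).
#' @return data.frame of experiment results, one row per configuration,
#'   chunk size and repeat.
#' @export
run_transfer_curve <- function(source_table, target_table, spec = split_spec(),
                               configs = TRANSFER_CONFIGS,
                               chunk_sizes = seq(0L, 500L, by = 100L),
                               repeats = 0L, model_args = list()) {
  unknown <- setdiff(configs, TRANSFER_CONFIGS)
  if (length(unknown)) stopf("unknown config(s): %s", paste(unknown, collapse = ", "))
  if (!identical(feature_names(source_table), feature_names(target_table))) {
    stopf("source and target schemas differ")
  }
  step <- min(chunk_sizes[chunk_sizes > 0])
  max_total <- max(chunk_sizes)
  s_splits <- stratified_split(source_table, spec)
  t_splits <- stratified_split(target_table, spec)
  src_sp <- species_of(source_table)
  tgt_sp <- species_of(target_table)
  rows <- list()
  for (r in repeats) {
    ss <- s_splits[[r + 1L]]; ts <- t_splits[[r + 1L]]
    src_train <- ft_by_ids(source_table, ss$train_ids)
    src_val <- ft_by_ids(source_table, ss$validation_ids)
    tgt_train <- ft_by_ids(target_table, ts$train_ids)
    tgt_val <- ft_by_ids(target_table, ts$validation_ids)
    test <- ft_by_ids(target_table, ts$test_ids)
    chunks <- sample_chunks(tgt_train, chunk_size = step, max_total = max_total,
                            seed = child_seed(spec$rng_seed, 100L + r))
    chunk_ids <- function(k) if (k == 0L) character(0) else chunks[[k %/% step]]
    for (k in chunk_sizes) {
      assert_isolation(ts$test_ids, chunk_ids(k))
    }
    eval_model <- function(model) {
      compute_metrics(table_labels(test), predict(model, test))
    }
    need_ann_source <- any(c("ann_transfer") %in% configs)
    ann_source <- if (need_ann_source) {
      fit_family("ann", src_train, src_val, model_args)
    }
    xgb_source <- if ("xgb_transfer" %in% configs) {
      fit_family("xgb", src_train, src_val, model_args)
    }
    for (cfg_name in configs) {
      if (cfg_name %in% c("ann_baseline_full", "xgb_baseline_full")) {
        fam <- sub("_baseline_full", "", cfg_name)
        model <- fit_family(fam, tgt_train, tgt_val, model_args)
        m <- eval_model(model)
        for (k in chunk_sizes) {
          rows[[length(rows) + 1L]] <- result_row("transfer", src_sp, tgt_sp,
                                                  cfg_name, k, r, m)
        }
        next
      }
      for (k in chunk_sizes) {
        ids <- chunk_ids(k)
        chunk <- ft_by_ids(target_table, ids)
        attr(chunk, "species") <- tgt_sp
        m <- switch(cfg_name,
          ann_transfer = {
            model <- if (k == 0L) ann_source else {
              transfer_ann(ann_source, chunk, model_args$transfer_cfg)
            }
            eval_model(model)
          },
          xgb_transfer = {
            model <- if (k == 0L) xgb_source else {
              transfer_xgb(xgb_source, chunk,
                           n_new_trees = model_args$n_new_trees %||% 50L)
            }
            eval_model(model)
          },
          ann_mix_no_transfer = {
            mix <- feature_table(rbind(as.data.frame(src_train),
                                       as.data.frame(chunk)),
                                 feature_names(src_train))
            eval_model(fit_family("ann", mix, src_val, model_args))
          },
          ann_target_only = {
            if (k == 0L) list(ACC = NA_real_, AUC = NA_real_,
                              F1 = NA_real_, MCC = NA_real_)
            else eval_model(fit_family("ann", chunk, NULL, model_args))
          })
        rows[[length(rows) + 1L]] <- result_row("transfer", src_sp, tgt_sp,
                                                cfg_name, k, r, m)
      }
    }
  }
  do.call(rbind, rows)
}

#' Reshape results into a species-by-species matrix for one metric
#'
#' Heatmap-ready: rows are source species, columns target species, values the
#' mean of `metric` over repeats.
#'
#' @param results data.frame from the harnesses.
#' @param metric one of `"ACC"`, `"AUC"`, `"F1"`, `"MCC"`.
#' @export
results_matrix <- function(results, metric = "ACC") {
  stopifnot(metric %in% c("ACC", "AUC", "F1", "MCC"))
  agg <- stats::aggregate(results[[metric]],
                          by = list(source = results$source_species,
                                    target = results$target_species),
                          FUN = mean, na.rm = TRUE)
  species <- sort(unique(c(agg$source, agg$target)))
  m <- matrix(NA_real_, length(species), length(species),
              dimnames = list(source = species, target = species))
  for (i in seq_len(nrow(agg))) m[agg$source[i], agg$target[i]] <- agg$x[i]
  m
}
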