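# Transfer models: a common S3 wrapper around the two classifier families.
# ANN transfer = fine-tuning with frozen layers; XGB transfer = boosting
# continuation (new trees appended to the source ensemble, "partial fit").
# The source-phase parameters are always retained untouched so that the
# transfer step itself can be interrogated (predictions of both phases,
# TransferSHAP).

new_transfer_model <- function(family, source_state, scaler, feature_names,
                               config, mechanism, background,
                               provenance = list()) {
  structure(list(family = family, source_state = source_state,
                 transfer_state = NULL, mechanism = mechanism,
                 scaler = scaler, feature_names = feature_names,
                 config = config, background = background,
                 provenance = modifyList(list(source_species = NA_character_,
                                              target_species = NA_character_,
                                              n_target_observations = 0L),
                                         provenance)),
            class = "transfer_model")
}

model_scale <- function(model, X) {
  sweep(sweep(X, 2L, model$scaler$center, `-`), 2L, model$scaler$scale, `/`)
}

check_schema <- function(model, ft) {
  if (!identical(feature_names(ft), model$feature_names)) {
    stopf("feature schema mismatch between model and table")
  }
}

# Deterministic background sample (for Shapley reference distributions),
# capped at `cap` rows.
background_sample <- function(X, cap = 256L, seed = 99L) {
  if (nrow(X) <= cap) return(X)
  with_local_seed(seed, X[sample.int(nrow(X), cap), , drop = FALSE])
}

#' Train a feed-forward ANN source model
#'
#' Features are standardized by training-set mean and standard deviation
#' (stored in the model and re-applied at prediction time); training
#' minimizes binary cross-entropy with the settings in `cfg`. With a
#' validation table, early stopping keeps the weights of the best validation
#' epoch. Deterministic given `cfg$rng_seed`.
#'
#' @param table balanced training `feature_table`.
#' @param cfg an [ann_config()].
#' @param validation optional validation `feature_table` (same schema).
#' @return A `transfer_model` of family `"ann"`.
#' @export
train_ann <- function(table, cfg = ann_config(), validation = NULL) {
  stopifnot(inherits(table, "feature_table"), inherits(cfg, "ann_config"))
  X <- feature_matrix(table)
  y <- table_labels(table)
  ctr <- colMeans(X)
  scl <- apply(X, 2L, sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  Xs <- sweep(sweep(X, 2L, ctr, `-`), 2L, scl, `/`)
  Xv <- NULL; yv <- NULL
  if (!is.null(validation)) {
    if (!identical(feature_names(validation), feature_names(table))) {
      stopf("validation schema does not match training schema")
    }
    Xv <- sweep(sweep(feature_matrix(validation), 2L, ctr, `-`), 2L, scl, `/`)
    yv <- table_labels(validation)
  }
  cfg_src <- cfg
  cfg_src$frozen_layers <- integer(0) # freezing applies to the transfer phase
  net <- ann_fit(Xs, y, cfg_src, X_val = Xv, y_val = yv)
  new_transfer_model("ann", net, scaler = list(center = ctr, scale = scl),
                     feature_names = feature_names(table), config = cfg,
                     mechanism = "freeze_layers",
                     background = background_sample(X),
                     provenance = list(source_species =
                                         attr(table, "species") %||% NA_character_))
}

#' Fine-tune an ANN model on a target chunk with frozen layers
#'
#' Continues training from the source weights on the target chunk; dense
#' layers listed in `cfg$frozen_layers` are skipped by the optimizer and stay
#' bitwise identical. The source model is retained untouched inside the
#' returned object. The default freeze set is every dense layer except the
#' last two.
#'
#' @param model a `transfer_model` of family `"ann"`.
#' @param target_chunk `feature_table` of target-species training rows.
#' @param cfg optional [ann_config()] for the transfer phase; defaults to the
#'   source configuration with the default freeze set.
#' @return A new `transfer_model` carrying both phases.
#' @export
transfer_ann <- function(model, target_chunk, cfg = NULL) {
  stopifnot(inherits(model, "transfer_model"))
  if (model$family != "ann") stopf("transfer_ann requires an ann model")
  check_schema(model, target_chunk)
  n_dense <- length(model$config$layer_widths) + 1L
  if (is.null(cfg)) {
    cfg <- model$config
    cfg$frozen_layers <- seq_len(max(0L, n_dense - 2L))
    # fine-tuning convention: halve the step size (as the boosting
    # continuation halves its learning rate) and train the small chunk
    # longer, to convergence
    cfg$learning_rate <- cfg$learning_rate / 2
    cfg$epochs <- cfg$epochs * 2L
  }
  if (all(seq_len(n_dense) %in% cfg$frozen_layers)) {
    stopf("all layers are frozen: nothing to train")
  }
  if (nrow(target_chunk) == 0L) {
    # zero target observations: the transfer model is the source model
    out <- model
    out$provenance$n_target_observations <- 0L
    return(out)
  }
  Xs <- model_scale(model, feature_matrix(target_chunk))
  y <- table_labels(target_chunk)
  net <- ann_fit(Xs, y, cfg, net = model$source_state)
  out <- model
  out$transfer_state <- net
  out$config_transfer <- cfg
  out$background <- rbind(model$background,
                          background_sample(feature_matrix(target_chunk)))
  out$provenance$n_target_observations <- nrow(target_chunk)
  out$provenance$target_species <- attr(target_chunk, "species") %||%
    out$provenance$target_species
  out
}

xgb_default_params <- function() {
  list(max_depth = 4L, eta = 0.1, min_child_weight = 1, subsample = 1,
       colsample_bytree = 1, gamma = 0, lambda = 1,
       objective = "binary:logistic", eval_metric = "logloss",
       nthread = 1L, seed = 1L)
}

#' Train a gradient-boosted tree source model
#'
#' Thin wrapper over [xgboost::xgb.train()] with single-threaded,
#' seed-deterministic settings; with a validation table, early stopping on
#' validation log-loss is applied.
#'
#' @param table balanced training `feature_table`.
#' @param params named list overriding the defaults (max_depth 4, eta 0.1,
#'   binary:logistic, single thread).
#' @param validation optional validation `feature_table`.
#' @param nrounds boosting rounds.
#' @param early_stopping_rounds patience for early stopping (ignored without
#'   a validation set).
#' @return A `transfer_model` of family `"xgb"`.
#' @export
train_xgb <- function(table, params = list(), validation = NULL,
                      nrounds = 200L, early_stopping_rounds = 20L) {
  stopifnot(inherits(table, "feature_table"))
  y <- table_labels(table)
  if (length(unique(y)) < 2L) stopf("degenerate training set: all labels identical")
  params <- modifyList(xgb_default_params(), params)
  X <- feature_matrix(table)
  dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1L)
  args <- list(params = params, data = dtrain, nrounds = nrounds, verbose = 0)
  if (!is.null(validation)) {
    if (!identical(feature_names(validation), feature_names(table))) {
      stopf("validation schema does not match training schema")
    }
    dval <- xgboost::xgb.DMatrix(feature_matrix(validation),
                                 label = table_labels(validation), nthread = 1L)
    args$evals <- list(val = dval)
    args$early_stopping_rounds <- early_stopping_rounds
  }
  booster <- do.call(xgboost::xgb.train, args)
  scaler <- list(center = rep(0, ncol(X)), scale = rep(1, ncol(X)))
  m <- new_transfer_model("xgb", booster, scaler = scaler,
                          feature_names = feature_names(table),
                          config = list(params = params, nrounds = nrounds),
                          mechanism = "boosting_continuation",
                          background = background_sample(X),
                          provenance = list(source_species =
                                              attr(table, "species") %||% NA_character_))
  m
}

#' Continue boosting on a target chunk ("partial fit")
#'
#' Appends `n_new_trees` trees fitted on the target chunk to the source
#' ensemble; the original trees are preserved verbatim and the source booster
#' is retained untouched. The learning rate is halved during continuation to
#' keep the update low-variance on small chunks.
#'
#' @param model a `transfer_model` of family `"xgb"`.
#' @param target_chunk `feature_table` of target training rows (non-empty
#'   unless `n_new_trees = 0`).
#' @param n_new_trees number of additional trees.
#' @return A new `transfer_model` carrying both phases.
#' @export
transfer_xgb <- function(model, target_chunk, n_new_trees = 50L) {
  stopifnot(inherits(model, "transfer_model"))
  if (model$family != "xgb") stopf("transfer_xgb requires an xgb model")
  if (n_new_trees == 0L) {
    out <- model
    out$transfer_state <- model$source_state
    out$provenance$n_target_observations <- nrow(target_chunk) %||% 0L
    return(out)
  }
  if (is.null(target_chunk) || nrow(target_chunk) == 0L) {
    stopf("empty target chunk")
  }
  check_schema(model, target_chunk)
  params <- model$config$params
  params$eta <- params$eta / 2
  dchunk <- xgboost::xgb.DMatrix(feature_matrix(target_chunk),
                                 label = table_labels(target_chunk), nthread = 1L)
  # continue from a detached copy of the source booster: xgb.train would
  # otherwise mutate (and can invalidate) the shared source handle when the
  # same source model is continued repeatedly
  src_copy <- xgboost::xgb.load.raw(xgboost::xgb.save.raw(model$source_state))
  booster <- xgboost::xgb.train(params = params, data = dchunk,
                                nrounds = n_new_trees, verbose = 0,
                                xgb_model = src_copy)
  # the inherited early-stopping marker would cap prediction at the source
  # prefix, silently ignoring the continuation trees
  xgboost::xgb.attr(booster, "best_iteration") <- NULL
  out <- model
  out$transfer_state <- booster
  out$background <- rbind(model$background,
                          background_sample(feature_matrix(target_chunk)))
  out$provenance$n_target_observations <- nrow(target_chunk)
  out$provenance$target_species <- attr(target_chunk, "species") %||%
    out$provenance$target_species
  out
}

#' Predict interaction probabilities
#'
#' @param object a `transfer_model`.
#' @param newdata a `feature_table` or a numeric matrix with the model's
#'   feature columns.
#' @param phase `"auto"` (transfer state when present, else source),
#'   `"source"` or `"transfer"`.
#' @param ... unused.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict.transfer_model <- function(object, newdata,
                                   phase = c("auto", "source", "transfer"), ...) {
  phase <- match.arg(phase)
  X <- if (inherits(newdata, "feature_table")) {
    check_schema(object, newdata)
    feature_matrix(newdata)
  } else {
    as.matrix(newdata)[, object$feature_names, drop = FALSE]
  }
  state <- switch(phase,
    auto = object$transfer_state %||% object$source_state,
    source = object$source_state,
    transfer = {
      if (is.null(object$transfer_state)) {
        stopf("model has no transfer state (n_target_observations = 0?)")
      }
      object$transfer_state
    })
  if (object$family == "ann") {
    unname(ann_predict(state, model_scale(object, X)))
  } else {
    unname(as.numeric(predict(state, xgboost::xgb.DMatrix(X, nthread = 1L))))
  }
}

#' @export
print.transfer_model <- function(x, ...) {
  cat(sprintf("transfer_model <%s, %s>: source=%s target=%s n_target=%d%s\n",
              x$family, x$mechanism,
              x$provenance$source_species, x$provenance$target_species,
              x$provenance$n_target_observations,
              if (is.null(x$transfer_state)) " (source phase only)" else ""))
  invisible(x)
}

#' Exhaustive grid search over model hyperparameters
#'
#' Fits every combination of the supplied grid on the training table,
#' evaluates classification accuracy on the validation table, and returns the
#' best combination (ties broken by declared grid order: the first maximum
#' wins) together with the full results table.
#'
#' @param family `"ann"` or `"xgb"`.
#' @param table training `feature_table`.
#' @param validation validation `feature_table`.
#' @param grid named list of parameter value vectors. For `"ann"` the names
#'   must be [ann_config()] arguments; for `"xgb"`, [train_xgb()] params or
#'   `nrounds`.
#' @param fit_hook optional function called once per fitted configuration
#'   (receives the one-row parameter data.frame); useful for counting fits.
#' @return List with `best_params` (named list), `results` (data.frame with
#'   one row per grid point and its validation accuracy), `n_fits`.
#' @export
grid_search <- function(family = c("ann", "xgb"), table, validation, grid,
                        fit_hook = NULL) {
  family <- match.arg(family)
  stopifnot(length(grid) >= 1L, !is.null(names(grid)))
  combos <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  acc <- numeric(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    pars <- as.list(combos[i, , drop = FALSE])
    names(pars) <- names(combos)
    pars <- lapply(pars, function(p) if (is.list(p)) p[[1]] else p)
    if (!is.null(fit_hook)) fit_hook(combos[i, , drop = FALSE])
    model <- if (family == "ann") {
      train_ann(table, do.call(ann_config, pars), validation)
    } else {
      nr <- pars$nrounds %||% 100L
      pars$nrounds <- NULL
      train_xgb(table, params = pars, validation = validation, nrounds = nr)
    }
    scores <- predict(model, validation)
    acc[i] <- compute_metrics(table_labels(validation), scores)$ACC
  }
  best <- which.max(acc) # first maximum in declared grid order
  results <- cbind(combos, validation_accuracy = acc)
  best_params <- as.list(combos[best, , drop = FALSE])
  names(best_params) <- names(combos)
  list(best_params = best_params, results = results, n_fits = nrow(combos))
}
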