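# Dataset mechanics: merging per-experiment tables into species tables, the
# miRNA-stratified 80/10/20 split with singleton handling and ten repeats,
# and nested chunk sampling for the transfer phase.

#' Split specification
#'
#' 80% of the data goes to training, 20% to test; 10% of the training set is
#' reserved for validation, so the validation share of the whole dataset is a
#' fixed 8%. The split is repeated `n_repeats` times with different random
#' assignments.
#'
#' @param train_fraction fraction of rows in the training set.
#' @param validation_fraction_of_train fraction of the training set reserved
#'   for validation.
#' @param n_repeats number of independent repeats.
#' @param rng_seed integer seed; splits are deterministic given the seed.
#' @export
split_spec <- function(train_fraction = 0.8, validation_fraction_of_train = 0.1,
                       n_repeats = 10L, rng_seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1,
            validation_fraction_of_train >= 0, validation_fraction_of_train < 1,
            n_repeats >= 1L)
  structure(list(train_fraction = train_fraction,
                 validation_fraction_of_train = validation_fraction_of_train,
                 n_repeats = as.integer(n_repeats),
                 rng_seed = as.integer(rng_seed)),
            class = "split_spec")
}

#' Merge per-experiment feature tables into one species table
#'
#' Concatenates tables with identical schemas, preserving the `source`
#' provenance column. Duplicate interaction ids across inputs are
#' deduplicated keeping the first occurrence (a message reports how many).
#'
#' @param tables list of `feature_table`s with identical feature columns.
#' @param species species identifier attached to the merged table.
#' @return A `feature_table`.
#' @export
merge_species <- function(tables, species) {
  stopifnot(length(tables) >= 1L)
  fn <- feature_names(tables[[1]])
  for (t in tables[-1]) {
    if (!identical(feature_names(t), fn)) {
      stopf("cannot merge: feature schemas differ")
    }
  }
  merged <- do.call(rbind, lapply(tables, as.data.frame))
  dup <- duplicated(merged$interaction_id)
  if (any(dup)) {
    message(sprintf("merge_species: dropping %d duplicate interaction id(s)",
                    sum(dup)))
    merged <- merged[!dup, , drop = FALSE]
  }
  rownames(merged) <- NULL
  out <- feature_table(merged, fn)
  attr(out, "species") <- species
  out
}

# Largest-remainder integer allocation: distribute `total` items over strata
# proportionally to quota (real counts), ties broken by stratum name order.
largest_remainder <- function(quota, total) {
  fl <- floor(quota)
  rem <- total - sum(fl)
  if (rem > 0) {
    frac <- quota - fl
    ord <- order(-frac, names(quota))
    fl[ord[seq_len(rem)]] <- fl[ord[seq_len(rem)]] + 1L
  } else if (rem < 0) {
    ord <- order(quota - fl, names(quota))
    take <- ord[fl[ord] > 0][seq_len(-rem)]
    fl[take] <- fl[take] - 1L
  }
  as.integer(fl)
}

#' miRNA-stratified repeated train/validation/test split
#'
#' Rows are allocated per miRNA so that each miRNA's train/validation/test
#' proportions match the whole-dataset 72/8/20 proportions as closely as
#' integer allocation allows (largest-remainder rounding, ties by miRNA name
#' order). miRNAs with exactly one interaction always go to the test set, so
#' every model is evaluated on at least some entirely unseen miRNAs. The
#' procedure is repeated `spec$n_repeats` times with fresh random assignments
#' within each miRNA; everything is deterministic given `spec$rng_seed`.
#'
#' @param table a `feature_table` with miRNA ids.
#' @param spec a [split_spec()].
#' @return A list of `spec$n_repeats` splits; each is a list with
#'   `train_ids`, `validation_ids`, `test_ids`, `repeat_index`.
#' @export
stratified_split <- function(table, spec = split_spec()) {
  stopifnot(inherits(table, "feature_table"), inherits(spec, "split_spec"))
  if (nrow(table) < 5L) stopf("table too small to honor split fractions (%d rows)",
                              nrow(table))
  ids_by_mirna <- split(table$interaction_id, table$mirna_id)
  sizes <- lengths(ids_by_mirna)
  singles <- names(sizes)[sizes == 1L]
  multi <- names(sizes)[sizes > 1L]
  n_total <- nrow(table)
  test_frac <- 1 - spec$train_fraction
  target_test <- round(test_frac * n_total)
  target_test_multi <- max(0L, target_test - length(singles))
  quota_test <- test_frac * sizes[multi]
  test_alloc <- stats::setNames(
    largest_remainder(stats::setNames(as.numeric(quota_test), multi),
                      target_test_multi), multi)
  trainval_sizes <- sizes[multi] - test_alloc
  target_val <- round(spec$train_fraction * spec$validation_fraction_of_train * n_total)
  quota_val <- spec$validation_fraction_of_train * trainval_sizes
  val_alloc <- stats::setNames(
    largest_remainder(stats::setNames(as.numeric(quota_val), multi),
                      min(target_val, sum(trainval_sizes))), multi)
  lapply(seq_len(spec$n_repeats) - 1L, function(r) {
    with_local_seed(child_seed(spec$rng_seed, r), {
      test_ids <- unlist(ids_by_mirna[singles], use.names = FALSE)
      val_ids <- character(0)
      train_ids <- character(0)
      for (m in multi) {
        ids <- sample(ids_by_mirna[[m]])
        nt <- test_alloc[[m]]
        nv <- val_alloc[[m]]
        if (nt > 0L) test_ids <- c(test_ids, ids[seq_len(nt)])
        rest <- if (nt > 0L) ids[-seq_len(nt)] else ids
        if (nv > 0L) {
          val_ids <- c(val_ids, rest[seq_len(nv)])
          rest <- rest[-seq_len(nv)]
        }
        train_ids <- c(train_ids, rest)
      }
      list(train_ids = train_ids, validation_ids = val_ids,
           test_ids = test_ids, repeat_index = r)
    })
  })
}

#' Nested, label-balanced transfer chunks
#'
#' Samples cumulative chunks of target-species training interactions for the
#' transfer phase: nested id sets of sizes `chunk_size, 2*chunk_size, ...,
#' max_total`, each drawn without replacement from the training split only
#' and balanced 50/50 between labels whenever the remaining pool allows.
#' Nesting makes the transfer curve monotone in data, matching how the curve
#' is reported per cumulative count.
#'
#' @param train_table `feature_table` restricted to the target training split.
#' @param chunk_size observations added per step.
#' @param max_total maximum cumulative observations (truncated with a warning
#'   if the table is smaller).
#' @param seed RNG seed.
#' @return List of character vectors of interaction ids, nested and of sizes
#'   `chunk_size * (1:k)`.
#' @export
sample_chunks <- function(train_table, chunk_size = 100L, max_total = 500L,
                          seed = 1L) {
  stopifnot(inherits(train_table, "feature_table"))
  chunk_size <- as.integer(chunk_size)
  max_total <- as.integer(max_total)
  if (nrow(train_table) < max_total) {
    warning(sprintf("train table has %d rows < max_total %d; truncating",
                    nrow(train_table), max_total), call. = FALSE)
    max_total <- chunk_size * (nrow(train_table) %/% chunk_size)
  }
  with_local_seed(seed, {
    pos_pool <- sample(train_table$interaction_id[train_table$label == 1L])
    neg_pool <- sample(train_table$interaction_id[train_table$label == 0L])
    out <- list()
    acc <- character(0)
    half <- chunk_size %/% 2L
    while (length(acc) + chunk_size <= max_total) {
      take_pos <- min(half, length(pos_pool))
      take_neg <- min(chunk_size - take_pos, length(neg_pool))
      if (take_pos + take_neg < chunk_size) {
        extra <- chunk_size - take_pos - take_neg
        add_pos <- min(extra, length(pos_pool) - take_pos)
        take_pos <- take_pos + add_pos
      }
      chunk <- c(pos_pool[seq_len(take_pos)], neg_pool[seq_len(take_neg)])
      pos_pool <- pos_pool[-seq_len(take_pos)]
      if (take_neg > 0L) neg_pool <- neg_pool[-seq_len(take_neg)]
      acc <- c(acc, chunk)
      out[[length(out) + 1L]] <- acc
    }
    out
  })
}

#' Write / read split manifests
#'
#' Persists the id sets of every repeat as JSON so that experiments are
#' exactly replayable.
#'
#' @param splits result of [stratified_split()].
#' @param path JSON file path.
#' @export
write_split_manifest <- function(splits, path) {
  jsonlite::write_json(splits, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_split_manifest
#' @export
read_split_manifest <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(seq_len(nrow_or_len(raw)), function(i) {
    s <- if (is.data.frame(raw)) raw[i, ] else raw[[i]]
    list(train_ids = unlist(s$train_ids), validation_ids = unlist(s$validation_ids),
         test_ids = unlist(s$test_ids), repeat_index = unlist(s$repeat_index))
  })
}

nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
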