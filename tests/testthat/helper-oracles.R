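# Independent oracles shared across test files.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Direct-arithmetic oracle for F1 and MCC from raw confusion counts, written
# independently of the package implementation (F1 via precision/recall).
oracle_f1_mcc <- function(TP, TN, FP, FN) {
  prec <- if (TP + FP == 0) NA_real_ else TP / (TP + FP)
  rec <- if (TP + FN == 0) NA_real_ else TP / (TP + FN)
  f1 <- if (is.na(prec) || is.na(rec) || prec + rec == 0) 0
    else 2 * prec * rec / (prec + rec)
  den <- sqrt(as.numeric(TP + FP)) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
  mcc <- if (den == 0) 0 else (TP * TN - FP * FN) / den
  c(F1 = f1, MCC = mcc)
}

# Brute-force double loop for the TransferSHAP column aggregation.
oracle_transfershap <- function(src, tgt) {
  out <- numeric(ncol(src))
  for (j in seq_len(ncol(src))) {
    for (i in seq_len(nrow(src))) {
      out[j] <- out[j] + abs(tgt[i, j] - src[i, j])
    }
  }
  out
}

# Assemble a shapley_matrix object directly from a value matrix.
fake_phi <- function(values, ids = NULL, features = NULL) {
  features <- features %||% paste0("f", seq_len(ncol(values)))
  ids <- ids %||% sprintf("o%02d", seq_len(nrow(values)))
  colnames(values) <- features
  structure(list(values = values, base_values = rep(0, nrow(values)),
                 observation_ids = ids, feature_names = features,
                 method = "exact_small", family = "xgb"),
            class = "shapley_matrix")
}
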