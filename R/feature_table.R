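# The FeatureTable container: a plain data.frame in the package's "standard
# format" — metadata columns (interaction_id, source, mirna_id), a 0/1 label
# column, then the named feature columns. Feature columns are everything that
# is not metadata/label, recorded in the "feature_names" attribute so callers
# never guess.

META_COLS <- c("interaction_id", "source", "mirna_id", "label")

#' Construct / validate a feature table
#'
#' @param df a data.frame with metadata columns `interaction_id`, `source`,
#'   `mirna_id`, an integer 0/1 `label`, and numeric feature columns.
#' @param feature_names optional explicit feature column names; defaults to
#'   all non-metadata columns.
#' @return The validated data.frame with class `feature_table`.
#' @export
feature_table <- function(df, feature_names = NULL) {
  stopifnot(is.data.frame(df))
  missing_meta <- setdiff(META_COLS, names(df))
  if (length(missing_meta)) {
    stopf("feature table lacks metadata columns: %s",
          paste(missing_meta, collapse = ", "))
  }
  feature_names <- feature_names %||% setdiff(names(df), META_COLS)
  bad <- feature_names[!vapply(df[feature_names], is.numeric, logical(1))]
  if (length(bad)) stopf("non-numeric feature columns: %s", paste(bad, collapse = ", "))
  if (nrow(df) && !all(df$label %in% c(0L, 1L))) stopf("labels must be 0/1")
  attr(df, "feature_names") <- feature_names
  class(df) <- unique(c("feature_table", class(df)))
  df
}

#' @rdname feature_table
#' @param ft a `feature_table`.
#' @export
feature_names <- function(ft) attr(ft, "feature_names")

#' @rdname feature_table
#' @export
feature_matrix <- function(ft) {
  as.matrix(as.data.frame(ft)[, feature_names(ft), drop = FALSE])
}

#' @rdname feature_table
#' @export
table_labels <- function(ft) as.integer(ft$label)

# Subset rows of a feature table, preserving attributes.
ft_rows <- function(ft, idx) {
  out <- as.data.frame(ft)[idx, , drop = FALSE]
  rownames(out) <- NULL
  out <- feature_table(out, feature_names(ft))
  attr(out, "species") <- attr(ft, "species")
  out
}

ft_by_ids <- function(ft, ids) {
  idx <- match(ids, ft$interaction_id)
  if (anyNA(idx)) stopf("unknown interaction ids: %s",
                        paste(head(ids[is.na(idx)], 5), collapse = ", "))
  ft_rows(ft, idx)
}

#' Read / write feature tables in the standard TSV format
#'
#' Tab-separated with a header row; metadata columns first, then features.
#'
#' @param path file path.
#' @export
read_feature_table <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
  feature_table(df)
}

#' @rdname read_feature_table
#' @param ft a `feature_table`.
#' @export
write_feature_table <- function(ft, path) {
  write.table(as.data.frame(ft), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d interactions, %d features, %d positive / %d negative\n",
              nrow(x), length(feature_names(x)), sum(x$label == 1), sum(x$label == 0)))
  invisible(x)
}

# Minimal FASTA I/O for plain character vectors of sequences. Uses Biostrings
# when available for robustness; falls back to a simple reader otherwise.
#' Write named sequences as FASTA
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(c(paste0(">", names(seqs)[i]), seqs[[i]]), con)
  }
  invisible(path)
}

#' Read a FASTA file into a named character vector
#'
#' Accepts miRBase-style headers; only the first whitespace-delimited token of
#' each header is kept as the sequence id.
#' @param path FASTA file.
#' @export
read_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    ss <- Biostrings::readBStringSet(path)
    out <- toupper(as.character(ss))
    names(out) <- vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1L)
    return(gsub("T", "U", out, fixed = TRUE))
  }
  lines <- readLines(path)
  idx <- grep("^>", lines)
  if (!length(idx)) stopf("no FASTA records in %s", path)
  ids <- sub("^>\\s*", "", lines[idx])
  ids <- vapply(strsplit(ids, "\\s+"), `[`, character(1), 1L)
  ends <- c(idx[-1L] - 1L, length(lines))
  seqs <- vapply(seq_along(idx), function(i) {
    paste(lines[(idx[i] + 1L):ends[i]], collapse = "")
  }, character(1))
  stats::setNames(gsub("T", "U", toupper(seqs), fixed = TRUE), ids)
}
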