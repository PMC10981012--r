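# Feature extraction for miRNA:site pairs. The schema is a fixed, versioned,
# ordered set of ~50 numeric/Boolean features spanning the families used for
# tabular MTI classification: seed-type indicators, per-region duplex pairing
# counts, duplex score summaries, site/miRNA composition, and site location.

FEATURE_SCHEMA_VERSION <- "1.0"

NUC <- c("A", "C", "G", "U")
DINUC <- as.vector(outer(NUC, NUC, paste0))

feature_schema_names <- function() {
  c("seed_canonical_2_7", "seed_canonical_3_8",
    "seed_noncanonical_2_7", "seed_noncanonical_3_8",
    "seed_type_canonical", "seed_type_noncanonical",
    "wc_pairs_seed", "gu_pairs_seed", "unpaired_seed",
    "wc_pairs_central", "gu_pairs_central", "unpaired_central",
    "wc_pairs_comp", "gu_pairs_comp", "unpaired_comp",
    "duplex_score", "n_paired", "frac_mirna_paired", "longest_wc_run",
    paste0("site_freq_", NUC),
    paste0("site_freq_", DINUC),
    "site_au_content", "site_gc_content", "site_length", "site_rel_position",
    "mirna_length", "mirna_gc_content", paste0("mirna_freq_", NUC))
}

#' Feature schema manifest
#'
#' The ordered list of features produced by [extract_features()], with type
#' and a one-line description each. The same manifest ships as
#' `inst/extdata/feature_manifest.json` and is used by tests to pin the
#' schema.
#'
#' @return A data.frame with columns `name`, `type`, `description`.
#' @export
feature_schema <- function() {
  n <- feature_schema_names()
  type <- rep("numeric", length(n))
  type[grepl("^seed_", n)] <- "boolean"
  desc <- character(length(n))
  names(desc) <- n
  desc[grepl("^seed_canonical", n)] <- "canonical seed pairing in the window"
  desc[grepl("^seed_noncanonical", n)] <- "non-canonical seed pairing in the window"
  desc["seed_type_canonical"] <- "overall seed class is canonical"
  desc["seed_type_noncanonical"] <- "overall seed class is non-canonical"
  desc[grepl("^wc_pairs_", n)] <- "Watson-Crick pairs in the miRNA region"
  desc[grepl("^gu_pairs_", n)] <- "GU wobble pairs in the miRNA region"
  desc[grepl("^unpaired_", n)] <- "unpaired miRNA positions in the region"
  desc["duplex_score"] <- "total duplex score (arbitrary units)"
  desc["n_paired"] <- "number of paired bases in the duplex"
  desc["frac_mirna_paired"] <- "fraction of miRNA positions paired"
  desc["longest_wc_run"] <- "longest run of consecutive WC pairs"
  desc[grepl("^site_freq_", n)] <- "site mono-/di-nucleotide frequency"
  desc["site_au_content"] <- "A+U fraction of the site"
  desc["site_gc_content"] <- "G+C fraction of the site"
  desc["site_length"] <- "site length in nt"
  desc["site_rel_position"] <- "site start / UTR length (0 without context)"
  desc["mirna_length"] <- "miRNA length in nt"
  desc["mirna_gc_content"] <- "G+C fraction of the miRNA"
  desc[grepl("^mirna_freq_", n)] <- "miRNA mononucleotide frequency"
  data.frame(name = n, type = type, description = unname(desc),
             stringsAsFactors = FALSE)
}

region_counts <- function(duplex, from, to) {
  p <- duplex$pairs
  p <- p[p$mirna_pos >= from & p$mirna_pos <= to, , drop = FALSE]
  width <- to - from + 1L
  c(wc = sum(p$type == "WC"), gu = sum(p$type == "GU"),
    unpaired = width - nrow(p))
}

seed_window_class <- function(duplex, a) {
  s <- seed_window_stats(duplex, a)
  if (s$n_paired == 6L && s$all_wc && s$consecutive) return("canonical")
  if (s$defects <= 1L) return("non_canonical")
  "other"
}

nt_freqs <- function(seq) {
  b <- strsplit(seq, "")[[1]]
  tab <- table(factor(b, levels = NUC))
  as.numeric(tab) / length(b)
}

dint_freqs <- function(seq) {
  b <- strsplit(seq, "")[[1]]
  if (length(b) < 2L) return(stats::setNames(rep(0, 16L), DINUC))
  di <- paste0(b[-length(b)], b[-1L])
  tab <- table(factor(di, levels = DINUC))
  as.numeric(tab) / (length(b) - 1L)
}

#' Extract the interaction feature vector
#'
#' Computes the fixed-order feature vector for one miRNA:site pair. The
#' duplex is predicted with [predict_duplex()]; seed windows 2-7 and 3-8 are
#' classified as in [classify_seed()]; miRNA regions are seed (1-8), central
#' (9-12) and 3'-compensatory (13-end), numbered 5'->3'. All features are
#' numeric; Boolean features take values 0/1 and absent signal encodes as 0.
#' The function is pure: identical inputs give identical vectors.
#'
#' @inheritParams predict_duplex
#' @param utr_context optional `c(utr_length, site_offset)` (1-based offset of
#'   the site within its UTR); when supplied, the relative-position feature is
#'   `site_offset / utr_length`, else 0.
#' @return Named numeric vector with attribute `schema_version`.
#' @export
extract_features <- function(mirna, site, utr_context = NULL) {
  mirna <- assert_rna(mirna, "mirna")
  site <- assert_rna(site, "site")
  dx <- predict_duplex(mirna, site)
  w27 <- seed_window_class(dx, 2L)
  w38 <- seed_window_class(dx, 3L)
  overall <- classify_seed(dx)
  seed <- region_counts(dx, 1L, 8L)
  central <- region_counts(dx, 9L, 12L)
  comp <- region_counts(dx, 13L, dx$mirna_len)
  is_wc <- seq_len(dx$mirna_len) %in% dx$pairs$mirna_pos[dx$pairs$type == "WC"]
  r <- rle(is_wc)
  longest_run <- if (any(r$values)) max(r$lengths[r$values]) else 0L
  rel_pos <- 0
  if (!is.null(utr_context)) {
    stopifnot(length(utr_context) == 2L)
    utr_len <- utr_context[[1]]
    offset <- utr_context[[2]]
    if (offset + nchar(site) - 1L > utr_len) {
      stopf("site offset %d + site length %d exceeds UTR length %d",
            offset, nchar(site), utr_len)
    }
    rel_pos <- offset / utr_len
  }
  sfreq <- nt_freqs(site)
  mfreq <- nt_freqs(mirna)
  v <- c(
    as.numeric(w27 == "canonical"), as.numeric(w38 == "canonical"),
    as.numeric(w27 == "non_canonical"), as.numeric(w38 == "non_canonical"),
    as.numeric(overall == "canonical"), as.numeric(overall == "non_canonical"),
    seed[["wc"]], seed[["gu"]], seed[["unpaired"]],
    central[["wc"]], central[["gu"]], central[["unpaired"]],
    comp[["wc"]], comp[["gu"]], comp[["unpaired"]],
    dx$score, nrow(dx$pairs), nrow(dx$pairs) / dx$mirna_len, longest_run,
    sfreq, dint_freqs(site),
    sfreq[1] + sfreq[4], sfreq[2] + sfreq[3], nchar(site), rel_pos,
    nchar(mirna), mfreq[2] + mfreq[3], mfreq
  )
  names(v) <- feature_schema_names()
  attr(v, "schema_version") <- FEATURE_SCHEMA_VERSION
  v
}

#' Build a feature table from interaction records
#'
#' Applies [extract_features()] to every record and assembles a
#' [feature_table()] carrying labels, miRNA group ids and metadata through.
#'
#' @param records data.frame of interaction records with columns
#'   `interaction_id`, `source`, `mirna_id`, `mirna_seq`, `site_seq`, `label`
#'   and optionally `utr_length`, `site_offset`.
#' @return A `feature_table` data.frame.
#' @export
extract_table <- function(records) {
  stopifnot(is.data.frame(records))
  fn <- feature_schema_names()
  if (nrow(records) == 0L) {
    empty <- as.data.frame(stats::setNames(
      rep(list(numeric(0)), length(fn)), fn))
    meta <- data.frame(interaction_id = character(0), source = character(0),
                       mirna_id = character(0), label = integer(0),
                       stringsAsFactors = FALSE)
    return(feature_table(cbind(meta, empty)))
  }
  has_ctx <- all(c("utr_length", "site_offset") %in% names(records))
  rows <- lapply(seq_len(nrow(records)), function(i) {
    ctx <- if (has_ctx) c(records$utr_length[i], records$site_offset[i]) else NULL
    extract_features(records$mirna_seq[i], records$site_seq[i], ctx)
  })
  sv <- unique(vapply(rows, attr, character(1), "schema_version"))
  if (length(sv) != 1L) stopf("mixed feature schema versions: %s",
                              paste(sv, collapse = ", "))
  feat <- as.data.frame(do.call(rbind, rows))
  meta <- data.frame(
    interaction_id = as.character(records$interaction_id),
    source = as.character(records$source %||% "unknown"),
    mirna_id = as.character(records$mirna_id),
    label = as.integer(records$label),
    stringsAsFactors = FALSE
  )
  feature_table(cbind(meta, feat))
}
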