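#' Predict the miRNA:target-site duplex structure
#'
#' Computes the maximum-score non-crossing intermolecular base pairing between
#' a miRNA (read 5'->3') and a target site (read antiparallel to the miRNA).
#' Base-pair scores are GC = +3, AU = +2, GU = +1; unpaired stretches between
#' two consecutive pairs are charged an affine gap cost per strand (opening 2,
#' extension 1) while unpaired flanks are free. The optimum is found by
#' dynamic programming over "last pair" states; ties are broken
#' deterministically by the DP scan order (miRNA position ascending, site
#' position descending), so repeated calls return the same structure.
#'
#' This is a deliberately simple base-pair scoring scheme, not a
#' nearest-neighbour thermodynamic model: scores are in arbitrary units,
#' higher meaning a more favourable duplex. The scorer sits behind a small
#' interface ([duplex_score_fun()]) so an external duplex engine can be
#' substituted without touching callers.
#'
#' @param mirna miRNA sequence, 5'->3', over A/C/G/U (T is converted to U
#'   with a warning).
#' @param site target-site sequence over A/C/G/U.
#' @return An object of class `duplex_structure`: a list with `pairs` (a
#'   data.frame with 1-based `mirna_pos`, `site_pos` and `type` in
#'   `{"WC","GU"}`), `score`, `mirna_len`, `site_len`.
#' @examples
#' dx <- predict_duplex("GGGG", "CCCC")
#' dx$score           # 12: four GC pairs
#' @export
predict_duplex <- function(mirna, site) {
  mirna <- assert_rna(mirna, "mirna")
  site <- assert_rna(site, "site")
  res <- .duplex_dp_cpp(mirna, site)
  mb <- strsplit(mirna, "")[[1]]
  sb <- strsplit(site, "")[[1]]
  type <- character(length(res$mirna_pos))
  if (length(type)) {
    a <- mb[res$mirna_pos]
    b <- sb[res$site_pos]
    type <- ifelse((a == "G" & b == "U") | (a == "U" & b == "G"), "GU", "WC")
  }
  structure(
    list(
      pairs = data.frame(mirna_pos = res$mirna_pos, site_pos = res$site_pos,
                         type = type, stringsAsFactors = FALSE),
      score = res$score,
      mirna_len = nchar(mirna),
      site_len = nchar(site)
    ),
    class = "duplex_structure"
  )
}

#' Exhaustive duplex score by enumeration
#'
#' Enumerates every non-crossing chain of base pairs between the two strands
#' and returns the maximum score under the same scoring scheme as
#' [predict_duplex()]. Exponential in sequence length; intended as an
#' independent reference for validating the dynamic program on short
#' sequences (lengths up to about 12).
#'
#' @inheritParams predict_duplex
#' @return The maximum duplex score (a single number).
#' @export
enumerate_duplex_score <- function(mirna, site) {
  mirna <- assert_rna(mirna, "mirna")
  site <- assert_rna(site, "site")
  .duplex_enumerate_cpp(mirna, site)
}

#' @export
print.duplex_structure <- function(x, ...) {
  cat(sprintf("duplex_structure: %d pairs, score %.1f (miRNA %d nt, site %d nt)\n",
              nrow(x$pairs), x$score, x$mirna_len, x$site_len))
  if (nrow(x$pairs)) print(x$pairs, row.names = FALSE)
  invisible(x)
}

#' Pluggable duplex scorer
#'
#' Returns the function used to score miRNA:site duplexes. Callers that scan
#' candidate sites (e.g. [generate_negative()]) go through this indirection so
#' that an alternative duplex engine can be plugged in via the
#' `mirtransfer.duplex_fun` option.
#'
#' @return A function `(mirna, site) -> duplex_structure`.
#' @export
duplex_score_fun <- function() {
  getOption("mirtransfer.duplex_fun", predict_duplex)
}

# Count pairing defects of a seed window [a, a+5] of the miRNA against a
# duplex. Returns list(defects, has_gu, n_wc): defects = unpaired miRNA
# positions in the window plus site-side bulged nucleotides between
# consecutive window pairs beyond those matched by miRNA-side gaps.
seed_window_stats <- function(duplex, a) {
  b <- a + 5L
  p <- duplex$pairs
  p <- p[p$mirna_pos >= a & p$mirna_pos <= b, , drop = FALSE]
  p <- p[order(p$mirna_pos), , drop = FALSE]
  unpaired <- 6L - nrow(p)
  site_bulge <- 0L
  if (nrow(p) >= 2L) {
    gm <- diff(p$mirna_pos) - 1L
    gs <- p$site_pos[-nrow(p)] - p$site_pos[-1L] - 1L
    site_bulge <- sum(pmax(0L, gs - gm))
  }
  list(defects = unpaired + site_bulge,
       has_gu = any(p$type == "GU"),
       consecutive = nrow(p) >= 2L &&
         all(diff(p$mirna_pos) == 1L) && all(diff(p$site_pos) == -1L),
       n_paired = nrow(p),
       all_wc = all(p$type == "WC"))
}

#' Classify the seed type of a duplex
#'
#' Decides the seed class of an interaction from its duplex structure,
#' restricted to miRNA seed positions. An interaction is *canonical* if
#' positions 2-7 or 3-8 of the miRNA are each Watson-Crick paired to
#' consecutive site positions (no bulge on either strand within the window);
#' *non-canonical* if, in one of those windows, pairing holds when GU pairs
#' are allowed and at most one position is bulged, mismatched or unpaired;
#' otherwise *other*. The two windows are checked independently and the more
#' favourable classification wins (canonical > non_canonical > other).
#'
#' @param duplex a `duplex_structure` from [predict_duplex()].
#' @return A single string: `"canonical"`, `"non_canonical"` or `"other"`.
#' @export
classify_seed <- function(duplex) {
  stopifnot(inherits(duplex, "duplex_structure"))
  cls <- vapply(c(2L, 3L), function(a) {
    s <- seed_window_stats(duplex, a)
    if (s$n_paired == 6L && s$all_wc && s$consecutive) return("canonical")
    if (s$defects <= 1L) return("non_canonical")
    "other"
  }, character(1))
  if ("canonical" %in% cls) return("canonical")
  if ("non_canonical" %in% cls) return("non_canonical")
  "other"
}

# 6-mers of a miRNA at seed windows 2-7 and 3-8.
seed_kmers <- function(mirna) {
  c(substr(mirna, 2L, 7L), substr(mirna, 3L, 8L))
}

#' Generate a synthetic negative interaction
#'
#' Builds a negative counterpart for a positive interaction by shuffling the
#' positive's mature miRNA sequence (uniform random permutation) until the
#' shuffled 6-mers at positions 2-7 and 3-8 match the corresponding 6-mers of
#' no miRNA in the species catalog, then selecting the most favourable target
#' site for the shuffled miRNA within the whole 3'UTR: windows of length
#' `nchar(mirna) + 5` are scanned with step 1 and scored with the duplex
#' scorer; the leftmost window with the maximum score is chosen.
#'
#' @param positive a one-row data.frame (an interaction record) with at least
#'   `interaction_id`, `mirna_id`, `mirna_seq`, `utr_id`.
#' @param mirna_catalog named character vector of the species' real mature
#'   miRNA sequences.
#' @param utr the 3'UTR sequence to scan for the negative's site.
#' @param max_attempts maximum number of shuffles before giving up.
#' @return A one-row data.frame like `positive` with `label = 0`, the shuffled
#'   `mirna_seq`, the selected `site_seq`, its `site_offset` (1-based) and the
#'   duplex `seed_type`.
#' @export
generate_negative <- function(positive, mirna_catalog, utr, max_attempts = 1000L) {
  stopifnot(is.data.frame(positive), nrow(positive) == 1L)
  if (!length(mirna_catalog)) stopf("mirna_catalog is empty")
  mirna <- assert_rna(positive$mirna_seq, "mirna")
  utr <- assert_rna(utr, "utr")
  win_len <- nchar(mirna) + 5L
  if (nchar(utr) < win_len) {
    stopf("utr (%d nt) is shorter than the scan window (%d nt)", nchar(utr), win_len)
  }
  catalog_kmers <- unique(unlist(lapply(mirna_catalog, function(s) {
    s <- toupper(gsub("T", "U", s, fixed = TRUE))
    km <- seed_kmers(s)
    paste0(c("w27:", "w38:"), km)
  })))
  bases <- strsplit(mirna, "")[[1]]
  shuffled <- NULL
  for (attempt in seq_len(max_attempts)) {
    cand <- paste(sample(bases), collapse = "")
    km <- paste0(c("w27:", "w38:"), seed_kmers(cand))
    if (!any(km %in% catalog_kmers)) {
      shuffled <- cand
      break
    }
  }
  if (is.null(shuffled)) {
    stopf("no valid shuffle found for miRNA '%s' after %d attempts",
          positive$mirna_id, max_attempts)
  }
  scorer <- duplex_score_fun()
  offsets <- seq_len(nchar(utr) - win_len + 1L)
  scores <- vapply(offsets, function(o) {
    scorer(shuffled, substr(utr, o, o + win_len - 1L))$score
  }, numeric(1))
  best <- offsets[which.max(scores)] # which.max -> leftmost tie
  site <- substr(utr, best, best + win_len - 1L)
  out <- positive
  out$interaction_id <- paste0(positive$interaction_id, "_neg")
  out$mirna_seq <- shuffled
  out$site_seq <- site
  out$site_offset <- best
  out$seed_type <- classify_seed(scorer(shuffled, site))
  out$label <- 0L
  out
}
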