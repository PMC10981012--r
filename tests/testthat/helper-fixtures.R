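# Shared fixtures and independent oracles for the test suite.

rna_alphabet <- c("A", "C", "G", "U")

random_rna_str <- function(n, alphabet = rna_alphabet) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Independent R enumerator for the duplex score: depth-first search over all
# non-crossing pair chains (miRNA ascending, site descending), scoring pairs
# GC=3/AU=2/GU=1 with affine internal gap costs (open 2, extend 1) per
# strand. Used on very short sequences to validate both the DP and the
# package's C++ enumerator.
r_duplex_oracle <- function(mirna, site) {
  mb <- strsplit(mirna, "")[[1]]
  sb <- strsplit(site, "")[[1]]
  ps <- function(a, b) {
    if ((a == "G" && b == "C") || (a == "C" && b == "G")) return(3)
    if ((a == "A" && b == "U") || (a == "U" && b == "A")) return(2)
    if ((a == "G" && b == "U") || (a == "U" && b == "G")) return(1)
    -1
  }
  gap <- function(k) if (k <= 0) 0 else 2 + (k - 1)
  cand <- list()
  for (i in seq_along(mb)) for (j in seq_along(sb)) {
    s <- ps(mb[i], sb[j])
    if (s > 0) cand[[length(cand) + 1L]] <- c(i, j, s)
  }
  best <- 0
  rec <- function(k, last_i, last_j, acc) {
    for (t in seq_along(cand)) {
      if (t < k) next
      p <- cand[[t]]
      if (last_i > 0 && (p[1] <= last_i || p[2] >= last_j)) next
      add <- p[3]
      if (last_i > 0) add <- add - gap(p[1] - last_i - 1) - gap(last_j - p[2] - 1)
      nacc <- acc + add
      if (nacc > best) best <<- nacc
      rec(t + 1L, p[1], p[2], nacc)
    }
  }
  # sort candidates by miRNA position ascending so suffix recursion is valid
  ord <- order(vapply(cand, `[`, numeric(1), 1L))
  cand <- cand[ord]
  rec(1L, 0L, 0L, 0)
  best
}

# Hand-construct a duplex_structure without running the DP.
make_duplex <- function(mirna_pos, site_pos, type, mirna_len = 22L, site_len = 27L) {
  structure(list(
    pairs = data.frame(mirna_pos = as.integer(mirna_pos),
                       site_pos = as.integer(site_pos),
                       type = type, stringsAsFactors = FALSE),
    score = sum(c(WC = 2.5, GU = 1)[type]),
    mirna_len = mirna_len, site_len = site_len),
    class = "duplex_structure")
}

# Small balanced feature table with explicit miRNA groups.
toy_feature_table <- function(n = 40L, m = 4L, seed = 1L, groups = NULL) {
  set.seed(seed)
  x <- matrix(rnorm(n * m), n, m, dimnames = list(NULL, paste0("f", seq_len(m))))
  y <- rep(c(0L, 1L), length.out = n)
  if (is.null(groups)) groups <- paste0("mir-", rep(seq_len(max(1L, n %/% 4L)), length.out = n))
  feature_table(cbind(
    data.frame(interaction_id = sprintf("i%03d", seq_len(n)), source = "toy",
               mirna_id = groups, label = y, stringsAsFactors = FALSE),
    as.data.frame(x)))
}

# Linearly separable two-feature table.
separable_table <- function(n = 400L, seed = 1L, margin = 0.5) {
  set.seed(seed)
  x1 <- rnorm(n)
  x2 <- rnorm(n)
  y <- as.integer(x1 + x2 > 0)
  x1 <- x1 + ifelse(y == 1L, margin, -margin)
  feature_table(cbind(
    data.frame(interaction_id = sprintf("s%04d", seq_len(n)), source = "sep",
               mirna_id = paste0("mir-", rep(1:20, length.out = n)),
               label = y, stringsAsFactors = FALSE),
    data.frame(f1 = x1, f2 = x2)))
}

# XOR-pattern table (learnable by trees, not by a linear rule).
xor_table <- function(n = 400L, seed = 1L) {
  set.seed(seed)
  x1 <- runif(n, -1, 1)
  x2 <- runif(n, -1, 1)
  y <- as.integer(x1 * x2 > 0)
  feature_table(cbind(
    data.frame(interaction_id = sprintf("x%04d", seq_len(n)), source = "xor",
               mirna_id = paste0("mir-", rep(1:20, length.out = n)),
               label = y, stringsAsFactors = FALSE),
    data.frame(f1 = x1, f2 = x2)))
}

# Two-species feature-mode world with a given shift, used by model and
# harness tests at reduced sizes.
two_species_tables <- function(n = 1000L, n_features = 20L, delta = 0.6,
                               seed = 1L) {
  fn <- paste0("f", seq_len(n_features))
  rule <- make_shift_rule(fn, c("src", "tgt"),
                          list(src = fn[1:3], tgt = fn[4:6]),
                          deltas = delta, seed = seed)
  tabs <- simulate_feature_tables(rule, list(
    species_spec("src", n_mirnas = 40L, shift = delta, rng_seed = seed + 100L),
    species_spec("tgt", n_mirnas = 40L, shift = delta, rng_seed = seed + 200L)),
    n)
  list(rule = rule, tables = tabs)
}

fast_ann_cfg <- function(...) {
  ann_config(layer_widths = c(16L, 8L), dropout_rates = c(0.1, 0),
             epochs = 40L, batch_size = 64L, rng_seed = 11L, ...)
}
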