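test_that("species_spec validates its invariants", {
  expect_error(species_spec("x", n_mirnas = 5, n_positive = 3), "n_positive")
  expect_error(species_spec("x", shift = 1.5), "shift")
  expect_error(species_spec("x", noncanonical_fraction = -0.1), "noncanonical")
  # a UTR too short to hold a site is an impossible spec at generation time
  expect_error(simulate_sequences(species_spec("x", n_mirnas = 1L,
                                               n_positive = 1L,
                                               utr_length_range = c(10L, 20L))),
               "cannot hold")
})

test_that("sequence simulation honors counts, seed classes and determinism", {
  spec <- species_spec("sp", n_mirnas = 4L, n_positive = 15L,
                       noncanonical_fraction = 0, rng_seed = 5L)
  sim <- simulate_sequences(spec)
  expect_equal(nrow(sim$positives), 15L)
  expect_equal(length(sim$mirna_catalog), 4L)
  expect_true(all(nchar(sim$mirna_catalog) >= 20 & nchar(sim$mirna_catalog) <= 24))
  expect_true(all(grepl("^[ACGU]+$", sim$mirna_catalog)))
  # noncanonical_fraction = 0 -> every positive canonical by construction
  expect_true(all(sim$positives$seed_type == "canonical"))
  # positives re-classify from their sequences, never "other"
  recls <- mapply(function(m, s) classify_seed(predict_duplex(m, s)),
                  sim$positives$mirna_seq, sim$positives$site_seq)
  expect_true(all(recls == "canonical"))

  spec_nc <- species_spec("sp", n_mirnas = 4L, n_positive = 30L,
                          noncanonical_fraction = 0.5, rng_seed = 6L)
  sim_nc <- simulate_sequences(spec_nc)
  expect_true(all(sim_nc$positives$seed_type %in% c("canonical", "non_canonical")))
  expect_true(any(sim_nc$positives$seed_type == "non_canonical"))

  # byte-identical FASTA under the same spec and seed
  sim2 <- simulate_sequences(spec)
  f1 <- tempfile(); f2 <- tempfile()
  write_fasta(sim$mirna_catalog, f1)
  write_fasta(sim2$mirna_catalog, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_identical(sim$utrs, sim2$utrs)
})

test_that("sites are embedded at the recorded UTR offsets", {
  sim <- simulate_sequences(species_spec("sp", n_mirnas = 3L, n_positive = 8L,
                                         rng_seed = 9L))
  for (i in seq_len(nrow(sim$positives))) {
    p <- sim$positives[i, ]
    expect_identical(substr(sim$utrs[[p$utr_id]], p$site_offset,
                            p$site_offset + nchar(p$site_seq) - 1L),
                     p$site_seq)
  }
})

test_that("feature-mode tables are balanced, schema-aligned and seeded", {
  w <- two_species_tables(n = 200L, seed = 3L)
  tab <- w$tables$src
  expect_s3_class(tab, "feature_table")
  expect_equal(nrow(tab), 200L)
  expect_equal(sum(tab$label == 1L), 100L)
  expect_identical(feature_names(w$tables$src), feature_names(w$tables$tgt))
  # determinism
  w2 <- two_species_tables(n = 200L, seed = 3L)
  expect_identical(as.data.frame(w$tables$src), as.data.frame(w2$tables$src))
  # singletons occur when miRNAs are plentiful relative to interactions
  many <- simulate_feature_tables(w$rule, list(
    species_spec("src", n_mirnas = 150L, n_positive = 200L, rng_seed = 77L)),
    200L)$src
  expect_true(any(table(many$mirna_id) == 1L))
  expect_error(simulate_feature_tables(w$rule, list(species_spec("unknown")), 100),
               "missing from rule")
  expect_error(simulate_feature_tables(w$rule, list(species_spec("src")), 101),
               "even")
})

test_that("features outside the shifted subset keep identical marginals", {
  fn <- paste0("f", 1:10)
  rule <- make_shift_rule(fn, c("a", "b"), list(a = c("f1", "f2"), b = character(0)),
                          deltas = c(0.8, 0), seed = 2)
  tabs <- simulate_feature_tables(rule, list(
    species_spec("a", shift = 0.8, rng_seed = 21L),
    species_spec("b", shift = 0, rng_seed = 22L)), 2000L)
  pvals <- vapply(paste0("f", 3:10), function(f) {
    suppressWarnings(stats::ks.test(as.data.frame(tabs$a)[[f]],
                                    as.data.frame(tabs$b)[[f]]))$p.value
  }, numeric(1))
  # identical generative marginals: with 8 independent tests at alpha = 0.01
  # allow at most the one false positive expected under the null
  expect_lte(sum(pvals <= 0.01), 1L)
  expect_gt(mean(pvals > 0.01), 0.85)
  # and the shifted features do diverge (dispersion shift)
  ks1 <- suppressWarnings(stats::ks.test(as.data.frame(tabs$a)[["f1"]],
                                         as.data.frame(tabs$b)[["f1"]]))
  expect_lt(ks1$p.value, 0.05)
  expect_setequal(shifted_features(rule), c("f1", "f2"))
})

test_that("a logistic fit recovers the signs of the generating weights", {
  fn <- paste0("f", 1:20)
  set.seed(8)
  w <- stats::setNames(sample(c(-1, 1), 20, TRUE) * runif(20, 0.3, 1.2), fn)
  rule <- ground_truth_rule(w, list(sp = stats::setNames(rep(0, 20), fn)))
  tab <- simulate_feature_tables(rule, list(species_spec("sp", rng_seed = 4L)),
                                 5000L)$sp
  fit <- stats::glm(label ~ . - 1,
                    data = cbind(label = tab$label,
                                 as.data.frame(tab)[, fn]),
                    family = stats::binomial())
  agree <- mean(sign(stats::coef(fit)[fn]) == sign(w))
  expect_gte(agree, 0.95)
})

test_that("pooled and per-species training are equivalent when delta is 0", {
  fn <- paste0("f", 1:10)
  rule <- make_shift_rule(fn, c("a", "b"), list(a = "f1", b = "f1"), deltas = 0)
  accs_pool <- c(); accs_single <- c()
  for (sd in 1:6) {
    tabs <- simulate_feature_tables(rule, list(
      species_spec("a", n_mirnas = 30L, rng_seed = 500L + sd),
      species_spec("b", n_mirnas = 30L, rng_seed = 600L + sd)), 600L)
    pooled <- merge_species(tabs, "pooled")
    sp <- split_spec(n_repeats = 1L, rng_seed = sd)
    r_pool <- run_intra(pooled, sp, "xgb", list(nrounds = 40L))
    r_a <- run_intra(tabs$a, sp, "xgb", list(nrounds = 40L))
    accs_pool <- c(accs_pool, mean(r_pool$ACC))
    accs_single <- c(accs_single, mean(r_a$ACC))
  }
  # no detectable difference between pooled and per-species training
  expect_gt(stats::t.test(accs_pool, accs_single, paired = TRUE)$p.value, 0.05)
})

test_that("table_from_sequences validates references and balance", {
  ds <- suppressWarnings(simulate_species_dataset(
    species_spec("sq", n_mirnas = 3L, n_positive = 6L, rng_seed = 12L)))
  expect_equal(sum(ds$table$label == 1L), sum(ds$table$label == 0L))
  expect_error(table_from_sequences(ds$mirna_catalog, ds$utrs, ds$positives, NULL),
               "balanced")
  bad <- ds$positives
  bad$mirna_id[1] <- "mir-unknown"
  expect_error(table_from_sequences(ds$mirna_catalog, ds$utrs, bad, ds$negatives),
               "unknown miRNAs")
  bad2 <- ds$positives
  bad2$utr_id[2] <- "utr-missing"
  expect_error(table_from_sequences(ds$mirna_catalog, ds$utrs, bad2, ds$negatives),
               "unknown UTRs")
  # permuting record order changes row order only
  perm <- sample(nrow(ds$positives))
  t1 <- table_from_sequences(ds$mirna_catalog, ds$utrs, ds$positives, ds$negatives)
  t2 <- table_from_sequences(ds$mirna_catalog, ds$utrs,
                             ds$positives[perm, ], ds$negatives)
  d1 <- as.data.frame(t1); d2 <- as.data.frame(t2)
  expect_setequal(d1$interaction_id, d2$interaction_id)
  d2 <- d2[match(d1$interaction_id, d2$interaction_id), ]
  rownames(d2) <- NULL
  expect_equal(d1, d2)
})

test_that("dataset round-trips through disk including the JSON sidecar", {
  spec <- species_spec("io", n_mirnas = 3L, n_positive = 6L, rng_seed = 13L)
  ds <- suppressWarnings(simulate_species_dataset(spec))
  dir <- tempfile()
  write_species_dataset(ds, dir, spec)
  expect_true(all(file.exists(file.path(dir, c("mirnas.fa", "utrs.fa",
                                               "interactions.tsv", "dataset.json")))))
  back <- read_feature_table(file.path(dir, "interactions.tsv"))
  expect_equal(nrow(back), nrow(ds$table))
  expect_identical(feature_names(back), feature_names(ds$table))
  fa <- read_fasta(file.path(dir, "mirnas.fa"))
  expect_identical(fa, ds$mirna_catalog)
  side <- jsonlite::read_json(file.path(dir, "dataset.json"))
  expect_equal(side$spec$name, "io")
  expect_equal(side$spec$rng_seed, 13L)
})
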