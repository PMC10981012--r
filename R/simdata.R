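# Synthetic multi-species MTI data. Two generation modes feed the same
# feature_table type:
#   * sequence mode — miRNA catalogs, 3'UTRs and embedded target sites, so
#     the duplex / seed / negative-generation code paths are exercised;
#   * feature mode — tabular features drawn around a known logistic ground
#     truth with a per-species weight shift, so transfer and TransferSHAP
#     behaviour can be checked against planted structure.
# The shift parameter (delta, in [0,1]) is a stand-in for evolutionary
# distance: 0 means identical interaction rules, 1 a strongly diverged rule.

#' Specify a synthetic species
#'
#' @param name species identifier.
#' @param n_mirnas number of distinct miRNAs in the catalog.
#' @param n_positive number of positive interactions to generate.
#' @param utr_length_range min/max 3'UTR length in nucleotides.
#' @param shift domain-shift magnitude delta in `[0, 1]`.
#' @param noncanonical_fraction fraction of positives built with a
#'   non-canonical (GU / single-defect) seed.
#' @param rng_seed integer seed; identical specs with identical seeds give
#'   byte-identical output.
#' @return An object of class `species_spec`.
#' @export
species_spec <- function(name, n_mirnas = 20L, n_positive = 100L,
                         utr_length_range = c(80L, 200L), shift = 0,
                         noncanonical_fraction = 0.2, rng_seed = 1L) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  n_mirnas <- as.integer(n_mirnas)
  n_positive <- as.integer(n_positive)
  if (n_mirnas < 1L || n_positive < n_mirnas) {
    stopf("need n_positive >= n_mirnas >= 1 (got %d, %d)", n_positive, n_mirnas)
  }
  if (shift < 0 || shift > 1) stopf("shift must be in [0, 1]")
  if (noncanonical_fraction < 0 || noncanonical_fraction > 1) {
    stopf("noncanonical_fraction must be in [0, 1]")
  }
  stopifnot(length(utr_length_range) == 2L, utr_length_range[1] <= utr_length_range[2])
  structure(list(name = name, n_mirnas = n_mirnas, n_positive = n_positive,
                 utr_length_range = as.integer(utr_length_range), shift = shift,
                 noncanonical_fraction = noncanonical_fraction,
                 rng_seed = as.integer(rng_seed)),
            class = "species_spec")
}

random_rna <- function(n, probs = c(A = 0.25, C = 0.25, G = 0.25, U = 0.25)) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

# Allocate n_positive interactions over n_mirnas miRNAs with geometric-ish
# multiplicities so that singleton miRNAs occur naturally (the real
# multiplicity distribution is unknown; this is a stand-in).
allocate_multiplicities <- function(n_mirnas, n_positive) {
  sizes <- 1L + rgeom(n_mirnas, prob = 0.35)
  while (sum(sizes) < n_positive) {
    i <- sample.int(n_mirnas, 1L)
    sizes[i] <- sizes[i] + 1L
  }
  while (sum(sizes) > n_positive) {
    eligible <- which(sizes > 1L)
    i <- if (length(eligible) > 1L) sample(eligible, 1L) else eligible
    sizes[i] <- sizes[i] - 1L
  }
  sizes
}

# Build a target site for a miRNA: random flank (5' side of the site) plus
# the reverse complement of miRNA positions 1..9, so seed windows 2-7 and
# 3-8 pair canonically. Non-canonical sites perturb one window position with
# a GU wobble (when possible) or a mismatch.
build_site <- function(mirna, noncanonical, flank_probs) {
  len <- nchar(mirna) + 5L
  seed_part <- rna_revcomp(substr(mirna, 1L, 9L))
  if (noncanonical) {
    p <- sample(3:7, 1L) # inside both seed windows
    site_idx <- 10L - p  # position within seed_part pairing miRNA position p
    mb <- substr(mirna, p, p)
    repl <- switch(mb,
      G = "U", U = "G",              # GU wobble
      A = sample(c("C", "G"), 1L),   # mismatch (A pairs only U)
      C = sample(c("A", "C", "U"), 1L)) # mismatch (C pairs only G)
    substr(seed_part, site_idx, site_idx) <- repl
  }
  flank <- random_rna(len - nchar(seed_part), flank_probs)
  paste0(flank, seed_part)
}

#' Simulate sequence-level data for one species
#'
#' Generates a miRNA catalog (20-24 nt, A/C/G/U), one 3'UTR per positive
#' interaction, and positive interaction records whose embedded target sites
#' classify as canonical (with probability `1 - noncanonical_fraction`) or
#' non-canonical seeds under [classify_seed()], never as "other". The shift
#' parameter perturbs the effective non-canonical fraction, site GC content
#' and flank AU content, mimicking divergence of targeting rules with one
#' knob.
#'
#' @param spec a [species_spec()].
#' @return A list with `mirna_catalog` and `utrs` (named character vectors)
#'   and `positives` (a data.frame of interaction records).
#' @export
simulate_sequences <- function(spec) {
  stopifnot(inherits(spec, "species_spec"))
  min_site <- 24L + 5L
  if (spec$utr_length_range[1] < min_site) {
    stopf("utr_length_range minimum %d cannot hold a site of up to %d nt",
          spec$utr_length_range[1], min_site)
  }
  with_local_seed(spec$rng_seed, {
    nc_frac <- min(1, spec$noncanonical_fraction * (1 + 0.5 * spec$shift))
    gc_site <- 0.5 + 0.15 * spec$shift     # site/flank GC drifts with shift
    flank_probs <- c(A = (1 - gc_site) / 2, C = gc_site / 2,
                     G = gc_site / 2, U = (1 - gc_site) / 2)
    utr_au <- 0.5 + 0.2 * spec$shift       # UTR background AU drifts too
    utr_probs <- c(A = utr_au / 2, C = (1 - utr_au) / 2,
                   G = (1 - utr_au) / 2, U = utr_au / 2)
    mirnas <- vapply(seq_len(spec$n_mirnas), function(i) {
      random_rna(sample(20:24, 1L))
    }, character(1))
    names(mirnas) <- sprintf("%s-mir-%03d", spec$name, seq_len(spec$n_mirnas))
    sizes <- allocate_multiplicities(spec$n_mirnas, spec$n_positive)
    mirna_of <- rep(names(mirnas), times = sizes)
    utrs <- character(spec$n_positive)
    recs <- vector("list", spec$n_positive)
    for (i in seq_len(spec$n_positive)) {
      mid <- mirna_of[i]
      mseq <- mirnas[[mid]]
      utr_len <- sample(spec$utr_length_range[1]:spec$utr_length_range[2], 1L)
      noncanonical <- runif(1) < nc_frac
      want <- if (noncanonical) "non_canonical" else "canonical"
      st <- "other"
      for (try in 1:40) {
        site <- build_site(mseq, noncanonical, flank_probs)
        st <- classify_seed(predict_duplex(mseq, site))
        if (st == want) break
      }
      if (st != want) stopf("failed to construct a %s site for %s", want, mid)
      offset <- sample.int(utr_len - nchar(site) + 1L, 1L)
      utr <- random_rna(utr_len, utr_probs)
      substr(utr, offset, offset + nchar(site) - 1L) <- site
      utrs[i] <- utr
      recs[[i]] <- data.frame(
        interaction_id = sprintf("%s_int_%04d", spec$name, i),
        source = spec$name,
        mirna_id = mid, mirna_seq = mseq,
        utr_id = sprintf("%s_utr_%04d", spec$name, i),
        site_seq = site, site_offset = offset, utr_length = utr_len,
        seed_type = st, label = 1L, stringsAsFactors = FALSE
      )
    }
    names(utrs) <- sprintf("%s_utr_%04d", spec$name, seq_len(spec$n_positive))
    list(mirna_catalog = mirnas, utrs = utrs,
         positives = do.call(rbind, recs))
  })
}

#' Ground-truth rule for feature-mode simulation
#'
#' A logistic labelling rule shared across species, plus per-species additive
#' weight shifts on a declared subset of features. The shifted subset is
#' recorded and queryable via [shifted_features()], which parameter-recovery
#' experiments rely on.
#'
#' @param base_weights named numeric vector of shared logistic weights.
#' @param species_deltas named list (one element per species) of named
#'   numeric vectors of weight shifts; names must be a subset of
#'   `names(base_weights)`.
#' @param intercept scalar intercept.
#' @export
ground_truth_rule <- function(base_weights, species_deltas = list(), intercept = 0) {
  stopifnot(!is.null(names(base_weights)), all(nzchar(names(base_weights))))
  for (s in names(species_deltas)) {
    bad <- setdiff(names(species_deltas[[s]]), names(base_weights))
    if (length(bad)) {
      stopf("species '%s' shifts unknown features: %s", s, paste(bad, collapse = ", "))
    }
  }
  structure(list(base_weights = base_weights, species_deltas = species_deltas,
                 intercept = intercept),
            class = "ground_truth_rule")
}

#' @rdname ground_truth_rule
#' @param rule a `ground_truth_rule`.
#' @param species optional species name; when given, only that species'
#'   shifted features are returned.
#' @export
shifted_features <- function(rule, species = NULL) {
  stopifnot(inherits(rule, "ground_truth_rule"))
  deltas <- if (is.null(species)) rule$species_deltas else rule$species_deltas[species]
  sort(unique(unlist(lapply(deltas, function(d) names(d)[d != 0]))))
}

#' Convenience constructor for a shifted multi-species rule
#'
#' Draws shared base weights and, for each species, an additive shift of
#' magnitude `delta * delta_scale` (random sign per feature and species) on
#' that species' shifted feature subset.
#'
#' @param feature_names all feature names.
#' @param species character vector of species names.
#' @param shift_features either a character vector (same shifted subset for
#'   all species) or a named list of per-species subsets.
#' @param deltas numeric vector (recycled) of per-species shift magnitudes in
#'   `[0, 1]`.
#' @param seed RNG seed.
#' @param base_sd standard deviation of the shared weights.
#' @param delta_scale weight-shift per unit delta.
#' @export
make_shift_rule <- function(feature_names, species, shift_features,
                            deltas, seed = 1L, base_sd = 0.7, delta_scale = 0.5) {
  deltas <- rep_len(deltas, length(species))
  if (!is.list(shift_features)) {
    shift_features <- stats::setNames(
      rep(list(shift_features), length(species)), species)
  }
  with_local_seed(seed, {
    base <- stats::setNames(rnorm(length(feature_names), 0, base_sd), feature_names)
    sd_list <- stats::setNames(vector("list", length(species)), species)
    for (k in seq_along(species)) {
      sf <- shift_features[[species[k]]]
      stopifnot(all(sf %in% feature_names))
      d <- stats::setNames(rep(0, length(feature_names)), feature_names)
      # graded effect sizes: features within a species' shifted subset are
      # affected to visibly different degrees, as real rule divergence would
      d[sf] <- deltas[k] * delta_scale * sample(c(-1, 1), length(sf), replace = TRUE) *
        runif(length(sf), 0.4, 1.6)
      sd_list[[species[k]]] <- d
    }
    ground_truth_rule(base, sd_list, intercept = 0)
  })
}

#' Simulate feature-level tables for several species
#'
#' Draws standard-normal features, labels each observation
#' `Bernoulli(sigmoid(intercept + (w_base + delta_s) . x))`, and resamples to
#' an exact 1:1 label balance. The species' `shift` knob also acts on the
#' covariates: features in the species' shifted subset are spread out by a
#' factor `1 + 1.5 * shift` (common mean), emulating that diverged species
#' differ in their feature distributions and not only in their targeting
#' rules. Features outside the shifted subset keep identical marginal
#' distributions across species.
#' miRNA group ids with geometric group sizes are attached so that
#' group-stratified splitting is exercised (singletons included).
#'
#' @param rule a [ground_truth_rule()].
#' @param specs list of [species_spec()]; every species name must appear in
#'   `rule$species_deltas`.
#' @param n_per_species rows per species table (must be even).
#' @return Named list of `feature_table`s, one per species.
#' @export
simulate_feature_tables <- function(rule, specs, n_per_species = 1000L) {
  stopifnot(inherits(rule, "ground_truth_rule"))
  n_per_species <- as.integer(n_per_species)
  if (n_per_species %% 2L != 0L) stopf("n_per_species must be even for 1:1 balance")
  fn <- names(rule$base_weights)
  out <- list()
  for (spec in specs) {
    stopifnot(inherits(spec, "species_spec"))
    if (!spec$name %in% names(rule$species_deltas)) {
      stopf("species '%s' missing from rule$species_deltas", spec$name)
    }
    delta <- rule$species_deltas[[spec$name]]
    w <- rule$base_weights
    w[names(delta)] <- w[names(delta)] + delta
    out[[spec$name]] <- with_local_seed(spec$rng_seed, {
      n_draw <- 4L * n_per_species
      x <- matrix(rnorm(n_draw * length(fn)), n_draw, length(fn),
                  dimnames = list(NULL, fn))
      s_shift <- names(delta)[delta != 0]
      if (length(s_shift) && spec$shift > 0) {
        # dispersion shift: the affected features spread out while keeping a
        # common mean, so species domains overlap but the shifted rule
        # matters most where the target's mass is
        x[, s_shift] <- x[, s_shift, drop = FALSE] * (1 + 1.5 * spec$shift)
      }
      p <- plogis(rule$intercept + drop(x %*% w))
      y <- rbinom(n_draw, 1L, p)
      half <- n_per_species %/% 2L
      pick <- function(lab) {
        idx <- which(y == lab)
        if (length(idx) >= half) sample(idx, half)
        else sample(idx, half, replace = TRUE)
      }
      idx <- c(pick(1L), pick(0L))
      idx <- sample(idx) # interleave classes
      gsz <- allocate_multiplicities(max(1L, spec$n_mirnas), n_per_species)
      mirna_id <- rep(sprintf("%s-mir-%03d", spec$name, seq_along(gsz)), times = gsz)
      df <- data.frame(
        interaction_id = sprintf("%s_f_%05d", spec$name, seq_len(n_per_species)),
        source = spec$name,
        mirna_id = mirna_id,
        label = y[idx], stringsAsFactors = FALSE
      )
      ft <- feature_table(cbind(df, as.data.frame(x[idx, , drop = FALSE])))
      attr(ft, "species") <- spec$name
      ft
    })
  }
  out
}

#' Assemble a feature table from sequence-level records
#'
#' Validates that every record references an existing miRNA and UTR, joins
#' positives and negatives, and extracts the full feature schema per row.
#'
#' @param mirna_catalog named character vector of miRNA sequences.
#' @param utrs named character vector of 3'UTR sequences.
#' @param positives,negatives data.frames of interaction records (labels 1
#'   and 0 respectively); `negatives` must be non-empty so the emitted table
#'   can be balanced.
#' @return A `feature_table`.
#' @export
table_from_sequences <- function(mirna_catalog, utrs, positives, negatives) {
  if (is.null(negatives) || nrow(negatives) == 0L) {
    stopf("negatives are required: emitted datasets must be label-balanced")
  }
  recs <- rbind(positives, negatives)
  dangling_mir <- setdiff(unique(positives$mirna_id), names(mirna_catalog))
  if (length(dangling_mir)) {
    stopf("records reference unknown miRNAs: %s", paste(dangling_mir, collapse = ", "))
  }
  dangling_utr <- setdiff(unique(recs$utr_id), names(utrs))
  if (length(dangling_utr)) {
    bad <- recs$interaction_id[recs$utr_id %in% dangling_utr]
    stopf("records reference unknown UTRs (e.g. record %s)", bad[1])
  }
  extract_table(recs)
}

#' Simulate a complete sequence-mode species dataset
#'
#' Runs [simulate_sequences()], generates one negative per positive with
#' [generate_negative()] (pairs whose miRNA cannot be validly shuffled are
#' dropped with a warning, together with their positive, to keep balance),
#' and assembles the feature table.
#'
#' @inheritParams simulate_sequences
#' @param max_attempts shuffle budget per negative.
#' @return List with `table` (a `feature_table`), `mirna_catalog`, `utrs`,
#'   `positives`, `negatives`.
#' @export
simulate_species_dataset <- function(spec, max_attempts = 1000L) {
  sim <- simulate_sequences(spec)
  with_local_seed(child_seed(spec$rng_seed, 7L), {
    negs <- list()
    keep <- logical(nrow(sim$positives))
    for (i in seq_len(nrow(sim$positives))) {
      pos <- sim$positives[i, , drop = FALSE]
      res <- tryCatch(
        generate_negative(pos, sim$mirna_catalog, sim$utrs[[pos$utr_id]],
                          max_attempts = max_attempts),
        error = function(e) e)
      if (inherits(res, "error")) {
        warning(sprintf("dropping pair %s: %s", pos$interaction_id,
                        conditionMessage(res)), call. = FALSE)
        keep[i] <- FALSE
      } else {
        negs[[length(negs) + 1L]] <- res
        keep[i] <- TRUE
      }
    }
    positives <- sim$positives[keep, , drop = FALSE]
    negatives <- do.call(rbind, negs)
    tab <- table_from_sequences(sim$mirna_catalog, sim$utrs, positives, negatives)
    attr(tab, "species") <- spec$name
    list(table = tab, mirna_catalog = sim$mirna_catalog, utrs = sim$utrs,
         positives = positives, negatives = negatives)
  })
}

#' Write a simulated dataset to disk
#'
#' FASTA for the miRNA catalog and UTRs, TSV for the feature table, and a
#' JSON sidecar recording the generating spec (including the shifted feature
#' subset when a rule is supplied) for test introspection.
#'
#' @param dataset result of [simulate_species_dataset()].
#' @param dir output directory (created if needed).
#' @param spec the generating [species_spec()].
#' @param rule optional [ground_truth_rule()].
#' @export
write_species_dataset <- function(dataset, dir, spec, rule = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(dataset$mirna_catalog, file.path(dir, "mirnas.fa"))
  write_fasta(dataset$utrs, file.path(dir, "utrs.fa"))
  write_feature_table(dataset$table, file.path(dir, "interactions.tsv"))
  sidecar <- list(spec = unclass(spec))
  if (!is.null(rule)) {
    sidecar$rule <- list(base_weights = as.list(rule$base_weights),
                         species_deltas = lapply(rule$species_deltas, as.list),
                         intercept = rule$intercept,
                         shifted_features = shifted_features(rule))
  }
  jsonlite::write_json(sidecar, file.path(dir, "dataset.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
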