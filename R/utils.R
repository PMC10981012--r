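# Internal helpers shared across modules.

# Evaluate `expr` with the global RNG temporarily seeded to `seed`, restoring
# the caller's RNG state afterwards so no function leaks global state.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

# Derive a reproducible child seed from a base seed and a stream index,
# kept within the 32-bit integer range.
child_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + stream * 1299721) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

assert_rna <- function(seq, what = "sequence") {
  if (length(seq) != 1L || !nzchar(seq)) {
    stopf("%s must be a single non-empty string", what)
  }
  seq <- toupper(seq)
  if (grepl("T", seq, fixed = TRUE)) {
    warning(sprintf("%s contains T; converting to U", what), call. = FALSE)
    seq <- gsub("T", "U", seq, fixed = TRUE)
  }
  bad <- setdiff(unique(strsplit(seq, "")[[1]]), c("A", "C", "G", "U"))
  if (length(bad)) {
    stopf("%s contains invalid characters: %s", what, paste(bad, collapse = ", "))
  }
  seq
}

# Watson-Crick (antiparallel) complement of an RNA string, 5'->3'.
rna_revcomp <- function(seq) {
  comp <- c(A = "U", U = "A", G = "C", C = "G")
  paste(rev(comp[strsplit(seq, "")[[1]]]), collapse = "")
}
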