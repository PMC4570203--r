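# Independent oracles and shared fixtures.

# Naive affine-gap global alignment, plain-R Gotoh written independently of
# the compiled engine (same convention: a gap of length L costs
# open + L * extend, end gaps penalised). Score only.
naive_global_score <- function(a, b, mat, open = 8, extend = 2) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  M <- matrix(-Inf, n + 1, m + 1)
  X <- matrix(-Inf, n + 1, m + 1)
  Y <- matrix(-Inf, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(open + i * extend)
  for (j in seq_len(m)) Y[1, j + 1] <- -(open + j * extend)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + mat[ca[i], cb[j]]
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - extend,
                             Y[i, j + 1] - open - extend,
                             X[i, j + 1] - extend)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - extend,
                             X[i + 1, j] - open - extend,
                             Y[i + 1, j] - extend)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Exhaustive isolated-cell scan over a fraction matrix (NA = empty).
brute_isolated <- function(frac) {
  filled <- !is.na(frac)
  out <- list()
  for (i in seq_len(nrow(frac))) {
    for (j in seq_len(ncol(frac))) {
      if (!filled[i, j]) next
      if (sum(filled[i, ]) == 1 && sum(filled[, j]) == 1) {
        out[[length(out) + 1]] <- c(i, j)
      }
    }
  }
  out
}

random_aa <- function(n, alphabet = c("A","R","N","D","C","Q","E","G","H","I",
                                      "L","K","M","F","P","S","T","W","Y","V")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Default synthetic bundle, generated once per test run.
.fixture_cache <- new.env(parent = emptyenv())
default_bundle <- function() {
  if (is.null(.fixture_cache$bundle)) {
    .fixture_cache$bundle <- generate_fixture(fixture_spec(seed = 101))
  }
  .fixture_cache$bundle
}

# Manifest-derived oracle for the missing-representative list: orphan
# sequences in kept classes, one per four-level prefix (longest, then
# smallest id). Recomputed with plain R, independent of package internals.
oracle_missing <- function(bundle, classes = c(1:5, 8)) {
  man <- bundle$manifest$sequences
  cls <- as.integer(sub("\\..*", "", man$tc))
  orf <- man[man$orphan & cls %in% classes, , drop = FALSE]
  if (!nrow(orf)) return(character(0))
  pfx <- vapply(strsplit(orf$tc, ".", fixed = TRUE),
                function(t) paste(t[1:4], collapse = "."), character(1))
  reps <- vapply(split(orf$seq_id, pfx), function(ids) {
    len <- nchar(bundle$seqs[ids])
    ids <- ids[len == max(len)]
    sort(ids)[1]
  }, character(1))
  unname(reps)
}
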