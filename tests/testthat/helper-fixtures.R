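# Fixtures are generated once per test run and memoised here; every test
# consumes the same deterministic objects.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Desk-scale octoploid fixture: 48 chromosomes of ~20 kb base length with
# subgenome-structured repeats and 8 planted markers.
fix_small <- function() {
  memo("small", function() {
    simulate_tully(seed = 101, base_length = 2e4, n_markers = 8)
  })
}

# Full default fixture (100 kb base chromosomes), for the heavier
# end-to-end checks.
fix_full <- function() {
  memo("full", function() {
    simulate_tully(seed = 42, base_length = 1e5)
  })
}

# chromosome -> subgenome truth map of a polyploid, as a tibble
truth_map <- function(polyploid) {
  tr <- polyploid$truth$chromosomes
  tibble::tibble(chromosome = tr$chromosome, subgenome = tr$ancestry)
}

# Adjusted Rand index between an assignment and the generator truth
ari_vs_truth <- function(assignment, polyploid) {
  lab <- tidy(assignment)
  tr <- polyploid$truth$chromosomes
  mclust::adjustedRandIndex(
    lab$subgenome, tr$ancestry[match(lab$chromosome, tr$chromosome)])
}

# Naive canonical k-mer counter (independent oracle for count_kmers):
# plain string scanning, no rolling encoding.
naive_kmer_counts <- function(seq, k) {
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  n <- nchar(seq) - k + 1
  out <- new.env(parent = emptyenv())
  for (i in seq_len(max(n, 0))) {
    w <- toupper(substr(seq, i, i + k - 1))
    if (grepl("[^ACGT]", w)) next
    canon <- min(w, rc(w))
    out[[canon]] <- (out[[canon]] %||% 0) + 1
  }
  as.list(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Build a kmer_matrix by hand (for unit tests of the differential rule)
manual_kmer_matrix <- function(mat, k = 15) {
  structure(list(counts = Matrix::Matrix(mat, sparse = TRUE),
                 k = k,
                 lengths = setNames(rep(1e6, nrow(mat)), rownames(mat))),
            class = "kmer_matrix")
}
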