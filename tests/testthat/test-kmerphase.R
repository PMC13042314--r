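test_that("count_kmers agrees with a naive scanner and canonicalises", {
  set.seed(77)
  seqs <- c(s1 = polyphase:::random_dna(2000),
            s2 = polyphase:::random_dna(1500))
  for (k in c(11, 15)) {
    km <- count_kmers(seqs, k)
    for (nm in names(seqs)) {
      oracle <- naive_kmer_counts(seqs[[nm]], k)
      row <- km$counts[nm, ]
      row <- row[row > 0] * nchar(seqs[[nm]]) / 1e6  # back to raw counts
      names(row) <- decode_kmers(names(row), k)
      expect_equal(length(row), length(oracle))
      expect_equal(row[sort(names(row))],
                   unlist(oracle)[sort(names(oracle))],
                   tolerance = 1e-9, ignore_attr = TRUE)
    }
  }
  # raw window count is L - k + 1
  km3 <- count_kmers(c(s = "ACGTACGT"), k = 3)
  expect_equal(sum(km3$counts) * 8 / 1e6, 6)
  # a sequence and its reverse complement give identical rows
  rc <- polyphase:::revcomp(seqs[["s1"]])
  km2 <- count_kmers(c(a = seqs[["s1"]], b = rc), k = 15)
  expect_equal(km2$counts["a", ], km2$counts["b", ])
  # row sums scale with length (no ambiguous bases here)
  kmN <- count_kmers(seqs, 15)
  raw <- Matrix::rowSums(kmN$counts) * nchar(seqs) / 1e6
  expect_equal(unname(raw), unname(nchar(seqs) - 15 + 1))
  expect_error(count_kmers(seqs, 14), "odd")
  expect_error(count_kmers(character(0)), "non-empty")
})

test_that("differential k-mer rule follows the fold and floor thresholds", {
  mat <- rbind(
    a1 = c(10, 5, 0, 1),
    a2 = c(12, 5, 0, 1),
    c1 = c(0, 5, 9, 1),
    c2 = c(0, 5, 11, 1))
  colnames(mat) <- sprintf("km%d", 1:4)
  km <- manual_kmer_matrix(mat)
  groups <- c(a1 = "A", a2 = "A", c1 = "C", c2 = "C")
  d <- find_differential_kmers(km, groups, fold_q = 2, min_count = 2)
  # km1 private to A, km3 private to C; km2 equal means; km4 below floor
  expect_setequal(d$kmer, c("km1", "km3"))
  expect_equal(d$label[d$kmer == "km1"], "A")
  expect_equal(d$label[d$kmer == "km3"], "C")
  expect_true(all(is.infinite(d$score)))
  expect_error(find_differential_kmers(km, groups, fold_q = 1), "fold_q")
  expect_error(find_differential_kmers(km, c(a1 = "A", a2 = "A",
                                             c1 = "A", c2 = "A")),
               "clusters")
})

test_that("every C chromosome carries C-labelled differential k-mers", {
  fx <- fix_small()
  pp <- fx$polyploid
  km <- count_kmers(pp$seqs, 15)
  truth <- truth_map(pp)
  d <- find_differential_kmers(km, setNames(truth$subgenome,
                                            truth$chromosome))
  ckmers <- d$kmer[d$label == "C"]
  expect_gt(length(ckmers), 0)
  sub <- km$counts[truth$chromosome[truth$subgenome == "C"], ckmers]
  expect_true(all(Matrix::rowSums(sub > 0) >= 1))
})

test_that("phasing recovers the true ancestry partition on the fixture", {
  fx <- fix_small()
  km <- count_kmers(fx$polyploid$seqs, 15)
  asg <- phase_subgenomes(km, K = 3, seed = 7)
  expect_equal(ari_vs_truth(asg, fx$polyploid), 1)
  expect_true(asg$converged)
  # deterministic under a fixed seed
  asg2 <- phase_subgenomes(km, K = 3, seed = 7)
  expect_identical(tidy(asg), tidy(asg2))
  # partition is invariant to chromosome input order
  perm <- sample(length(fx$polyploid$seqs))
  km_p <- count_kmers(fx$polyploid$seqs[perm], 15)
  asg_p <- phase_subgenomes(km_p, K = 3, seed = 7)
  l1 <- tidy(asg); l2 <- tidy(asg_p)
  expect_equal(mclust::adjustedRandIndex(
    l1$subgenome, l2$subgenome[match(l1$chromosome, l2$chromosome)]), 1)
})

test_that("K = 2 separates A from B on a C-free hexaploid", {
  fx <- fix_small()
  hex <- compose_polyploid(fx$genomes, aabbbb_spec(), seed = 55)
  asg <- phase_subgenomes(count_kmers(hex$seqs, 15), K = 2, seed = 7)
  expect_equal(ari_vs_truth(asg, hex), 1)
})

test_that("phasing accuracy degrades as A-B divergence approaches the
          haplotype level", {
  ari_at <- function(d_ab) {
    m <- ancestry_model(3, 1e4,
                        divergence = c(AB = d_ab, AC = 0.12, BC = 0.12),
                        seed = 61)
    g <- simulate_ancestral_genomes(m)
    ir <- insert_repeats(g, default_repeat_families(), seed = 62)
    spec <- polyploid_spec(tibble::tibble(
      base = rep(1:3, each = 2), ancestry = rep(c("A", "B"), 3),
      copies = rep(c(2L, 4L), 3)))
    pp <- compose_polyploid(ir$genomes, spec, seed = 63,
                            insertions = ir$insertions)
    asg <- phase_subgenomes(count_kmers(pp$seqs, 15), K = 2, seed = 7)
    ari_vs_truth(asg, pp)
  }
  aris <- vapply(c(0.03, 0.012, 0.005), ari_at, 0)
  expect_equal(aris[1], 1)
  expect_true(all(diff(aris) <= 1e-9))  # monotone non-increasing
  expect_lt(aris[3], 1)                 # indistinguishable at hap level
})

test_that("identical chromosomes share a label at zero dendrogram height", {
  set.seed(91)
  s1 <- polyphase:::random_dna(5000)
  s2 <- polyphase:::random_dna(5000)
  seqs <- c(x1 = s1, x2 = s1, y1 = s2, y2 = s2)
  asg <- phase_subgenomes(count_kmers(seqs, 15), K = 2, seed = 3)
  lab <- tidy(asg)
  expect_equal(lab$subgenome[lab$chromosome == "x1"],
               lab$subgenome[lab$chromosome == "x2"])
  coph <- as.matrix(stats::cophenetic(asg$dendrogram))
  expect_equal(coph["x1", "x2"], 0)
})

test_that("an empty differential set is rejected with advice", {
  set.seed(92)
  s <- polyphase:::random_dna(3000)
  seqs <- c(a = s,
            b = polyphase:::cpp_mutate_seqs(s, 0.004)[[1]],
            c = polyphase:::cpp_mutate_seqs(s, 0.004)[[1]],
            d = polyphase:::cpp_mutate_seqs(s, 0.004)[[1]])
  expect_error(phase_subgenomes(count_kmers(seqs, 15), K = 2, seed = 1,
                                min_count = 1e6),
               "lower fold_q")
})

test_that("assignment reports round-trip losslessly", {
  fx <- fix_small()
  asg <- phase_subgenomes(count_kmers(fx$polyploid$seqs, 15), K = 3,
                          seed = 7)
  prefix <- file.path(withr::local_tempdir(), "report")
  paths <- assignment_report(asg, prefix, plots = FALSE)
  lab <- readr::read_tsv(paths[["labels"]], show_col_types = FALSE)
  expect_equal(tibble::as_tibble(lab), tidy(asg))
  ord <- readr::read_tsv(paths[["ordination"]], show_col_types = FALSE)
  expect_equal(nrow(ord), 48)
  expect_true(all(c("PC1", "PC2") %in% names(ord)))
  expect_equal(tibble::as_tibble(ord), asg$ordination)
})
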