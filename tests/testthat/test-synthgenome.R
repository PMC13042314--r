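test_that("zero divergence yields identical ancestral genomes", {
  m <- ancestry_model(2, 1e4, divergence = c(AB = 0, AC = 0, BC = 0),
                      seed = 5)
  g <- simulate_ancestral_genomes(m)
  expect_identical(g$A, g$B)
  expect_identical(g$A, g$C)
})

test_that("realised pairwise divergences match the model", {
  m <- ancestry_model(3, 2e4, seed = 11)
  g <- simulate_ancestral_genomes(m)
  p_ab <- mean(mapply(polyphase:::p_distance_chr, g$A, g$B))
  p_ac <- mean(mapply(polyphase:::p_distance_chr, g$A, g$C))
  p_bc <- mean(mapply(polyphase:::p_distance_chr, g$B, g$C))
  expect_gte(p_ab, 0.024); expect_lte(p_ab, 0.036)   # 0.03 +- 20%
  expect_gte(p_ac, 0.096); expect_lte(p_ac, 0.144)   # 0.12 +- 20%
  expect_gte(p_bc, 0.096); expect_lte(p_bc, 0.144)
})

test_that("ancestral simulation is deterministic and validates input", {
  m <- ancestry_model(2, 1e4, seed = 9)
  expect_identical(simulate_ancestral_genomes(m),
                   simulate_ancestral_genomes(m))
  expect_error(ancestry_model(2, 1e4,
                              divergence = c(AB = 0.8, AC = 0.1, BC = 0.1)),
               "0.75")
  expect_error(ancestry_model(1, 5000), "10 kb")
})

test_that("compose_polyploid emits the requested copies with truth", {
  g <- simulate_ancestral_genomes(ancestry_model(6, 1e4, seed = 2))
  pp <- compose_polyploid(g, tully_spec(), seed = 3)
  expect_length(pp$seqs, 48)
  tot <- spec_totals(tully_spec())
  expect_equal(setNames(tot$n, tot$ancestry), c(A = 14, B = 22, C = 12))
  counts <- table(pp$truth$chromosomes$ancestry)
  expect_equal(as.integer(counts[c("A", "B", "C")]), c(14, 22, 12))
  expect_true(all(grepl("^chr[1-6][ABC][0-9]+$",
                        pp$truth$chromosomes$chromosome)))
  # one truth record per emitted sequence
  expect_setequal(pp$truth$chromosomes$chromosome, names(pp$seqs))

  hex <- compose_polyploid(g, aabbbb_spec(), seed = 4)
  expect_length(hex$seqs, 36)
  expect_false(any(hex$truth$chromosomes$ancestry == "C"))

  hap <- compose_polyploid(g, polyploid_spec(
    tibble::tibble(base = 1:6, ancestry = "B", copies = 1L)), seed = 5)
  expect_length(hap$seqs, 6)
  expect_equal(nrow(hap$truth$chromosomes), 6)
})

test_that("fragmentation partitions chromosomes exactly", {
  fx <- fix_small()
  fr <- fragment_to_contigs(fx$polyploid, mean_contig_length = 6000,
                            seed = 7)
  pp <- fx$polyploid
  # conservation of bases
  expect_equal(sum(nchar(fr$contigs)), sum(nchar(pp$seqs)))
  # truth AGP reconstructs every chromosome exactly
  rec <- apply_agp(fr$truth_agp, fr$contigs)
  expect_identical(rec[names(pp$seqs)], pp$seqs)
  # determinism
  fr2 <- fragment_to_contigs(fx$polyploid, mean_contig_length = 6000,
                             seed = 7)
  expect_identical(fr$contigs, fr2$contigs)
  # mean >= chromosome length -> one contig per chromosome
  one <- fragment_to_contigs(pp$seqs[1], mean_contig_length = 1e7, seed = 1)
  expect_length(one$contigs, 1)
})

test_that("simulated reads track dosage and carry exact truth labels", {
  g <- simulate_ancestral_genomes(
    ancestry_model(1, 1e4, divergence = c(AB = 0.03, AC = 0.12, BC = 0.12),
                   seed = 21))
  spec <- polyploid_spec(tibble::tibble(base = 1L,
                                        ancestry = c("A", "B", "C"),
                                        copies = c(1L, 2L, 1L)))
  pp <- compose_polyploid(g, spec, seed = 22)
  reads <- simulate_reads(pp, coverage_per_copy = 25, read_length = 100,
                          error_rate = 0, seed = 23)
  # error-free reads are exact substrings of source or its reverse
  # complement
  idx <- seq_len(50)
  for (i in idx) {
    src <- pp$seqs[[reads$source[i]]]
    fwd <- grepl(reads$mate1[i], src, fixed = TRUE)
    rev <- grepl(polyphase:::revcomp(reads$mate1[i]), src, fixed = TRUE)
    expect_true(fwd || rev)
  }
  # equal-length chromosomes: read fractions within 2 points of
  # chromosome-count fractions
  frac <- table(pp$truth$chromosomes$ancestry[
    match(reads$source, pp$truth$chromosomes$chromosome)]) / nrow(reads)
  expect_lt(max(abs(frac - c(A = 0.25, B = 0.5, C = 0.25))), 0.02)
  # one-chromosome genome: all reads labelled to it
  solo <- simulate_reads(pp$seqs[1], coverage_per_copy = 5, seed = 1)
  expect_true(all(solo$source == names(pp$seqs)[1]))
  expect_error(simulate_reads(pp, coverage_per_copy = 0), "positive")
})

test_that("planted markers have truth copy number equal to base dosage", {
  fx <- fix_small()
  # markers homed round-robin on bases 1..6: every base gives 8 copies
  # (2+4+2 for chr1-4, 3+3+2 for chr5-6)
  expect_true(all(fx$copy_number$copies == 8))
  # each marker occurs exactly once per haplotype copy of its home base
  per <- dplyr::count(fx$placements, marker, chromosome)
  expect_true(all(per$n == 1))
  # haploid spec: one copy per marker
  g <- simulate_ancestral_genomes(ancestry_model(2, 1e4, seed = 31))
  hap <- compose_polyploid(g, polyploid_spec(
    tibble::tibble(base = 1:2, ancestry = "A", copies = 1L)), seed = 32)
  pm <- plant_markers(hap, n_markers = 4, seed = 33)
  expect_true(all(pm$copy_number$copies == 1))
})

test_that("repeat insertion honours specificity and age model", {
  g <- simulate_ancestral_genomes(ancestry_model(6, 1e4, seed = 41))
  # age point-mass at 0: both LTRs identical
  fam0 <- repeat_family("young", "A", copies_per_chromosome = 2,
                        age_mean_myr = 0, age_sd_myr = 0)
  ir0 <- insert_repeats(g, fam0, seed = 42)
  expect_true(all(ir0$insertions$ltr5 == ir0$insertions$ltr3))
  # C-specific family never lands on A or B
  famC <- repeat_family("cfam", "C", copies_per_chromosome = 2)
  irC <- insert_repeats(g, famC, seed = 43)
  expect_setequal(unique(irC$insertions$ancestry), "C")
  # mean LTR p-distance ~ 2 mu age at >= 50 copies (1 Myr -> 0.026)
  fam1 <- repeat_family("dated", c("A", "B"), copies_per_chromosome = 5,
                        age_mean_myr = 1, age_sd_myr = 0.2)
  ir1 <- insert_repeats(g, fam1, seed = 44)
  expect_gte(nrow(ir1$insertions), 50)
  pd <- mean(mapply(polyphase:::p_distance_chr,
                    ir1$insertions$ltr5, ir1$insertions$ltr3))
  expect_gt(pd, 0.026 * 0.7)
  expect_lt(pd, 0.026 * 1.3)
  # element longer than the chromosome is rejected
  huge <- repeat_family("huge", "A", element_length = 20001,
                        ltr_length = 100, copies_per_chromosome = 1)
  expect_error(insert_repeats(g, huge, seed = 45), "longer")
})
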