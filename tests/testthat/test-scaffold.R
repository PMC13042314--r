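paf_row <- function(qname, qstart, qend, tname, tstart, tend,
                    strand = "+", qlen = 1e5, tlen = 1e6) {
  tibble::tibble(qname = qname, qlen = qlen, qstart = qstart, qend = qend,
                 strand = strand, tname = tname, tlen = tlen,
                 tstart = tstart, tend = tend,
                 nmatch = qend - qstart, alen = qend - qstart, mapq = 60L)
}

test_that("colinear alignments chain; short or split ones do not", {
  # two colinear 8 kb blocks with 1 kb gaps -> one 16 kb chain
  al <- dplyr::bind_rows(
    paf_row("q1", 0, 8000, "t1", 10000, 18000),
    paf_row("q1", 9000, 17000, "t1", 19000, 27000))
  ch <- chain_alignments(al)
  expect_equal(nrow(ch), 1)
  expect_equal(ch$aligned_bases, 16000)
  expect_equal(ch$n_members, 2L)
  # a single 9 kb block fails the 10 kb minimum
  expect_equal(nrow(chain_alignments(paf_row("q2", 0, 9000, "t1", 0, 9000))),
               0)
  # blocks on opposite strands stay separate
  al2 <- dplyr::bind_rows(
    paf_row("q3", 0, 12000, "t1", 0, 12000, strand = "+"),
    paf_row("q3", 13000, 25000, "t1", 40000, 52000, strand = "-"))
  expect_equal(nrow(chain_alignments(al2)), 2)
  # a gap beyond max_gap breaks the chain
  al3 <- dplyr::bind_rows(
    paf_row("q4", 0, 12000, "t1", 0, 12000),
    paf_row("q4", 12000, 24000, "t1", 300000, 312000))
  expect_equal(nrow(chain_alignments(al3, max_gap = 1e5)), 2)
})

test_that("unique-link filtering drops multi-linked queries and
          overlapping targets, and is idempotent", {
  ch <- dplyr::bind_rows(
    chain_alignments(paf_row("amb", 0, 20000, "t1", 0, 20000)),
    chain_alignments(paf_row("amb", 0, 20000, "t2", 0, 20000)),
    chain_alignments(paf_row("solo", 0, 15000, "t1", 50000, 65000)),
    chain_alignments(paf_row("u1", 0, 15000, "t3", 0, 15000)),
    chain_alignments(paf_row("u2", 0, 15000, "t3", 20000, 35000)),
    chain_alignments(paf_row("u3", 0, 15000, "t3", 40000, 55000)))
  kept <- filter_unique_links(ch)
  # the doubly-linked contig is gone entirely; unique links survive
  expect_false("amb" %in% kept$qname)
  expect_setequal(kept$qname, c("solo", "u1", "u2", "u3"))
  # idempotent
  expect_equal(filter_unique_links(kept), kept)
  # overlapping target windows knock out both parties
  ov <- dplyr::bind_rows(
    chain_alignments(paf_row("o1", 0, 15000, "t9", 0, 15000)),
    chain_alignments(paf_row("o2", 0, 15000, "t9", 10000, 25000)))
  expect_equal(nrow(filter_unique_links(ov)), 0)
})

test_that("apply_agp honours spans, orientation and gaps", {
  contigs <- c(c1 = "ACGTACGTAA", c2 = "TTTTGGGGCC")
  plan <- polyphase:::new_agp_plan(tibble::tibble(
    object = "chrZ",
    object_beg = c(1L, 11L, 111L),
    object_end = c(10L, 110L, 120L),
    part_number = 1:3,
    component_type = c("W", "U", "W"),
    component_id = c("c1", NA, "c2"),
    component_beg = c(1L, NA, 1L),
    component_end = c(10L, NA, 10L),
    orientation = c("+", NA, "-"),
    gap_length = c(NA, 100L, NA),
    gap_type = c(NA, "scaffold", NA),
    linkage = c(NA, "yes", NA),
    evidence = c(NA, "align_genus", NA)))
  out <- apply_agp(plan, contigs)
  expect_equal(nchar(out[["chrZ"]]), 10 + 100 + 10)
  expect_equal(substr(out[["chrZ"]], 1, 10), "ACGTACGTAA")
  expect_equal(substr(out[["chrZ"]], 111, 120),
               polyphase:::revcomp("TTTTGGGGCC"))
  expect_error(apply_agp(plan, contigs["c1"]), "missing contig")
  bad <- plan; bad$component_end[3] <- 99L
  expect_error(apply_agp(bad, contigs), "outside")
  # a contig may not appear twice in a plan
  dup <- plan; dup$component_id[3] <- "c1"; dup$component_end[3] <- 10L
  expect_error(polyphase:::new_agp_plan(dup), "more than once")
})

test_that("AGP files round-trip through write and read", {
  fx <- fix_small()
  fr <- fragment_to_contigs(fx$polyploid, mean_contig_length = 8000,
                            seed = 13)
  path <- withr::local_tempfile(fileext = ".agp")
  write_agp(fr$truth_agp, path)
  back <- read_agp(path)
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(fr$truth_agp))
})

test_that("anchoring reconstructs fixture chromosomes exactly", {
  fx <- fix_small()
  pp <- fx$polyploid
  fr <- fragment_to_contigs(pp, mean_contig_length = 12000, seed = 17,
                            min_contig_length = 6000)
  an <- anchor_contigs(fr$contigs, pp$seqs, min_chain_len = 5000)
  expect_length(an$unplaced, 0)
  out <- apply_agp(an$plan, fr$contigs)
  expect_setequal(names(out), names(pp$seqs))
  for (nm in names(out)) {
    expect_identical(gsub("N", "", out[[nm]]), pp$seqs[[nm]])
  }
  # an unrelated random contig stays unplaced
  junk <- c(junk1 = polyphase:::random_dna(15000))
  an2 <- anchor_contigs(c(fr$contigs[1:4], junk),
                        pp$seqs, min_chain_len = 5000)
  expect_true("junk1" %in% an2$unplaced)
})

test_that("a chromosome-spanning contig anchors as a single component", {
  fx <- fix_small()
  pp <- fx$polyploid
  whole <- setNames(pp$seqs[1], "bigtig")
  an <- anchor_contigs(whole, pp$seqs[1], min_chain_len = 5000)
  expect_equal(nrow(an$plan), 1)
  expect_equal(an$plan$component_id, "bigtig")
})

test_that("fused references concatenate with exact liftover", {
  set.seed(19)
  g <- setNames(vapply(1:9, function(i)
    polyphase:::random_dna(1000 + 100 * i), ""),
    paste0("chr", 1:9))
  fus <- build_fused_reference(
    g, list(c("chr1", "chr7"), c("chr2", "chr4"), c("chr5", "chr6")))
  expect_length(fus$genome, 6)
  expect_setequal(names(fus$genome),
                  c("chr1+chr7", "chr2+chr4", "chr5+chr6",
                    "chr3", "chr8", "chr9"))
  # coordinate arithmetic: a position on old chr4 maps past chr2 + gap
  pos <- 57L
  lifted <- liftover_position(fus$liftover, "chr4", pos)
  expect_equal(lifted$new_chromosome, "chr2+chr4")
  expect_equal(lifted$new_position, nchar(g[["chr2"]]) + 100 + pos)
  # the lifted base is the same base
  expect_equal(substr(fus$genome[["chr2+chr4"]], lifted$new_position,
                      lifted$new_position),
               substr(g[["chr4"]], pos, pos))
  # liftover is a bijection on covered coordinates: all of chr4
  all_pos <- seq_len(nchar(g[["chr4"]]))
  lifted_all <- liftover_position(fus$liftover,
                                  rep("chr4", length(all_pos)), all_pos)
  expect_equal(anyDuplicated(lifted_all$new_position), 0L)
  # empty map is the identity
  ident <- build_fused_reference(g, list())
  expect_identical(ident$genome[names(g)], g)
  # misuse is rejected
  expect_error(build_fused_reference(g, list(c("chr1", "chr1"))), "twice")
  expect_error(build_fused_reference(g, list(c("chr1", "chrX"))),
               "missing")
})
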