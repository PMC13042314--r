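#' Ancestry model for a synthetic polyploid
#'
#' Describes the ancestral lineages (by default A, B and C) from which a
#' synthetic polyploid is composed: the base chromosome number, base
#' chromosome lengths and the pairwise substitution divergence between
#' lineages.  Defaults mirror a three-lineage history in which A and B are
#' recently diverged (3% of sites) and C is distant (12%), over a base
#' number of x = 6.
#'
#' @param n_base_chromosomes Number of base chromosomes (x).
#' @param base_lengths Integer vector of base chromosome lengths in bp
#'   (recycled to `n_base_chromosomes`); each must be at least 10 kb.
#' @param divergence Named numeric vector of pairwise substitution
#'   proportions per site, one entry per unordered lineage pair, names like
#'   `"AB"`.  All values must lie in `[0, 0.75)` (Jukes-Cantor saturation).
#' @param indel_rate Per-site indel probability (default 0; substitutions
#'   only).
#' @param seed Integer seed governing all randomness downstream of this
#'   model.
#' @return An object of class `ancestry_model`.
#' @export
#' @examples
#' ancestry_model(base_lengths = 2e4)
ancestry_model <- function(n_base_chromosomes = 6,
                           base_lengths = 100000,
                           divergence = c(AB = 0.03, AC = 0.12, BC = 0.12),
                           indel_rate = 0,
                           seed = 1) {
  stopifnot(n_base_chromosomes >= 1)
  base_lengths <- rep_len(as.integer(base_lengths), n_base_chromosomes)
  if (any(base_lengths < 10000))
    stop("base chromosome lengths must be at least 10 kb")
  if (is.null(names(divergence)) || any(nchar(names(divergence)) != 2))
    stop("divergence must be named by lineage pairs, e.g. c(AB = 0.03)")
  if (any(divergence < 0 | divergence >= 0.75))
    stop("divergences must be in [0, 0.75): beyond 0.75 substitution ",
         "proportions are saturated and unrealisable")
  ancestries <- sort(unique(unlist(strsplit(names(divergence), ""))))
  pairs <- utils::combn(ancestries, 2)
  want <- paste0(pairs[1, ], pairs[2, ])
  key <- vapply(strsplit(names(divergence), ""),
                function(p) paste(sort(p), collapse = ""), "")
  if (!setequal(key, want))
    stop("divergence must cover every unordered pair of ancestries once")
  names(divergence) <- key
  structure(
    list(n_base_chromosomes = n_base_chromosomes,
         base_lengths = base_lengths,
         ancestries = ancestries,
         divergence = divergence[want],
         indel_rate = indel_rate,
         seed = as.integer(seed)),
    class = "ancestry_model")
}

# Transform under which single-round substitution proportions compose
# additively along branches: if each branch mutates a proportion p of sites
# (uniform alternative base), the observed proportion between two tips with
# branch proportions u, v is u + v - (4/3)uv, i.e. g(u) + g(v) = g(d) with
# g(p) = -(3/4) log(1 - 4p/3).
g_sat <- function(p) -0.75 * log(1 - 4 * p / 3)
g_sat_inv <- function(x) 0.75 * (1 - exp(-4 * x / 3))

#' Simulate diverged ancestral genomes
#'
#' Draws one random root sequence per base chromosome and derives one copy
#' per ancestral lineage by i.i.d. substitution along a star tree whose
#' branch lengths are solved (in closed form) so that realised pairwise
#' p-distances match the model's divergence map in expectation.
#'
#' @param model An [ancestry_model()].
#' @return Named list, one element per ancestry, each a named character
#'   vector of base chromosome sequences (names `"1"`, `"2"`, ...).
#' @export
#' @examples
#' g <- simulate_ancestral_genomes(ancestry_model(2, 1e4, seed = 7))
#' names(g)
simulate_ancestral_genomes <- function(model) {
  stopifnot(inherits(model, "ancestry_model"))
  anc <- model$ancestries
  # Solve star-tree branch proportions from the pairwise map via the
  # additive transform; a three-point (or n-point average) formula.
  G <- matrix(0, length(anc), length(anc), dimnames = list(anc, anc))
  for (nm in names(model$divergence)) {
    a <- substr(nm, 1, 1); b <- substr(nm, 2, 2)
    G[a, b] <- G[b, a] <- g_sat(model$divergence[[nm]])
  }
  branch <- vapply(anc, function(a) {
    others <- setdiff(anc, a)
    if (length(others) == 1) return(G[a, others] / 2)
    est <- utils::combn(others, 2, function(p)
      (G[a, p[1]] + G[a, p[2]] - G[p[1], p[2]]) / 2)
    mean(est)
  }, 0)
  if (any(branch < -1e-8))
    stop("divergence map is not realisable on a star tree ",
         "(a branch length came out negative)")
  branch <- g_sat_inv(pmax(branch, 0))
  set.seed(model$seed)
  roots <- vapply(model$base_lengths, random_dna, "")
  names(roots) <- as.character(seq_along(roots))
  out <- lapply(anc, function(a) {
    s <- cpp_mutate_seqs(roots, rep(branch[[a]], length(roots)))
    names(s) <- names(roots)
    s
  })
  names(out) <- anc
  attr(out, "branch_p") <- branch
  out
}

#' Repeat family specification
#'
#' Describes an LTR retrotransposon family to be amplified in specific
#' ancestral lineages, with an insertion-age distribution that sets how far
#' the two LTRs of each copy have diverged (expected pairwise divergence
#' 2 * mu * age).
#'
#' @param name Family name (e.g. `"RLG_c1"` for a Gypsy-like family).
#' @param ancestry Character vector of ancestries the family amplifies in.
#' @param element_length Total element length in bp (including both LTRs).
#' @param ltr_length Length of each LTR in bp; must be shorter than half
#'   the element.
#' @param copies_per_chromosome Insertions per (ancestry, base chromosome).
#' @param age_mean_myr,age_sd_myr Mean and sd of insertion age, in million
#'   years (ages truncated at 0).
#' @param mu Substitution rate per site per year.
#' @return An object of class `repeat_family`.
#' @export
repeat_family <- function(name, ancestry, element_length = 1500,
                          ltr_length = 300, copies_per_chromosome = 3,
                          age_mean_myr = 1, age_sd_myr = 0.2,
                          mu = 1.3e-8) {
  stopifnot(is.character(name), length(name) == 1,
            copies_per_chromosome >= 0, mu > 0,
            age_mean_myr >= 0, age_sd_myr >= 0)
  if (ltr_length * 2 >= element_length)
    stop("ltr_length must be less than half element_length")
  structure(list(name = name, ancestry = ancestry,
                 element_length = as.integer(element_length),
                 ltr_length = as.integer(ltr_length),
                 copies_per_chromosome = as.integer(copies_per_chromosome),
                 age_mean_myr = age_mean_myr, age_sd_myr = age_sd_myr,
                 mu = mu),
            class = "repeat_family")
}

#' Default repeat families for the octoploid fixture
#'
#' Gypsy- and Copia-like families mirroring the repeat landscape of a
#' stepwise allopolyploid: young families shared by the recently diverged
#' A and B lineages (whose per-lineage consensus variants have drifted
#' apart with the genomes, providing the lineage-diagnostic k-mers), and
#' older families restricted to the long-isolated C lineage.
#'
#' @param mu Substitution rate per site per year.
#' @return List of [repeat_family()] objects.
#' @export
default_repeat_families <- function(mu = 1.3e-8) {
  list(
    repeat_family("RLG_ab1", c("A", "B"), age_mean_myr = 0.75,
                  age_sd_myr = 0.2, mu = mu),
    repeat_family("RLC_ab1", c("A", "B"), age_mean_myr = 1,
                  age_sd_myr = 0.25, mu = mu),
    repeat_family("RLG_c1", "C", age_mean_myr = 4.5, age_sd_myr = 0.8,
                  mu = mu),
    repeat_family("RLC_c1", "C", age_mean_myr = 4, age_sd_myr = 0.8,
                  mu = mu))
}

#' Insert LTR retrotransposon copies into ancestral genomes
#'
#' For each family and each targeted (ancestry, base chromosome), splices
#' `copies_per_chromosome` element copies in at random positions.  Each
#' copy's two LTRs are identical at insertion and then independently
#' mutated by `mu * age` substitutions per site, so the pair diverges by
#' 2 * mu * age in expectation -- the signal LTR insertion dating recovers.
#'
#' Because transposon families keep evolving inside each lineage, the
#' family consensus each copy derives from is a per-ancestry variant of
#' the family consensus, drifted apart by the same branch divergences as
#' the host genomes (taken from the `"branch_p"` attribute that
#' [simulate_ancestral_genomes()] attaches, or from `lineage_divergence`).
#' These lineage-specific variants, amplified across every chromosome of
#' an ancestry, are what makes k-mers subgenome-diagnostic.
#'
#' @param genomes Output of [simulate_ancestral_genomes()].
#' @param families List of [repeat_family()] objects.
#' @param seed Integer seed.
#' @param lineage_divergence Named per-ancestry substitution proportions
#'   applied to each family consensus (default: the genomes' own branch
#'   proportions; 0 if absent).
#' @return List with elements `genomes` (with insertions spliced in) and
#'   `insertions`, a tibble recording family, ancestry, base chromosome,
#'   final coordinates, true age and the aged LTR sequences of every copy.
#' @export
insert_repeats <- function(genomes, families, seed = 1,
                           lineage_divergence = attr(genomes, "branch_p")) {
  stopifnot(is.list(genomes), length(genomes) > 0)
  if (inherits(families, "repeat_family")) families <- list(families)
  if (is.null(lineage_divergence))
    lineage_divergence <- setNames(numeric(length(genomes)), names(genomes))
  set.seed(seed)
  # family consensus, then one drifted variant per target ancestry
  cons <- lapply(families, function(f) {
    ltr <- random_dna(f$ltr_length)
    internal <- random_dna(f$element_length - 2 * f$ltr_length)
    per_anc <- lapply(setNames(nm = f$ancestry), function(a) {
      p <- lineage_divergence[[a]] %||% 0
      v <- cpp_mutate_seqs(c(ltr, internal), c(p, p))
      list(ltr = v[[1]], internal = v[[2]])
    })
    per_anc
  })
  rec <- list()
  for (anc in names(genomes)) {
    for (b in names(genomes[[anc]])) {
      chrom <- genomes[[anc]][[b]]
      plan <- list()
      for (fi in seq_along(families)) {
        f <- families[[fi]]
        if (!(anc %in% f$ancestry) || f$copies_per_chromosome == 0) next
        if (f$element_length >= nchar(chrom))
          stop("element of family ", f$name,
               " is longer than its target chromosome")
        for (cp in seq_len(f$copies_per_chromosome)) {
          age <- max(0, rnorm(1, f$age_mean_myr, f$age_sd_myr))
          p_ltr <- f$mu * age * 1e6
          if (p_ltr >= 0.75)
            stop("family ", f$name, ": age so large the LTRs saturate")
          cc <- cons[[fi]][[anc]]
          ltrs <- cpp_mutate_seqs(c(cc$ltr, cc$ltr, cc$internal),
                                  c(p_ltr, p_ltr, p_ltr))
          pos <- sample.int(nchar(chrom) - 1, 1)
          plan[[length(plan) + 1]] <- list(
            family = f$name, pos = pos, age = age,
            ltr5 = ltrs[[1]], ltr3 = ltrs[[2]],
            element = paste0(ltrs[[1]], ltrs[[3]], ltrs[[2]]),
            ltr_length = f$ltr_length)
        }
      }
      if (!length(plan)) next
      ord <- order(vapply(plan, `[[`, 0, "pos"))
      plan <- plan[ord]
      pieces <- character(0)
      prev <- 0; shift <- 0
      for (ins in plan) {
        pieces <- c(pieces, substr(chrom, prev + 1, ins$pos), ins$element)
        start <- ins$pos + shift + 1
        rec[[length(rec) + 1]] <- tibble::tibble(
          family = ins$family, ancestry = anc, base = as.integer(b),
          start = start, end = start + nchar(ins$element) - 1L,
          ltr_length = ins$ltr_length, age_myr = ins$age,
          ltr5 = ins$ltr5, ltr3 = ins$ltr3)
        shift <- shift + nchar(ins$element)
        prev <- ins$pos
      }
      pieces <- c(pieces, substr(chrom, prev + 1, nchar(chrom)))
      genomes[[anc]][[b]] <- paste(pieces, collapse = "")
    }
  }
  insertions <- if (length(rec)) dplyr::bind_rows(rec) else
    tibble::tibble(family = character(), ancestry = character(),
                   base = integer(), start = integer(), end = integer(),
                   ltr_length = integer(), age_myr = double(),
                   ltr5 = character(), ltr3 = character())
  list(genomes = genomes, insertions = insertions)
}

#' Per-chromosome polyploid composition specification
#'
#' @param copies A data frame with columns `base` (base chromosome index),
#'   `ancestry` and `copies` (non-negative integer copy count).
#' @return A `polyploid_spec` tibble.
#' @seealso [tully_spec()] for the default octoploid fixture.
#' @export
polyploid_spec <- function(copies) {
  copies <- tibble::as_tibble(copies)
  stopifnot(all(c("base", "ancestry", "copies") %in% names(copies)))
  if (any(copies$copies < 0)) stop("copy counts must be non-negative")
  copies$base <- as.integer(copies$base)
  copies$copies <- as.integer(copies$copies)
  structure(copies, class = c("polyploid_spec", class(copies)))
}

#' Composition of the octoploid reference fixture
#'
#' The aneuploid AABBBBCC / AAABBBCC composition: base chromosomes 1-4
#' carry 2A + 4B + 2C copies and base chromosomes 5-6 carry 3A + 3B + 2C,
#' totalling 14A, 22B and 12C = 48 chromosomes.
#'
#' @return A [polyploid_spec()].
#' @export
#' @examples
#' spec_totals(tully_spec())
tully_spec <- function() {
  polyploid_spec(tibble::tibble(
    base = rep(1:6, each = 3),
    ancestry = rep(c("A", "B", "C"), 6),
    copies = c(rep(c(2L, 4L, 2L), 4), rep(c(3L, 3L, 2L), 2))))
}

#' An AABBBB (hexaploid, C-free) composition over 6 base chromosomes
#'
#' @return A [polyploid_spec()] with 12A + 24B = 36 chromosomes.
#' @export
aabbbb_spec <- function() {
  polyploid_spec(tibble::tibble(
    base = rep(1:6, each = 2),
    ancestry = rep(c("A", "B"), 6),
    copies = rep(c(2L, 4L), 6)))
}

#' Per-ancestry chromosome totals of a composition spec
#'
#' @param spec A [polyploid_spec()].
#' @return Tibble with columns `ancestry` and `n`; total N is
#'   `sum(spec_totals(spec)$n)`.
#' @export
spec_totals <- function(spec) {
  spec |>
    dplyr::group_by(.data$ancestry) |>
    dplyr::summarise(n = sum(.data$copies), .groups = "drop")
}

#' Compose a chromosome-level polyploid from ancestral genomes
#'
#' Emits one chromosome per haplotype copy requested by the spec, named
#' `chr{base}{ancestry}{hap}` (e.g. `chr1B2`), each independently mutated
#' from its ancestral base chromosome by `haplotype_divergence`
#' substitutions per site.  Repeat-insertion truth (if provided) is
#' propagated to every emitted copy.
#'
#' @param genomes Output of [simulate_ancestral_genomes()] (possibly after
#'   [insert_repeats()], in which case pass `$genomes`).
#' @param spec A [polyploid_spec()].
#' @param haplotype_divergence Substitution proportion between haplotype
#'   copies within an ancestry (default 0.005).
#' @param seed Integer seed.
#' @param insertions Optional insertion truth tibble from
#'   [insert_repeats()].
#' @return A `polyploid` object: list with `seqs` (named character vector
#'   of chromosomes) and `truth` (list of tibbles `chromosomes` and
#'   `repeats`).
#' @export
#' @examples
#' g <- simulate_ancestral_genomes(
#'   ancestry_model(2, 1e4, divergence = c(AB = 0.03, AC = 0.12, BC = 0.12)))
#' pp <- compose_polyploid(g, tully_spec()[tully_spec()$base <= 2, ])
#' length(pp$seqs)
compose_polyploid <- function(genomes, spec, haplotype_divergence = 0.005,
                              seed = 1, insertions = NULL) {
  stopifnot(inherits(spec, "polyploid_spec"))
  miss <- setdiff(unique(spec$ancestry[spec$copies > 0]), names(genomes))
  if (length(miss))
    stop("spec requests ancestries missing from genomes: ",
         paste(miss, collapse = ", "))
  set.seed(seed)
  seqs <- character(0)
  rows <- list()
  for (i in seq_len(nrow(spec))) {
    b <- spec$base[i]; anc <- spec$ancestry[i]; nc <- spec$copies[i]
    if (nc == 0) next
    src <- genomes[[anc]][[as.character(b)]]
    if (is.null(src))
      stop("ancestry ", anc, " has no base chromosome ", b)
    for (h in seq_len(nc)) {
      nm <- sprintf("chr%d%s%d", b, anc, h)
      seqs[[nm]] <- cpp_mutate_seqs(src, haplotype_divergence)[[1]]
      rows[[length(rows) + 1]] <- tibble::tibble(
        chromosome = nm, ancestry = anc, haplotype = h, base = b,
        length = nchar(seqs[[nm]]))
    }
  }
  chrom_truth <- dplyr::bind_rows(rows)
  rep_truth <- NULL
  if (!is.null(insertions) && nrow(insertions)) {
    rep_truth <- chrom_truth |>
      dplyr::select("chromosome", "ancestry", "base") |>
      dplyr::inner_join(insertions, by = c("ancestry", "base"),
                        relationship = "many-to-many")
  }
  structure(list(seqs = seqs,
                 truth = list(chromosomes = chrom_truth,
                              repeats = rep_truth),
                 spec = spec,
                 haplotype_divergence = haplotype_divergence),
            class = "polyploid")
}

#' @export
print.polyploid <- function(x, ...) {
  tot <- spec_totals(x$spec)
  cat("<polyploid> ", length(x$seqs), " chromosomes (",
      paste0(tot$n, tot$ancestry, collapse = " "), "), ",
      format(sum(nchar(x$seqs)), big.mark = ","), " bp\n", sep = "")
  invisible(x)
}

#' Fragment polyploid chromosomes into contigs
#'
#' Cuts every chromosome into contiguous, non-overlapping segments whose
#' lengths are drawn around `mean_contig_length`; segments partition each
#' chromosome exactly.  Contig names are emitted in shuffled order so they
#' carry no placement information.
#'
#' @param polyploid A `polyploid` object (or named character vector).
#' @param mean_contig_length Target mean contig length in bp.
#' @param length_dispersion Coefficient of variation of contig lengths.
#' @param seed Integer seed.
#' @param min_contig_length Minimum contig length (default a quarter of the
#'   mean).
#' @return List with `contigs` (named character vector) and `truth_agp`,
#'   the gap-free AGP plan that reconstructs the chromosomes exactly.
#' @export
fragment_to_contigs <- function(polyploid, mean_contig_length = 50000,
                                length_dispersion = 0.25, seed = 1,
                                min_contig_length = mean_contig_length / 4) {
  seqs <- if (inherits(polyploid, "polyploid")) polyploid$seqs else
    as_seq_char(polyploid)
  if (mean_contig_length < 1) stop("mean_contig_length must be positive")
  set.seed(seed)
  contigs <- character(0)
  rows <- list()
  idx <- 0L
  for (nm in names(seqs)) {
    len <- nchar(seqs[[nm]])
    cuts <- integer(0)
    pos <- 0
    while (TRUE) {
      step <- round(rnorm(1, mean_contig_length,
                          length_dispersion * mean_contig_length))
      step <- max(step, min_contig_length)
      if (pos + step >= len - min_contig_length) break
      pos <- pos + step
      cuts <- c(cuts, pos)
    }
    starts <- c(1L, cuts + 1L)
    ends <- c(cuts, len)
    for (j in seq_along(starts)) {
      idx <- idx + 1L
      cid <- sprintf("tig%05d", idx)
      contigs[[cid]] <- substr(seqs[[nm]], starts[j], ends[j])
      rows[[length(rows) + 1]] <- tibble::tibble(
        object = nm, object_beg = starts[j], object_end = ends[j],
        part_number = j, component_type = "W", component_id = cid,
        component_beg = 1L, component_end = ends[j] - starts[j] + 1L,
        orientation = "+",
        gap_length = NA_integer_, gap_type = NA_character_,
        linkage = NA_character_, evidence = NA_character_)
    }
  }
  plan <- new_agp_plan(dplyr::bind_rows(rows))
  contigs <- contigs[sample(length(contigs))]
  list(contigs = contigs, truth_agp = plan)
}

#' Simulate paired-end reads from a polyploid
#'
#' Uniform fragment sampling per chromosome: the expected pair count per
#' chromosome is proportional to its length, so subgenome read shares
#' mirror chromosome dosage -- the property competitive mapping exploits.
#' Fragments take either strand with equal probability; sequencing errors
#' are i.i.d. substitutions.
#'
#' @param polyploid A `polyploid` object (or named character vector).
#' @param coverage_per_copy Mean coverage per chromosome copy (x).
#' @param read_length Read length in bp.
#' @param insert_mean,insert_sd Fragment (insert) size distribution in bp.
#' @param error_rate Per-base substitution error rate.
#' @param seed Integer seed.
#' @return Tibble with columns `id`, `mate1`, `mate2` and `source` (the
#'   chromosome of origin; the truth label for every pair).
#' @export
simulate_reads <- function(polyploid, coverage_per_copy = 20,
                           read_length = 100, insert_mean = 300,
                           insert_sd = 30, error_rate = 0.002, seed = 1) {
  seqs <- if (inherits(polyploid, "polyploid")) polyploid$seqs else
    as_seq_char(polyploid)
  if (coverage_per_copy <= 0) stop("coverage_per_copy must be positive")
  if (!(read_length < insert_mean && insert_mean < min(nchar(seqs))))
    stop("need read_length < insert_mean < chromosome length")
  set.seed(seed)
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    chrom <- seqs[[i]]; len <- nchar(chrom)
    n <- round(len * coverage_per_copy / (2 * read_length))
    ins <- pmin(pmax(round(rnorm(n, insert_mean, insert_sd)),
                     read_length), len)
    start <- vapply(len - ins + 1L, function(m) sample.int(m, 1), 1L)
    end <- start + ins - 1L
    m1 <- substring(chrom, start, start + read_length - 1L)
    m2 <- revcomp(substring(chrom, end - read_length + 1L, end))
    flip <- runif(n) < 0.5
    tmp <- m1[flip]; m1[flip] <- m2[flip]; m2[flip] <- tmp
    if (error_rate > 0) {
      mut <- cpp_mutate_seqs(c(m1, m2), error_rate)
      m1 <- mut[seq_len(n)]; m2 <- mut[n + seq_len(n)]
    }
    out[[i]] <- tibble::tibble(
      id = sprintf("%s_read%06d", names(seqs)[i], seq_len(n)),
      mate1 = m1, mate2 = m2, source = names(seqs)[i])
  }
  dplyr::bind_rows(out)
}

#' Plant single-copy markers on a polyploid
#'
#' Each marker is homed on one base chromosome and planted exactly once on
#' every haplotype copy of that base chromosome (across all ancestries),
#' each planted copy independently mutated by `divergence`.  The true copy
#' number of a marker therefore equals the total copy count of its home
#' base chromosome -- the quantity a single-copy-marker multiplicity
#' histogram estimates.  Planting overwrites a random segment, avoiding
#' previously planted markers and recorded repeat insertions.
#'
#' @param polyploid A `polyploid` object.
#' @param n_markers Number of markers (homed round-robin on base
#'   chromosomes).
#' @param marker_length Marker length in bp (must be much shorter than the
#'   chromosomes).
#' @param divergence Substitution proportion applied to each planted copy.
#' @param seed Integer seed.
#' @return List with `polyploid` (sequences updated), `markers` (named
#'   character vector of pristine marker sequences), `placements` (tibble:
#'   marker, chromosome, start, end) and `copy_number` (tibble: marker,
#'   copies -- the ground truth).
#' @export
plant_markers <- function(polyploid, n_markers = 24, marker_length = 500,
                          divergence = 0.005, seed = 1) {
  stopifnot(inherits(polyploid, "polyploid"))
  if (marker_length * 10 > min(nchar(polyploid$seqs)))
    stop("marker_length must be much shorter than the chromosomes")
  set.seed(seed)
  truth <- polyploid$truth$chromosomes
  bases <- sort(unique(truth$base))
  home <- rep_len(bases, n_markers)
  markers <- setNames(vapply(seq_len(n_markers),
                             function(i) random_dna(marker_length), ""),
                      sprintf("marker%03d", seq_len(n_markers)))
  occupied <- lapply(setNames(nm = truth$chromosome), function(nm) {
    rp <- polyploid$truth$repeats
    if (is.null(rp)) return(IRanges::IRanges())
    rp <- rp[rp$chromosome == nm, ]
    IRanges::IRanges(start = rp$start, end = rp$end)
  })
  rows <- list()
  for (i in seq_len(n_markers)) {
    chroms <- truth$chromosome[truth$base == home[i]]
    for (nm in chroms) {
      len <- nchar(polyploid$seqs[[nm]])
      for (try in 1:200) {
        start <- sample.int(len - marker_length + 1L, 1)
        cand <- IRanges::IRanges(start, width = marker_length)
        if (length(IRanges::findOverlaps(cand, occupied[[nm]])) == 0) break
        if (try == 200) stop("could not place marker without overlap on ", nm)
      }
      occupied[[nm]] <- c(occupied[[nm]], cand)
      planted <- cpp_mutate_seqs(markers[[i]], divergence)[[1]]
      substr(polyploid$seqs[[nm]], start, start + marker_length - 1L) <-
        planted
      rows[[length(rows) + 1]] <- tibble::tibble(
        marker = names(markers)[i], chromosome = nm,
        start = start, end = start + marker_length - 1L)
    }
  }
  placements <- dplyr::bind_rows(rows)
  copy_number <- placements |>
    dplyr::count(.data$marker, name = "copies")
  list(polyploid = polyploid, markers = markers,
       placements = placements, copy_number = copy_number)
}

#' Simulate the default octoploid reference fixture
#'
#' One-call construction of the desk-scale stand-in for an octoploid
#' AABBBBCC/AAABBBCC genome: three ancestral lineages over x = 6 base
#' chromosomes (A-B 3%, A/B-C 12% diverged), subgenome-structured repeat
#' families, the aneuploid 14A + 22B + 12C composition at 0.5% haplotype
#' divergence, and (optionally) planted single-copy markers.
#'
#' @param seed Integer seed for every stage.
#' @param base_length Base chromosome length in bp (default 100 kb).
#' @param spec Composition spec (default [tully_spec()]).
#' @param with_repeats Insert [default_repeat_families()] (default TRUE).
#' @param n_markers Markers to plant (0 to skip).
#' @param haplotype_divergence Within-ancestry copy divergence.
#' @return List with `polyploid`, `genomes`, `insertions`, and (when
#'   markers are planted) `markers`, `placements`, `copy_number`.
#' @export
simulate_tully <- function(seed = 1, base_length = 1e5,
                           spec = tully_spec(), with_repeats = TRUE,
                           n_markers = 0, haplotype_divergence = 0.005) {
  model <- ancestry_model(6, base_length, seed = seed)
  genomes <- simulate_ancestral_genomes(model)
  insertions <- NULL
  if (with_repeats) {
    ir <- insert_repeats(genomes, default_repeat_families(), seed = seed + 1)
    genomes <- ir$genomes
    insertions <- ir$insertions
  }
  pp <- compose_polyploid(genomes, spec,
                          haplotype_divergence = haplotype_divergence,
                          seed = seed + 2, insertions = insertions)
  out <- list(polyploid = pp, genomes = genomes, insertions = insertions)
  if (n_markers > 0) {
    pm <- plant_markers(pp, n_markers = n_markers, seed = seed + 3)
    out$polyploid <- pm$polyploid
    out$markers <- pm$markers
    out$placements <- pm$placements
    out$copy_number <- pm$copy_number
  }
  out
}

#' Write a polyploid (or any named sequence set) to FASTA
#'
#' @param seqs Named character vector, `polyploid` object or DNAStringSet.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "polyploid")) seqs <- seqs$seqs
  seqs <- as_seq_char(seqs)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Write paired reads to a pair of FASTQ files
#'
#' @param reads Tibble from [simulate_reads()].
#' @param prefix Output prefix; files `{prefix}_1.fastq` and
#'   `{prefix}_2.fastq` are written with uniform quality.
#' @return Character vector of the two paths, invisibly.
#' @export
write_fastq_pairs <- function(reads, prefix) {
  paths <- paste0(prefix, c("_1.fastq", "_2.fastq"))
  for (m in 1:2) {
    ss <- Biostrings::DNAStringSet(reads[[paste0("mate", m)]])
    names(ss) <- paste0(reads$id, "/", m)
    q <- Biostrings::BStringSet(strrep("I", nchar(ss)))
    Biostrings::writeXStringSet(ss, paths[m], format = "fastq",
                                qualities = q)
  }
  invisible(paths)
}

#' Read paired FASTQ files into a read-pair tibble
#'
#' @param path1,path2 Paths to the mate-1 and mate-2 FASTQ files.
#' @return Tibble with columns `id`, `mate1`, `mate2`.
#' @export
read_fastq_pairs <- function(path1, path2) {
  s1 <- Biostrings::readDNAStringSet(path1, format = "fastq")
  s2 <- Biostrings::readDNAStringSet(path2, format = "fastq")
  if (length(s1) != length(s2)) stop("mate files differ in read count")
  tibble::tibble(id = sub("/1$", "", sub(" .*", "", names(s1))),
                 mate1 = as.character(s1), mate2 = as.character(s2))
}
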