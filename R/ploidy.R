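#' Count genomic copies of single-copy markers
#'
#' For every marker, counts the number of distinct loci in the target
#' sequences where the marker aligns over at least `min_coverage` of its
#' length at `min_identity` identity or better.  Loci whose intervals
#' overlap by 50% or more (either orientation) are collapsed to one.  The
#' resulting copy-number histogram is the basis for ploidy estimation:
#' in a 2n = 8x genome most single-copy markers align 8 times.
#'
#' Alignment is seed-and-extend: exact short seeds located with a
#' position-weight dictionary, candidate loci verified by local pairwise
#' alignment.
#'
#' @param markers Named character vector or DNAStringSet of marker
#'   sequences.
#' @param target_sequences Named character vector or DNAStringSet of
#'   chromosomes/contigs.
#' @param min_coverage Minimum fraction of the marker length aligned
#'   (default 0.9).
#' @param min_identity Minimum alignment identity (default 0.9).
#' @param seed_k Exact seed length (default 15).
#' @param seed_step Spacing between seeds along the marker (default 10).
#' @param min_seed_hits Minimum co-projected seed hits to open a candidate
#'   locus (default 3; guards against chance seed matches).
#' @return A `marker_copy_histogram` object with `$copies` (tibble: marker,
#'   copies), `$histogram` (tibble: copies, n_markers) and `$n_markers`.
#' @export
count_marker_copies <- function(markers, target_sequences,
                                min_coverage = 0.9, min_identity = 0.9,
                                seed_k = 15, seed_step = 10,
                                min_seed_hits = 3) {
  markers <- as_seq_char(markers, "markers")
  targets <- as_seq_char(target_sequences, "target_sequences")
  # Build seeds for every marker, forward and reverse-complement.
  seed_rows <- list()
  for (mi in seq_along(markers)) {
    m <- markers[[mi]]
    ml <- nchar(m)
    if (ml < seed_k) stop("marker shorter than seed_k")
    offs <- seq(1L, ml - seed_k + 1L, by = seed_step)
    for (strand in c("+", "-")) {
      s <- if (strand == "+") m else revcomp(m)
      seed_rows[[length(seed_rows) + 1]] <- tibble::tibble(
        marker = names(markers)[mi], strand = strand, offset = offs,
        seed = substring(s, offs, offs + seed_k - 1L), ml = ml)
    }
  }
  seeds <- dplyr::bind_rows(seed_rows)
  keep <- !grepl("[^ACGTacgt]", seeds$seed)
  seeds <- seeds[keep, ]
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(seeds$seed))
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)

  copies <- setNames(integer(length(markers)), names(markers))
  for (ti in seq_along(targets)) {
    tseq <- Biostrings::DNAString(targets[[ti]])
    hits <- Biostrings::matchPDict(pd, tseq)
    starts <- BiocGenerics::start(hits)
    nh <- lengths(starts)
    if (sum(nh) == 0) next
    ht <- tibble::tibble(
      marker = rep(seeds$marker, nh),
      strand = rep(seeds$strand, nh),
      offset = rep(seeds$offset, nh),
      ml = rep(seeds$ml, nh),
      hit_start = unlist(starts))
    ht$proj <- ht$hit_start - ht$offset + 1L
    # cluster projected starts per (marker, strand) into candidate loci
    loci <- ht |>
      dplyr::group_by(.data$marker, .data$strand) |>
      dplyr::group_modify(function(d, key) {
        d <- d[order(d$proj), ]
        grp <- cumsum(c(1L, diff(d$proj) > d$ml[1] / 2))
        d |>
          dplyr::mutate(grp = grp) |>
          dplyr::group_by(.data$grp) |>
          dplyr::summarise(proj = round(median(.data$proj)),
                           n_seeds = dplyr::n(), ml = .data$ml[1],
                           .groups = "drop")
      }) |>
      dplyr::ungroup() |>
      dplyr::filter(.data$n_seeds >= min_seed_hits)
    if (nrow(loci) == 0) next
    # verify candidate loci by local alignment
    verified <- list()
    for (li in seq_len(nrow(loci))) {
      ml <- loci$ml[li]
      w0 <- max(1L, loci$proj[li] - 50L)
      w1 <- min(length(tseq), loci$proj[li] + ml + 49L)
      window <- Biostrings::subseq(tseq, w0, w1)
      q <- markers[[loci$marker[li]]]
      if (loci$strand[li] == "-") q <- revcomp(q)
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(q), window, type = "local",
        substitutionMatrix = sm, gapOpening = 4, gapExtension = 1)
      nm <- Biostrings::nmatch(aln)
      nmm <- Biostrings::nmismatch(aln)
      cov <- (nm + nmm) / ml  # aligned non-gap marker positions
      ident <- if (nm + nmm > 0) nm / (nm + nmm) else 0
      if (cov >= min_coverage && ident >= min_identity) {
        sr <- Biostrings::subject(aln)
        verified[[length(verified) + 1]] <- tibble::tibble(
          marker = loci$marker[li],
          start = w0 + BiocGenerics::start(sr) - 1L,
          end = w0 + BiocGenerics::end(sr) - 1L)
      }
    }
    if (!length(verified)) next
    vt <- dplyr::bind_rows(verified)
    # de-duplicate loci overlapping >= 50% across strands per marker
    for (mk in unique(vt$marker)) {
      iv <- vt[vt$marker == mk, ]
      iv <- iv[order(iv$start), ]
      n_loci <- 0L
      cur_end <- -Inf
      cur_len <- 0
      for (r in seq_len(nrow(iv))) {
        ov <- cur_end - iv$start[r] + 1
        len <- iv$end[r] - iv$start[r] + 1
        if (ov >= 0.5 * min(len, cur_len)) {
          cur_end <- max(cur_end, iv$end[r])
        } else {
          n_loci <- n_loci + 1L
          cur_end <- iv$end[r]
          cur_len <- len
        }
      }
      copies[[mk]] <- copies[[mk]] + n_loci
    }
  }
  new_marker_copy_histogram(
    tibble::tibble(marker = names(copies), copies = unname(copies)))
}

new_marker_copy_histogram <- function(copies_tbl) {
  hist <- copies_tbl |>
    dplyr::count(.data$copies, name = "n_markers") |>
    dplyr::arrange(.data$copies)
  structure(list(copies = copies_tbl, histogram = hist,
                 n_markers = nrow(copies_tbl)),
            class = "marker_copy_histogram")
}

#' Build a marker copy-number histogram from counts
#'
#' Constructor for a `marker_copy_histogram` from an already-computed
#' copy-count table or histogram, e.g. when copy counts come from an
#' external alignment pipeline.
#'
#' @param x Either a data frame with columns `marker` and `copies`, or a
#'   named numeric vector `c("8" = 2899, ...)` mapping copy number to the
#'   number of markers.
#' @return A `marker_copy_histogram`.
#' @export
#' @examples
#' marker_copy_histogram(c("8" = 2899, "4" = 1000, "12" = 976))
marker_copy_histogram <- function(x) {
  if (is.data.frame(x)) {
    return(new_marker_copy_histogram(tibble::as_tibble(x)))
  }
  stopifnot(is.numeric(x), !is.null(names(x)))
  copies <- rep(as.integer(names(x)), as.integer(x))
  new_marker_copy_histogram(
    tibble::tibble(marker = sprintf("marker%05d", seq_along(copies)),
                   copies = copies))
}

#' @export
print.marker_copy_histogram <- function(x, ...) {
  cat("<marker_copy_histogram> ", x$n_markers, " markers\n", sep = "")
  print(x$histogram)
  invisible(x)
}

#' Modal marker copy number and its marker fraction
#'
#' The mode of the copy-number histogram estimates the haplotype
#' multiplicity of the genome (ties broken towards the larger copy
#' number); the fraction reports how dominant the mode is.
#'
#' @param hist A `marker_copy_histogram`.
#' @return One-row tibble: `modal_copy`, `fraction`, `n_markers`.
#' @export
#' @examples
#' modal_copy_fraction(marker_copy_histogram(c("8" = 2899, "4" = 1976)))
modal_copy_fraction <- function(hist) {
  stopifnot(inherits(hist, "marker_copy_histogram"))
  h <- hist$histogram
  if (nrow(h) == 0 || hist$n_markers == 0) stop("empty histogram")
  best <- h[h$n_markers == max(h$n_markers), ]
  modal <- max(best$copies)  # tie towards the larger copy number
  tibble::tibble(
    modal_copy = as.integer(modal),
    fraction = h$n_markers[h$copies == modal] / hist$n_markers,
    n_markers = hist$n_markers)
}

#' Estimate chromosome number from marker multiplicity
#'
#' With a base chromosome number x and single-copy markers aligning
#' `modal_copy` times, the expected chromosome count is their product
#' (e.g. modal copy 8 with x = 6 gives 2n = 8x = 48).
#'
#' @param modal_copy Modal marker copy number (>= 1).
#' @param base_number Base chromosome number x (>= 1).
#' @return Integer chromosome number.
#' @export
#' @examples
#' estimate_chromosome_number(8, 6)
estimate_chromosome_number <- function(modal_copy, base_number) {
  stopifnot(modal_copy >= 1, base_number >= 1)
  as.integer(modal_copy) * as.integer(base_number)
}
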