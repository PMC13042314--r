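#' Read a PAF alignment file
#'
#' Parses the 12 mandatory PAF columns (coordinates 0-based half-open, as
#' in the format); optional tag columns are ignored.
#'
#' @param path Path to a PAF file.
#' @return Tibble with columns `qname, qlen, qstart, qend, strand, tname,
#'   tlen, tstart, tend, nmatch, alen, mapq`.
#' @export
read_paf <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble::tibble(
      qname = character(), qlen = integer(), qstart = integer(),
      qend = integer(), strand = character(), tname = character(),
      tlen = integer(), tstart = integer(), tend = integer(),
      nmatch = integer(), alen = integer(), mapq = integer()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 12)) stop("malformed PAF: fewer than 12 fields")
  col <- function(i) vapply(parts, `[[`, "", i)
  tibble::tibble(
    qname = col(1), qlen = as.integer(col(2)),
    qstart = as.integer(col(3)), qend = as.integer(col(4)),
    strand = col(5), tname = col(6), tlen = as.integer(col(7)),
    tstart = as.integer(col(8)), tend = as.integer(col(9)),
    nmatch = as.integer(col(10)), alen = as.integer(col(11)),
    mapq = as.integer(col(12)))
}

#' Align contigs to a reference with minimap2
#'
#' Thin wrapper over the minimap2 executable (assembly-to-assembly
#' presets); primary alignments only, so each contig reports its single
#' best placement and near-identical homoeologs do not flood the link
#' filter with secondary hits.
#'
#' @param contigs Named character vector or DNAStringSet (or path to a
#'   FASTA file).
#' @param reference Same, for the reference chromosomes.
#' @param preset minimap2 preset (default `"asm5"`, for <=5% divergent
#'   assemblies).
#' @param extra_args Additional minimap2 arguments.
#' @return PAF tibble as from [read_paf()].
#' @export
align_contigs <- function(contigs, reference, preset = "asm5",
                          extra_args = character()) {
  if (Sys.which("minimap2") == "")
    stop("minimap2 not found on PATH; align_contigs() requires it ",
         "(or pass precomputed alignments to anchor_contigs())")
  as_fasta_path <- function(x, what) {
    if (is.character(x) && length(x) == 1 && is.null(names(x)) &&
        file.exists(x)) return(x)
    p <- tempfile(paste0(what, "_"), fileext = ".fa")
    write_fasta(x, p)
    p
  }
  qry <- as_fasta_path(contigs, "qry")
  ref <- as_fasta_path(reference, "ref")
  out <- tempfile("aln_", fileext = ".paf")
  status <- system2("minimap2",
                    c("-x", preset, "--secondary=no", "-t", "1",
                      extra_args, shQuote(ref), shQuote(qry)),
                    stdout = out, stderr = FALSE)
  if (status != 0) stop("minimap2 failed with status ", status)
  read_paf(out)
}

#' Chain colinear alignments per contig-chromosome pair
#'
#' Greedy colinear chaining within each (query, target, strand) group:
#' alignments are taken in query order and extended while both query and
#' target gaps stay below `max_gap` and target order is strand-consistent.
#' Chains with fewer than `min_chain_len` aligned bases are discarded
#' (default 10 kb, the conventional minimum alignment length for
#' assembly-to-assembly anchoring).
#'
#' @param alignments PAF tibble ([read_paf()] / [align_contigs()]).
#' @param max_gap Maximum query/target gap within a chain, bp.
#' @param min_chain_len Minimum total aligned bases per chain, bp.
#' @return Tibble of chains: `qname, tname, strand, n_members,
#'   aligned_bases, nmatch, qstart, qend, tstart, tend`.
#' @export
chain_alignments <- function(alignments, max_gap = 1e5,
                             min_chain_len = 1e4) {
  al <- tibble::as_tibble(alignments)
  need <- c("qname", "qstart", "qend", "strand", "tname", "tstart", "tend")
  stopifnot(all(need %in% names(al)))
  if (!"nmatch" %in% names(al)) al$nmatch <- al$qend - al$qstart
  chains <- list()
  al <- al[order(al$qname, al$tname, al$strand, al$qstart), ]
  grp <- paste(al$qname, al$tname, al$strand, sep = "\r")
  for (g in split(seq_len(nrow(al)), grp)) {
    d <- al[g, ]
    cur <- 1L
    chain_id <- integer(nrow(d))
    chain_id[1] <- cur
    for (r in seq_len(nrow(d))[-1]) {
      qgap <- d$qstart[r] - d$qend[r - 1]
      tgap <- if (d$strand[r] == "+") d$tstart[r] - d$tend[r - 1]
              else d$tstart[r - 1] - d$tend[r]
      ok <- qgap <= max_gap && tgap <= max_gap &&
        (if (d$strand[r] == "+") d$tstart[r] >= d$tstart[r - 1]
         else d$tstart[r] <= d$tstart[r - 1])
      if (!ok) cur <- cur + 1L
      chain_id[r] <- cur
    }
    for (cid in unique(chain_id)) {
      m <- d[chain_id == cid, ]
      chains[[length(chains) + 1]] <- tibble::tibble(
        qname = m$qname[1], tname = m$tname[1], strand = m$strand[1],
        n_members = nrow(m),
        aligned_bases = sum(m$qend - m$qstart),
        nmatch = sum(m$nmatch),
        qstart = min(m$qstart), qend = max(m$qend),
        tstart = min(m$tstart), tend = max(m$tend))
    }
  }
  out <- if (length(chains)) dplyr::bind_rows(chains) else
    tibble::tibble(qname = character(), tname = character(),
                   strand = character(), n_members = integer(),
                   aligned_bases = integer(), nmatch = integer(),
                   qstart = integer(), qend = integer(),
                   tstart = integer(), tend = integer())
  dplyr::filter(out, .data$aligned_bases >= min_chain_len)
}

#' Keep only uniquely linked chains
#'
#' Automates the manual AGP curation rule of dropping links whose query or
#' target has more than one alignment: first every chain whose query
#' contig participates in more than one chain is removed, then every chain
#' whose target interval overlaps another retained chain's target interval
#' is removed.  Idempotent.
#'
#' @param chains Tibble from [chain_alignments()].
#' @return The retained chains.
#' @export
filter_unique_links <- function(chains) {
  ch <- tibble::as_tibble(chains)
  if (nrow(ch) == 0) return(ch)
  ch <- ch |>
    dplyr::group_by(.data$qname) |>
    dplyr::filter(dplyr::n() == 1) |>
    dplyr::ungroup()
  if (nrow(ch) == 0) return(ch)
  drop <- logical(nrow(ch))
  for (tn in unique(ch$tname)) {
    i <- which(ch$tname == tn)
    ir <- IRanges::IRanges(ch$tstart[i] + 1L, ch$tend[i])
    ov <- IRanges::findOverlaps(ir, ir)
    multi <- unique(S4Vectors::queryHits(ov)[
      S4Vectors::queryHits(ov) != S4Vectors::subjectHits(ov)])
    drop[i[multi]] <- TRUE
  }
  ch[!drop, ]
}

new_agp_plan <- function(tbl) {
  tbl <- tibble::as_tibble(tbl)
  w <- tbl$component_type == "W"
  if (anyDuplicated(tbl$component_id[w]))
    stop("a contig appears more than once in the AGP plan")
  structure(tbl, class = c("agp_plan", class(tibble::tibble())))
}

#' Anchor contigs into chromosomes by synteny
#'
#' Aligns contigs to reference chromosomes (minimap2, primary alignments),
#' chains colinear alignments, keeps uniquely linked chains
#' ([filter_unique_links()]), then places each retained contig on its
#' chain's target: ordered along the chromosome by chain midpoint,
#' oriented by chain strand, with fixed-length scaffold gaps between
#' adjacent components.  Contigs without a retained chain are reported
#' unplaced.
#'
#' @param contigs Named character vector or DNAStringSet.
#' @param reference Named character vector or DNAStringSet of reference
#'   chromosomes (distinct names).
#' @param min_chain_len Minimum aligned bases per chain (default 10 kb).
#' @param max_gap Chaining gap limit, bp.
#' @param gap_length Gap record length between placed components, bp.
#' @param alignments Optional precomputed PAF tibble (skips minimap2).
#' @return List with `plan` (an `agp_plan`), `unplaced` (character vector
#'   of contig names) and `chains` (the retained chains).
#' @export
anchor_contigs <- function(contigs, reference, min_chain_len = 1e4,
                           max_gap = 1e5, gap_length = 100,
                           alignments = NULL) {
  contigs <- as_seq_char(contigs, "contigs")
  reference <- as_seq_char(reference, "reference")
  if (anyDuplicated(names(reference)))
    stop("reference chromosome names must be distinct")
  if (is.null(alignments))
    alignments <- align_contigs(contigs, reference)
  chains <- chain_alignments(alignments, max_gap = max_gap,
                             min_chain_len = min_chain_len)
  kept <- filter_unique_links(chains)
  rows <- list()
  if (nrow(kept)) {
    kept$mid <- (kept$tstart + kept$tend) / 2
    for (tn in unique(kept$tname)) {
      d <- kept[kept$tname == tn, ]
      d <- d[order(d$mid), ]
      obj_pos <- 0L
      part <- 0L
      for (r in seq_len(nrow(d))) {
        if (r > 1) {
          part <- part + 1L
          rows[[length(rows) + 1]] <- tibble::tibble(
            object = tn, object_beg = obj_pos + 1L,
            object_end = obj_pos + as.integer(gap_length),
            part_number = part, component_type = "U",
            component_id = NA_character_, component_beg = NA_integer_,
            component_end = NA_integer_, orientation = NA_character_,
            gap_length = as.integer(gap_length), gap_type = "scaffold",
            linkage = "yes", evidence = "align_genus")
          obj_pos <- obj_pos + as.integer(gap_length)
        }
        clen <- nchar(contigs[[d$qname[r]]])
        part <- part + 1L
        rows[[length(rows) + 1]] <- tibble::tibble(
          object = tn, object_beg = obj_pos + 1L,
          object_end = obj_pos + clen, part_number = part,
          component_type = "W", component_id = d$qname[r],
          component_beg = 1L, component_end = clen,
          orientation = d$strand[r],
          gap_length = NA_integer_, gap_type = NA_character_,
          linkage = NA_character_, evidence = NA_character_)
        obj_pos <- obj_pos + clen
      }
    }
  }
  plan <- new_agp_plan(if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(object = character(), object_beg = integer(),
                   object_end = integer(), part_number = integer(),
                   component_type = character(), component_id = character(),
                   component_beg = integer(), component_end = integer(),
                   orientation = character(), gap_length = integer(),
                   gap_type = character(), linkage = character(),
                   evidence = character()))
  placed <- plan$component_id[plan$component_type == "W"]
  list(plan = plan, unplaced = setdiff(names(contigs), placed),
       chains = kept)
}

#' Materialise an AGP plan into chromosome sequences
#'
#' @param plan An `agp_plan`.
#' @param contigs Named character vector or DNAStringSet holding every
#'   component contig.
#' @return Named character vector of assembled sequences; gap records
#'   become runs of `N`, `-` components are reverse-complemented.
#' @export
apply_agp <- function(plan, contigs) {
  contigs <- as_seq_char(contigs, "contigs")
  out <- character(0)
  for (obj in unique(plan$object)) {
    d <- plan[plan$object == obj, ]
    d <- d[order(d$part_number), ]
    pieces <- character(nrow(d))
    for (r in seq_len(nrow(d))) {
      if (d$component_type[r] %in% c("N", "U")) {
        pieces[r] <- strrep("N", d$gap_length[r])
      } else {
        cid <- d$component_id[r]
        if (!cid %in% names(contigs)) stop("missing contig: ", cid)
        clen <- nchar(contigs[[cid]])
        if (d$component_end[r] > clen || d$component_beg[r] < 1)
          stop("component span outside contig ", cid)
        s <- substr(contigs[[cid]], d$component_beg[r], d$component_end[r])
        pieces[r] <- if (identical(d$orientation[r], "-")) revcomp(s) else s
      }
    }
    out[[obj]] <- paste(pieces, collapse = "")
  }
  out
}

#' Write an AGP plan to a file (AGP v2.1)
#'
#' Component rows are written 1-based inclusive per the AGP
#' specification.
#'
#' @param plan An `agp_plan`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_agp <- function(plan, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##agp-version\t2.1", con)
  for (r in seq_len(nrow(plan))) {
    if (plan$component_type[r] == "W") {
      fields <- c(plan$object[r], plan$object_beg[r], plan$object_end[r],
                  plan$part_number[r], "W", plan$component_id[r],
                  plan$component_beg[r], plan$component_end[r],
                  plan$orientation[r])
    } else {
      fields <- c(plan$object[r], plan$object_beg[r], plan$object_end[r],
                  plan$part_number[r], plan$component_type[r],
                  plan$gap_length[r], plan$gap_type[r], plan$linkage[r],
                  plan$evidence[r])
    }
    writeLines(paste(fields, collapse = "\t"), con)
  }
  invisible(path)
}

#' Read an AGP v2.1 file
#'
#' @param path Path to an AGP file.
#' @return An `agp_plan` tibble.
#' @export
read_agp <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  rows <- lapply(parts, function(p) {
    gap <- p[5] %in% c("N", "U")
    tibble::tibble(
      object = p[1], object_beg = as.integer(p[2]),
      object_end = as.integer(p[3]), part_number = as.integer(p[4]),
      component_type = p[5],
      component_id = if (gap) NA_character_ else p[6],
      component_beg = if (gap) NA_integer_ else as.integer(p[7]),
      component_end = if (gap) NA_integer_ else as.integer(p[8]),
      orientation = if (gap) NA_character_ else p[9],
      gap_length = if (gap) as.integer(p[6]) else NA_integer_,
      gap_type = if (gap) p[7] else NA_character_,
      linkage = if (gap) p[8] else NA_character_,
      evidence = if (gap) p[9] else NA_character_)
  })
  new_agp_plan(dplyr::bind_rows(rows))
}

#' Build a fused reference genome
#'
#' Concatenates groups of chromosomes (in map order, separated by a
#' junction gap) into single fused sequences, passing untouched
#' chromosomes through -- e.g. collapsing a 9-chromosome relative onto a
#' 6-chromosome base karyotype by fusing 1+7, 2+4 and 5+6.  An exact
#' coordinate liftover table accompanies the fused genome.
#'
#' @param genome Named character vector or DNAStringSet.
#' @param fusion_map List of character vectors of chromosome names; each
#'   chromosome may appear at most once across the map.
#' @param gap_length Junction gap length in bp (default 100).
#' @return List with `genome` (fused, named character vector) and
#'   `liftover` (tibble: chromosome, start, end, new_chromosome,
#'   new_start, new_end).
#' @export
#' @examples
#' g <- setNames(rep(strrep("ACGT", 10), 3), c("c1", "c2", "c3"))
#' f <- build_fused_reference(g, list(c("c1", "c3")))
#' names(f$genome)
build_fused_reference <- function(genome, fusion_map, gap_length = 100) {
  genome <- as_seq_char(genome, "genome")
  used <- unlist(fusion_map)
  if (anyDuplicated(used))
    stop("a chromosome is referenced twice in the fusion map")
  miss <- setdiff(used, names(genome))
  if (length(miss))
    stop("fusion map references missing chromosomes: ",
         paste(miss, collapse = ", "))
  out <- character(0)
  lift <- list()
  for (members in fusion_map) {
    new_nm <- paste(members, collapse = "+")
    offset <- 0L
    pieces <- character(0)
    for (i in seq_along(members)) {
      if (i > 1) {
        pieces <- c(pieces, strrep("N", gap_length))
        offset <- offset + as.integer(gap_length)
      }
      len <- nchar(genome[[members[i]]])
      pieces <- c(pieces, genome[[members[i]]])
      lift[[length(lift) + 1]] <- tibble::tibble(
        chromosome = members[i], start = 1L, end = len,
        new_chromosome = new_nm, new_start = offset + 1L,
        new_end = offset + len)
      offset <- offset + len
    }
    out[[new_nm]] <- paste(pieces, collapse = "")
  }
  for (nm in setdiff(names(genome), used)) {
    out[[nm]] <- genome[[nm]]
    lift[[length(lift) + 1]] <- tibble::tibble(
      chromosome = nm, start = 1L, end = nchar(genome[[nm]]),
      new_chromosome = nm, new_start = 1L, new_end = nchar(genome[[nm]]))
  }
  list(genome = out, liftover = dplyr::bind_rows(lift))
}

#' Lift positions through a fusion liftover table
#'
#' @param liftover Liftover tibble from [build_fused_reference()].
#' @param chromosome,position Vectors of original chromosome names and
#'   1-based positions.
#' @return Tibble with `new_chromosome` and `new_position`.
#' @export
liftover_position <- function(liftover, chromosome, position) {
  i <- match(chromosome, liftover$chromosome)
  if (anyNA(i)) stop("position on a chromosome absent from the liftover")
  if (any(position < liftover$start[i] | position > liftover$end[i]))
    stop("position outside the lifted interval")
  tibble::tibble(new_chromosome = liftover$new_chromosome[i],
                 new_position = liftover$new_start[i] + position -
                   liftover$start[i])
}
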