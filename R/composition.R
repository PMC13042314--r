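#' Competitively assign read pairs to chromosomes
#'
#' Each pair is assigned to the single chromosome sharing the most
#' canonical k-mer windows summed over both mates ("top best" placement).
#' Pairs whose top score is below `min_shared` are unassigned.  Because
#' homoeologs diverge by several percent while alleles diverge far less,
#' reads sort predominantly into their subgenome of origin, making
#' per-subgenome read shares a readout of chromosome dosage.
#'
#' When several chromosomes tie for the top score (typically near-
#' identical haplotype copies), `ties = "random"` (default) picks one of
#' them by a deterministic hash -- the unbiased tie resolution of a "top
#' best" aligner, required for read shares to track chromosome dosage;
#' `ties = "unassign"` instead discards tied pairs, which is stricter but
#' systematically deflates subgenomes with more near-identical copies.
#'
#' @param read_pairs Tibble with columns `mate1` and `mate2` (e.g. from
#'   [simulate_reads()] or [read_fastq_pairs()]).
#' @param chromosomes Named character vector or DNAStringSet.
#' @param k Odd k-mer size for matching (default 21).
#' @param min_shared Minimum shared k-mer windows for assignment
#'   (default 10).
#' @param ties Tie handling: `"random"` (deterministic, dosage-unbiased)
#'   or `"unassign"`.
#' @return List with `counts` (tibble: chromosome, reads), `n_unassigned`
#'   and `n_pairs`.
#' @export
competitive_assign <- function(read_pairs, chromosomes, k = 21,
                               min_shared = 10,
                               ties = c("random", "unassign")) {
  ties <- match.arg(ties)
  chromosomes <- as_seq_char(chromosomes, "chromosomes")
  stopifnot(all(c("mate1", "mate2") %in% names(read_pairs)))
  if (k %% 2 == 0) stop("k must be odd")
  idx <- cpp_competitive_assign(read_pairs$mate1, read_pairs$mate2,
                                unname(chromosomes), as.integer(k),
                                as.integer(min_shared),
                                as.integer(ties == "random"))
  counts <- tabulate(idx, nbins = length(chromosomes))
  list(counts = tibble::tibble(chromosome = names(chromosomes),
                               reads = counts),
       n_unassigned = sum(idx == 0),
       n_pairs = length(idx))
}

#' Per-subgenome assigned-read percentages
#'
#' Collapses per-chromosome read counts onto subgenomes and reports the
#' percentage of assigned pairs per subgenome (half-up rounding to
#' `digits` decimals).  Unassigned pairs, when known, are carried through
#' as the `"unassigned"` attribute, not as a row.
#'
#' @param read_counts Output of [competitive_assign()], or a tibble with
#'   columns `chromosome` and `reads`, or a named vector of per-subgenome
#'   counts.
#' @param map Tibble mapping `chromosome` to `subgenome` (e.g.
#'   `tidy()` of a subgenome assignment).  Ignored when `read_counts` is
#'   already per-subgenome.
#' @param digits Decimal places (default 2).
#' @return Tibble with `subgenome`, `reads`, `percent`.
#' @export
#' @examples
#' coverage_table(c(A = 15646090, B = 31076742, C = 230974))
coverage_table <- function(read_counts, map = NULL, digits = 2) {
  unassigned <- NA_integer_
  if (is.list(read_counts) && !is.data.frame(read_counts) &&
      !is.null(read_counts$counts)) {
    unassigned <- read_counts$n_unassigned
    read_counts <- read_counts$counts
  }
  if (!is.data.frame(read_counts)) {
    stopifnot(is.numeric(read_counts), !is.null(names(read_counts)))
    tb <- tibble::tibble(subgenome = names(read_counts),
                         reads = as.numeric(read_counts))
  } else {
    stopifnot(!is.null(map))
    map <- if (inherits(map, "subgenome_assignment")) tidy(map) else
      tibble::as_tibble(map)
    miss <- setdiff(read_counts$chromosome, map$chromosome)
    if (length(miss))
      stop("chromosomes missing from the subgenome map: ",
           paste(head(miss, 5), collapse = ", "))
    tb <- read_counts |>
      dplyr::inner_join(map[, c("chromosome", "subgenome")],
                        by = "chromosome") |>
      dplyr::group_by(.data$subgenome) |>
      dplyr::summarise(reads = sum(.data$reads), .groups = "drop")
  }
  tb <- tb |>
    dplyr::arrange(.data$subgenome) |>
    dplyr::mutate(percent = round_half_up(
      100 * .data$reads / sum(.data$reads), digits))
  attr(tb, "unassigned") <- unassigned
  tb
}

#' Expected per-subgenome read proportions from chromosome counts
#'
#' The share of reads a subgenome should attract is its length-weighted
#' chromosome share; with equal chromosome lengths this is simply
#' counts/N (e.g. 14/48, 22/48, 12/48 -> 29%, 46%, 25% at 0 decimals).
#'
#' @param counts Named vector of per-subgenome chromosome counts, or a
#'   [polyploid_spec()].
#' @param lengths Optional named vector of representative chromosome
#'   lengths per subgenome (default equal).
#' @param digits Decimal places for half-up rounding (default 2).
#' @return Tibble with `subgenome` and `expected_percent`.
#' @export
#' @examples
#' expected_proportions(c(A = 14, B = 22, C = 12), digits = 0)
expected_proportions <- function(counts, lengths = NULL, digits = 2) {
  if (inherits(counts, "polyploid_spec")) {
    tot <- spec_totals(counts)
    counts <- setNames(tot$n, tot$ancestry)
  }
  stopifnot(is.numeric(counts), !is.null(names(counts)),
            all(counts >= 0))
  if (all(counts == 0)) stop("at least one count must be positive")
  w <- if (is.null(lengths)) rep(1, length(counts)) else
    unname(lengths[names(counts)])
  share <- counts * w / sum(counts * w)
  tibble::tibble(subgenome = names(counts),
                 expected_percent = unname(round_half_up(100 * share,
                                                         digits)))
}

#' Infer an integer chromosome composition from read proportions
#'
#' Fits non-negative integer per-subgenome chromosome counts summing to
#' `N` that minimise the L2 distance between `counts/N` and the observed
#' read fractions: largest-remainder apportionment followed by a +-1
#' local-search verification of optimality.  The result carries the
#' genome formula (e.g. `"AABBBB"`) and the dosage ratio (e.g. `"1A:2B"`).
#'
#' @param observed Named vector of observed per-subgenome percentages, or
#'   a [coverage_table()] tibble.
#' @param N Total chromosome number of the accession (e.g. 36 for a
#'   hexaploid with x = 6, 48 for an octoploid).
#' @param base_number Base chromosome number used for the formula string
#'   (default 6).
#' @return A `composition_estimate` object; see
#'   [tidy.composition_estimate()].
#' @export
#' @examples
#' infer_composition(c(A = 33.32, B = 66.19, C = 0.49), N = 36)
infer_composition <- function(observed, N, base_number = 6) {
  if (is.data.frame(observed))
    observed <- setNames(observed$percent, observed$subgenome)
  stopifnot(is.numeric(observed), !is.null(names(observed)), N >= 1)
  if (abs(sum(observed) - 100) > 1)
    stop("observed percentages must sum to 100 (+-1)")
  observed <- observed[order(names(observed))]
  frac <- observed / sum(observed)
  q <- frac * N
  counts <- floor(q)
  rem <- N - sum(counts)
  if (rem > 0) {
    give <- order(-(q - counts), -q)[seq_len(rem)]
    counts[give] <- counts[give] + 1
  }
  l2 <- function(ct) sum((100 * ct / N - observed)^2)
  repeat {
    best <- l2(counts); improved <- FALSE
    for (i in seq_along(counts)) for (j in seq_along(counts)) {
      if (i == j || counts[j] == 0) next
      cand <- counts
      cand[i] <- cand[i] + 1; cand[j] <- cand[j] - 1
      if (l2(cand) < best - 1e-12) {
        counts <- cand; best <- l2(cand); improved <- TRUE
      }
    }
    if (!improved) break
  }
  counts <- setNames(as.integer(counts), names(observed))
  fmt <- format_formula(counts, base_number)
  structure(list(observed = tibble::tibble(subgenome = names(observed),
                                           percent = unname(observed)),
                 counts = counts, N = as.integer(N),
                 base_number = base_number,
                 residual = sqrt(l2(counts)),
                 formula = fmt$formula, ratio = fmt$ratio),
            class = "composition_estimate")
}

#' @export
print.composition_estimate <- function(x, ...) {
  cat("<composition_estimate> N = ", x$N, ": ",
      paste0(x$counts, names(x$counts), collapse = " "),
      "  formula ", x$formula, "  ratio ", x$ratio,
      "  (residual ", signif(x$residual, 3), ")\n", sep = "")
  invisible(x)
}

#' Tidy a composition estimate
#'
#' @param x A `composition_estimate`.
#' @param ... Unused.
#' @return Tibble with per-subgenome observed percentage, fitted integer
#'   count and fitted percentage.
#' @export
tidy.composition_estimate <- function(x, ...) {
  x$observed |>
    dplyr::mutate(fitted_count = unname(x$counts),
                  fitted_percent = 100 * unname(x$counts) / x$N)
}

#' One-row summary of a composition estimate
#'
#' @param x A `composition_estimate`.
#' @param ... Unused.
#' @return Tibble with `N`, `formula`, `ratio`, `residual`.
#' @export
glance.composition_estimate <- function(x, ...) {
  tibble::tibble(N = x$N, formula = x$formula, ratio = x$ratio,
                 residual = x$residual)
}

#' Observed-versus-fitted composition barplot
#'
#' @param object A `composition_estimate`.
#' @param ... Unused.
#' @return A ggplot comparing observed read shares with the fitted
#'   integer-composition shares.
#' @export
autoplot.composition_estimate <- function(object, ...) {
  df <- tidy(object) |>
    tidyr::pivot_longer(c("percent", "fitted_percent"),
                        names_to = "kind", values_to = "value") |>
    dplyr::mutate(kind = ifelse(.data$kind == "percent",
                                "observed", "fitted"))
  ggplot2::ggplot(df, ggplot2::aes(.data$kind, .data$value,
                                   fill = .data$subgenome)) +
    ggplot2::geom_col(position = "stack", width = 0.6) +
    ggplot2::labs(x = NULL, y = "% of assigned read pairs",
                  fill = "Subgenome") +
    ggplot2::theme_minimal()
}

#' Format a chromosome composition as formula and ratio strings
#'
#' When every per-subgenome count is a multiple of the base number the
#' euploid letter-run formula is emitted (`(12, 24, 0)` with x = 6 ->
#' `"AABBBB"`); otherwise the aneuploid notation (`"14A 22B 12C"`).  The
#' ratio string divides counts by the smallest non-zero count, trimmed to
#' two decimals (`"1A:2B"`).
#'
#' @param counts Named non-negative integer vector per subgenome.
#' @param base_number Base chromosome number x (default 6).
#' @return List with `formula` and `ratio` strings.
#' @export
#' @examples
#' format_formula(c(A = 12, B = 24, C = 0))
#' format_formula(c(A = 14, B = 22, C = 12))
format_formula <- function(counts, base_number = 6) {
  stopifnot(is.numeric(counts), !is.null(names(counts)),
            all(counts >= 0))
  if (all(counts == 0)) stop("all-zero composition")
  counts <- counts[order(names(counts))]
  nz <- counts[counts > 0]
  formula <- if (all(counts %% base_number == 0)) {
    paste(rep(names(nz), nz / base_number), collapse = "")
  } else {
    paste0(nz, names(nz), collapse = " ")
  }
  r <- nz / min(nz)
  rs <- sub("\\.?0+$", "", sprintf("%.2f", r))
  list(formula = formula,
       ratio = paste0(rs, names(nz), collapse = ":"))
}
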