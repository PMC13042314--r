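#' Pairwise p-distance between the two LTRs of an element
#'
#' Proportion of mismatching sites over aligned non-gap columns.  Equal-
#' length sequences are compared site by site; unequal lengths are first
#' globally aligned.
#'
#' @param ltr5,ltr3 The 5' and 3' LTR sequences (character).
#' @return Mismatch proportion in `[0, 1]`.
#' @export
#' @examples
#' ltr_p_distance("AAAA", "AAAT")
ltr_p_distance <- function(ltr5, ltr3) {
  if (!nzchar(ltr5) || !nzchar(ltr3)) stop("empty LTR sequence")
  if (nchar(ltr5) == nchar(ltr3)) return(p_distance_chr(ltr5, ltr3))
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(ltr5), Biostrings::DNAString(ltr3),
    type = "global")
  nm <- Biostrings::nmatch(aln)
  nmm <- Biostrings::nmismatch(aln)
  if (nm + nmm == 0) stop("no aligned columns between the LTRs")
  nmm / (nm + nmm)
}

#' Jukes-Cantor correction of a p-distance
#'
#' d = -(3/4) ln(1 - 4p/3), the substitutions-per-site estimate
#' accounting for multiple hits.  Valid for p < 0.75 (saturation).
#'
#' @param p Observed mismatch proportion(s).
#' @return Corrected distance(s) d, substitutions/site.
#' @export
#' @examples
#' jc_correct(0.1)
jc_correct <- function(p) {
  if (any(p < 0 | p >= 0.75))
    stop("p must be in [0, 0.75): the Jukes-Cantor correction ",
         "saturates at 0.75")
  -0.75 * log(1 - 4 * p / 3)
}

#' Kimura 2-parameter distance from aligned LTRs
#'
#' Alternative to [jc_correct()] distinguishing transitions and
#' transversions: d = 0.5 ln(1/(1-2P-Q)) + 0.25 ln(1/(1-2Q)).
#'
#' @param ltr5,ltr3 Equal-length aligned LTR sequences.
#' @return Distance in substitutions/site.
#' @export
k2p_distance <- function(ltr5, ltr3) {
  a <- strsplit(toupper(ltr5), "")[[1]]
  b <- strsplit(toupper(ltr3), "")[[1]]
  stopifnot(length(a) == length(b))
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  a <- a[ok]; b <- b[ok]
  purine <- c("A", "G")
  ts <- mean(a != b & (a %in% purine) == (b %in% purine))
  tv <- mean(a != b & (a %in% purine) != (b %in% purine))
  if (1 - 2 * ts - tv <= 0 || 1 - 2 * tv <= 0)
    stop("K2P distance saturated")
  0.5 * log(1 / (1 - 2 * ts - tv)) + 0.25 * log(1 / (1 - 2 * tv))
}

#' Insertion age from LTR divergence
#'
#' The two LTRs are identical on insertion and diverge independently, so
#' T = d / (2 mu) with d the corrected per-LTR-pair distance and mu the
#' substitution rate per site per year.
#'
#' @param d Corrected distance(s), substitutions/site.
#' @param mu Substitution rate per site per year (default 1.3e-8, a
#'   common grass rate).
#' @return Age(s) in years.
#' @export
#' @examples
#' insertion_age(0.026, 1.3e-8)  # 1 Myr
insertion_age <- function(d, mu = 1.3e-8) {
  if (mu <= 0) stop("mu must be positive")
  d / (2 * mu)
}

#' Estimate insertion ages for a table of LTR elements
#'
#' @param elements Tibble with columns `element`, `family`, `chromosome`,
#'   `ltr5`, `ltr3` (see [extract_ltr_elements()]).
#' @param mu Substitution rate per site per year.
#' @param model Distance correction, `"JC"` (default) or `"K2P"`.
#' @return The input tibble (minus sequences) with `p_distance`,
#'   `distance`, `age_years` and `age_myr` columns.
#' @export
estimate_ltr_ages <- function(elements, mu = 1.3e-8,
                              model = c("JC", "K2P")) {
  model <- match.arg(model)
  stopifnot(all(c("element", "family", "chromosome", "ltr5", "ltr3")
                %in% names(elements)))
  p <- mapply(ltr_p_distance, elements$ltr5, elements$ltr3)
  d <- if (model == "JC") jc_correct(p) else
    mapply(k2p_distance, elements$ltr5, elements$ltr3)
  elements |>
    dplyr::select(-dplyr::any_of(c("ltr5", "ltr3"))) |>
    dplyr::mutate(p_distance = unname(p), distance = unname(d),
                  age_years = insertion_age(.data$distance, mu),
                  age_myr = .data$age_years / 1e6)
}

#' Extract LTR elements from a polyploid's repeat truth
#'
#' Slices the 5' and 3' LTR sequences of every recorded repeat insertion
#' out of the composed chromosome sequences, yielding the element table
#' the dating functions consume.  Note that haplotype-level mutation
#' applied during composition adds ~2 x haplotype divergence to each LTR
#' pair's distance on top of its age signal.
#'
#' @param polyploid A `polyploid` composed with repeat insertions.
#' @return Tibble with `element`, `family`, `chromosome`, `ltr5`, `ltr3`
#'   and the true `age_myr`.
#' @export
extract_ltr_elements <- function(polyploid) {
  stopifnot(inherits(polyploid, "polyploid"))
  rp <- polyploid$truth$repeats
  if (is.null(rp) || nrow(rp) == 0)
    stop("polyploid carries no repeat insertion truth")
  seqs <- polyploid$seqs[rp$chromosome]
  tibble::tibble(
    element = sprintf("ltr%05d", seq_len(nrow(rp))),
    family = rp$family,
    chromosome = rp$chromosome,
    ltr5 = substring(seqs, rp$start, rp$start + rp$ltr_length - 1L),
    ltr3 = substring(seqs, rp$end - rp$ltr_length + 1L, rp$end),
    age_myr = rp$age_myr)
}

#' Per-subgenome insertion-age profile
#'
#' Dates every element, attributes it to the subgenome of its chromosome,
#' and returns binned age distributions plus per-subgenome summaries --
#' the per-subgenome age spectrum that distinguishes recently associated
#' ancestries (overlapping young peaks) from a long-isolated one (older
#' insertions).
#'
#' @param elements LTR element tibble (with `ltr5`/`ltr3`).
#' @param assignment A `subgenome_assignment` or a tibble with
#'   `chromosome` and `subgenome` columns.
#' @param mu Substitution rate per site per year.
#' @param bins Number of age bins spanning the observed range.
#' @param model Distance correction passed to [estimate_ltr_ages()].
#' @return An `age_profile` object: list with `ages` (per-element tibble),
#'   `profile` (tibble: subgenome, bin_mid, n) and `summary` (tibble:
#'   subgenome, n, mean/median age in Myr).
#' @export
subgenome_age_profile <- function(elements, assignment, mu = 1.3e-8,
                                  bins = 20, model = "JC") {
  map <- if (inherits(assignment, "subgenome_assignment"))
    tidy(assignment) else tibble::as_tibble(assignment)
  stopifnot(all(c("chromosome", "subgenome") %in% names(map)))
  miss <- setdiff(unique(elements$chromosome), map$chromosome)
  if (length(miss))
    stop("elements on chromosomes without a subgenome label: ",
         paste(head(miss, 5), collapse = ", "))
  ages <- estimate_ltr_ages(elements, mu = mu, model = model) |>
    dplyr::inner_join(map[, c("chromosome", "subgenome")],
                      by = "chromosome")
  breaks <- seq(0, max(ages$age_myr) * (1 + 1e-9) + 1e-12,
                length.out = bins + 1)
  profile <- ages |>
    dplyr::mutate(bin = cut(.data$age_myr, breaks, include.lowest = TRUE,
                            labels = FALSE)) |>
    dplyr::count(.data$subgenome, .data$bin, name = "n") |>
    dplyr::mutate(bin_mid = (breaks[.data$bin] + breaks[.data$bin + 1]) / 2)
  summary <- ages |>
    dplyr::group_by(.data$subgenome) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_age_myr = mean(.data$age_myr),
                     median_age_myr = median(.data$age_myr),
                     .groups = "drop")
  structure(list(ages = ages, profile = profile, summary = summary,
                 mu = mu, breaks = breaks),
            class = "age_profile")
}

#' @export
print.age_profile <- function(x, ...) {
  cat("<age_profile> ", nrow(x$ages), " elements, mu = ", x$mu, "\n",
      sep = "")
  print(x$summary)
  invisible(x)
}

#' Insertion-age distribution plot per subgenome
#'
#' @param object An `age_profile`.
#' @param ... Unused.
#' @return A ggplot of per-subgenome age densities.
#' @export
autoplot.age_profile <- function(object, ...) {
  ggplot2::ggplot(object$ages,
                  ggplot2::aes(.data$age_myr, fill = .data$subgenome)) +
    ggplot2::geom_histogram(breaks = object$breaks, alpha = 0.6,
                            position = "identity") +
    ggplot2::labs(x = "Insertion age (Myr)", y = "Elements",
                  fill = "Subgenome") +
    ggplot2::theme_minimal()
}

#' Repeat-family enrichment per subgenome
#'
#' For every family x subgenome cell, the hypergeometric upper-tail
#' probability of seeing at least the observed number of family members
#' on that subgenome, given the family's total size and the subgenome's
#' element share (equivalently, the null that family labels are permuted
#' at random among elements).  P-values are Benjamini-Hochberg adjusted
#' across all cells.
#'
#' @param elements Element tibble with `element`, `family`, `chromosome`.
#' @param assignment A `subgenome_assignment` or `chromosome`/`subgenome`
#'   tibble.
#' @return Tibble with per-cell counts, expected counts, `p_value` and
#'   `p_adjusted`.
#' @export
family_enrichment <- function(elements, assignment) {
  if (nrow(elements) < 1) stop("need at least one element")
  map <- if (inherits(assignment, "subgenome_assignment"))
    tidy(assignment) else tibble::as_tibble(assignment)
  el <- elements |>
    dplyr::inner_join(map[, c("chromosome", "subgenome")],
                      by = "chromosome")
  if (nrow(el) < nrow(elements))
    stop("elements on chromosomes without a subgenome label")
  N <- nrow(el)
  fam_tot <- dplyr::count(el, .data$family, name = "n_family")
  sg_tot <- dplyr::count(el, .data$subgenome, name = "n_subgenome")
  grid <- tidyr::expand_grid(family = fam_tot$family,
                             subgenome = sg_tot$subgenome) |>
    dplyr::left_join(fam_tot, by = "family") |>
    dplyr::left_join(sg_tot, by = "subgenome") |>
    dplyr::left_join(dplyr::count(el, .data$family, .data$subgenome,
                                  name = "count"),
                     by = c("family", "subgenome")) |>
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0L),
                  expected = .data$n_family * .data$n_subgenome / N,
                  p_value = phyper(.data$count - 1, .data$n_subgenome,
                                   N - .data$n_subgenome, .data$n_family,
                                   lower.tail = FALSE))
  grid$p_adjusted <- p.adjust(grid$p_value, method = "BH")
  grid
}
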