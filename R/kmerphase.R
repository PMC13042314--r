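#' Count canonical k-mers per chromosome
#'
#' Builds the chromosomes-by-k-mers matrix that differential k-mer analysis
#' operates on.  K-mers are canonicalised (lexicographic minimum of the
#' k-mer and its reverse complement), windows containing ambiguous bases
#' are skipped, and counts are normalised to occurrences per Mb so
#' chromosomes of different lengths are comparable.
#'
#' @param sequences Named character vector or DNAStringSet of chromosome
#'   sequences.
#' @param k Odd k-mer size; 11-31 is the sensible range for subgenome
#'   phasing (default 15).  For `k <= 25` columns are named by the exact
#'   integer code of the canonical k-mer (decode with [decode_kmers()]);
#'   for `k >= 27` columns are the k-mer strings themselves.
#' @return A `kmer_matrix` object wrapping a sparse matrix (`$counts`,
#'   rows = chromosomes, columns = canonical k-mers, per-Mb counts), plus
#'   `$k` and `$lengths`.
#' @export
#' @examples
#' m <- count_kmers(c(chrX = "ACGTACGTACGT"), k = 3)
#' sum(m$counts) * nchar("ACGTACGTACGT") / 1e6  # raw windows = L - k + 1
count_kmers <- function(sequences, k = 15) {
  sequences <- as_seq_char(sequences)
  k <- as.integer(k)
  if (k %% 2 == 0) stop("k must be odd so canonicalisation is well-defined")
  if (k < 3 || k > 31) stop("k must be in [3, 31]")
  lens <- nchar(sequences)
  per <- cpp_kmer_counts(sequences, k)
  codes <- lapply(per, `[[`, "codes")
  counts <- lapply(per, `[[`, "counts")
  all_codes <- sort(unique(unlist(codes)))
  if (length(all_codes) == 0) stop("no unambiguous k-mer windows found")
  i <- rep(seq_along(per), lengths(codes))
  j <- match(unlist(codes), all_codes)
  x <- unlist(counts) / rep(lens, lengths(codes)) * 1e6
  colnames_chr <- if (k <= 25) sprintf("%.0f", all_codes) else
    as.character(cpp_decode_kmers(all_codes, k))
  mat <- Matrix::sparseMatrix(
    i = i, j = j, x = x,
    dims = c(length(sequences), length(all_codes)),
    dimnames = list(names(sequences), colnames_chr))
  structure(list(counts = mat, k = k, lengths = lens),
            class = "kmer_matrix")
}

#' @export
print.kmer_matrix <- function(x, ...) {
  cat("<kmer_matrix> ", nrow(x$counts), " chromosomes x ",
      ncol(x$counts), " canonical ", x$k, "-mers (per-Mb counts)\n",
      sep = "")
  invisible(x)
}

#' Decode integer k-mer codes back to sequences
#'
#' @param codes Character or numeric vector of k-mer column ids as produced
#'   by [count_kmers()] with `k <= 25`.
#' @param k The k-mer size.
#' @return Character vector of k-mer sequences.
#' @export
#' @examples
#' decode_kmers(colnames(count_kmers(c(s = "ACGTT"), k = 3)$counts), 3)
decode_kmers <- function(codes, k) {
  cpp_decode_kmers(as.numeric(codes), as.integer(k))
}

#' Find differential k-mers between provisional chromosome clusters
#'
#' A k-mer is differential when its highest cluster-mean normalised count
#' is at least `fold_q` times the second-highest cluster mean and at least
#' `min_count` per Mb.  Differential k-mers mark the cluster (ancestry)
#' they are enriched in; k-mers private to single haplotypes are removed by
#' the `min_count` floor because they dilute across the cluster mean.
#'
#' @param object A `kmer_matrix`.
#' @param groups Named vector mapping every chromosome to a cluster label.
#' @param fold_q Minimum fold change between best and second-best cluster
#'   mean (> 1; default 2).
#' @param min_count Minimum best cluster-mean count per Mb (default 2).
#' @return Tibble with columns `kmer`, `label` (enriched cluster),
#'   `top_mean`, `second_mean` and `score` (fold enrichment, `Inf` when the
#'   k-mer is absent outside its cluster), ordered by decreasing score then
#'   abundance.
#' @export
find_differential_kmers <- function(object, groups, fold_q = 2,
                                    min_count = 2) {
  stopifnot(inherits(object, "kmer_matrix"))
  if (fold_q <= 1) stop("fold_q must be greater than 1")
  X <- object$counts
  if (is.null(names(groups))) names(groups) <- rownames(X)
  if (!setequal(names(groups), rownames(X)))
    stop("groups must label exactly the chromosomes of the matrix")
  groups <- groups[rownames(X)]
  labs <- sort(unique(as.character(groups)))
  if (length(labs) < 2) stop("need at least 2 clusters")
  sizes <- table(factor(groups, labs))
  if (any(sizes == 0)) stop("every cluster must contain a chromosome")
  ind <- Matrix::sparseMatrix(
    i = match(groups, labs), j = seq_along(groups),
    x = 1 / as.numeric(sizes)[match(groups, labs)],
    dims = c(length(labs), length(groups)))
  means <- as.matrix(ind %*% X)  # clusters x kmers
  top <- means[1, ]; top_lab <- rep(1L, ncol(means))
  for (g in seq_len(nrow(means))[-1]) {
    hit <- means[g, ] > top
    top_lab[hit] <- g
    top <- pmax(top, means[g, ])
  }
  second <- rep(-Inf, ncol(means))
  for (g in seq_len(nrow(means))) {
    v <- means[g, ]
    v[top_lab == g] <- -Inf
    second <- pmax(second, v)
  }
  second[!is.finite(second)] <- 0
  keep <- top >= fold_q * second & top >= min_count
  out <- tibble::tibble(
    kmer = colnames(means)[keep],
    label = labs[top_lab[keep]],
    top_mean = top[keep],
    second_mean = second[keep],
    score = ifelse(second[keep] > 0, top[keep] / second[keep], Inf))
  dplyr::arrange(out, dplyr::desc(.data$score), dplyr::desc(.data$top_mean))
}

#' Phase chromosomes into subgenomes by iterative differential k-mer
#' clustering
#'
#' Starting from a centroid clustering of the highest-variance k-mers,
#' alternates (a) recomputing differential k-mers from the current clusters
#' and (b) re-clustering chromosomes on the differential submatrix, until
#' the partition stabilises.  Emits subgenome labels, an average-linkage
#' dendrogram on the Jaccard distance of differential k-mer
#' presence/absence, a 2-axis principal-component ordination and per-
#' chromosome silhouette widths.
#'
#' Cluster labels are letters assigned by order of first appearance along
#' the input chromosome order; the partition itself is invariant to
#' relabelling.
#'
#' @param object A `kmer_matrix` (or sequences, which are counted with the
#'   default k).
#' @param K Number of subgenomes (default 3).
#' @param seed Integer seed for the centroid restarts.
#' @param max_iter Maximum refinement iterations.
#' @param fold_q,min_count Differential k-mer thresholds, see
#'   [find_differential_kmers()].
#' @param n_init_kmers Number of top-variance k-mers for the initial
#'   clustering (default 10000).
#' @param max_cluster_kmers Cap on differential k-mers used for clustering,
#'   ordination and the dendrogram (top of the enrichment ordering;
#'   default 50000).
#' @return A `subgenome_assignment` object; see [tidy.subgenome_assignment()].
#' @export
phase_subgenomes <- function(object, K = 3, seed = 1, max_iter = 10,
                             fold_q = 2, min_count = 2,
                             n_init_kmers = 10000,
                             max_cluster_kmers = 50000) {
  if (!inherits(object, "kmer_matrix")) object <- count_kmers(object)
  X <- object$counts
  n <- nrow(X)
  if (K < 2) stop("K must be at least 2")
  if (n < K) stop("need at least K chromosomes")
  set.seed(seed)
  m1 <- Matrix::colMeans(X)
  v <- Matrix::colMeans(X^2) - m1^2
  idx <- head(order(v, decreasing = TRUE), n_init_kmers)
  sub <- as.matrix(X[, idx, drop = FALSE])
  cl <- kmeans_rows(sub, K)
  converged <- FALSE
  iter <- 0L
  diff <- NULL
  for (iter in seq_len(max_iter)) {
    diff <- find_differential_kmers(object, setNames(cl, rownames(X)),
                                    fold_q = fold_q, min_count = min_count)
    if (nrow(diff) == 0)
      stop("no differential k-mers under fold_q = ", fold_q,
           ", min_count = ", min_count, "; lower fold_q or min_count")
    sel <- head(diff$kmer, max_cluster_kmers)
    sub <- as.matrix(X[, sel, drop = FALSE])
    cl_new <- kmeans_rows(sub, K)
    if (same_partition(cl, cl_new)) {
      cl <- cl_new
      converged <- TRUE
      break
    }
    cl <- cl_new
  }
  if (!converged)
    warning("subgenome labels did not stabilise after ", max_iter,
            " iterations; returning last labels (flagged unstable)")
  # letters by order of first appearance
  first <- match(unique(cl), cl)
  lab_map <- setNames(LETTERS[seq_len(K)], cl[sort(first)])
  labels <- unname(lab_map[as.character(cl)])
  # silhouette on the clustered submatrix
  sil <- rep(NA_real_, n)
  if (n > K) {
    s <- cluster::silhouette(as.integer(factor(labels)), dist(sub))
    sil <- s[, "sil_width"]
  }
  pres <- sub > 0
  hc <- hclust(dist(pres, method = "binary"), method = "average")
  pc <- prcomp(sub, center = TRUE, rank. = 2)
  ord <- tibble::tibble(chromosome = rownames(X),
                        PC1 = unname(pc$x[, 1]),
                        PC2 = if (ncol(pc$x) > 1) unname(pc$x[, 2]) else 0)
  diff$label <- unname(lab_map[as.character(diff$label)])
  structure(
    list(labels = tibble::tibble(chromosome = rownames(X),
                                 subgenome = labels,
                                 silhouette = sil),
         diff_kmers = diff,
         clustered_kmers = sel,
         heatmap_matrix = sub[, head(seq_along(sel), 1000), drop = FALSE],
         dendrogram = hc,
         ordination = ord,
         k = object$k, K = K,
         iterations = iter, converged = converged),
    class = "subgenome_assignment")
}

# kmeans that tolerates duplicated rows (clusters the distinct rows, then
# assigns every row to the nearest centre)
kmeans_rows <- function(x, K, nstart = 10) {
  ux <- unique(x)
  if (nrow(ux) < K)
    stop("fewer distinct chromosomes than K clusters")
  centers <- if (nrow(ux) == K) ux else
    kmeans(ux, centers = K, nstart = nstart, iter.max = 100)$centers
  d2 <- vapply(seq_len(K), function(j)
    colSums((t(x) - centers[j, ])^2), numeric(nrow(x)))
  max.col(-d2, ties.method = "first")
}

same_partition <- function(a, b) {
  all(outer(a, a, "==") == outer(b, b, "=="))
}

#' @export
print.subgenome_assignment <- function(x, ...) {
  cat("<subgenome_assignment> ", nrow(x$labels), " chromosomes -> ",
      x$K, " subgenomes (", paste(
        capture_counts(x$labels$subgenome), collapse = " "), "); ",
      nrow(x$diff_kmers), " differential ", x$k, "-mers; ",
      if (x$converged) paste0("converged in ", x$iterations, " iteration(s)")
      else "NOT converged", "\n", sep = "")
  invisible(x)
}

capture_counts <- function(labels) {
  tb <- table(labels)
  paste0(as.integer(tb), names(tb))
}

#' Tidy a subgenome assignment
#'
#' @param x A `subgenome_assignment`.
#' @param ... Unused.
#' @return Tibble with one row per chromosome: `chromosome`, `subgenome`,
#'   `silhouette`.
#' @export
tidy.subgenome_assignment <- function(x, ...) x$labels

#' One-row summary of a subgenome assignment
#'
#' @param x A `subgenome_assignment`.
#' @param ... Unused.
#' @return Tibble with `n_chromosomes`, `K`, `n_differential_kmers`, `k`,
#'   `iterations`, `converged`, `mean_silhouette`.
#' @export
glance.subgenome_assignment <- function(x, ...) {
  tibble::tibble(n_chromosomes = nrow(x$labels), K = x$K,
                 n_differential_kmers = nrow(x$diff_kmers), k = x$k,
                 iterations = x$iterations, converged = x$converged,
                 mean_silhouette = mean(x$labels$silhouette))
}

#' Ordination plot of a subgenome assignment
#'
#' @param object A `subgenome_assignment`.
#' @param ... Unused.
#' @return A ggplot: chromosomes on the first two principal axes of the
#'   differential k-mer submatrix, coloured by subgenome.
#' @export
autoplot.subgenome_assignment <- function(object, ...) {
  df <- dplyr::left_join(object$ordination, object$labels,
                         by = "chromosome")
  ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2,
                                   colour = .data$subgenome)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(colour = "Subgenome",
                  title = "Differential k-mer ordination") +
    ggplot2::theme_minimal()
}

#' Write report tables (and plots) for a subgenome assignment
#'
#' Writes TSVs of labels, ordination coordinates, differential k-mers and
#' a heatmap-ready presence/absence matrix of the top differential k-mers,
#' plus PDF plots of the ordination and dendrogram.
#'
#' @param assignment A `subgenome_assignment`.
#' @param out_prefix Path prefix for output files.
#' @param heatmap_kmers Number of top differential k-mers in the heatmap
#'   table (default 1000).
#' @param plots Write PDF plots as well (default TRUE).
#' @return Named character vector of the paths written, invisibly.
#' @export
assignment_report <- function(assignment, out_prefix,
                              heatmap_kmers = 1000, plots = TRUE) {
  stopifnot(inherits(assignment, "subgenome_assignment"))
  if (nrow(assignment$diff_kmers) == 0)
    stop("assignment has an empty differential k-mer set; ",
         "re-run phasing with a lower fold_q or min_count")
  paths <- c(labels = paste0(out_prefix, "_labels.tsv"),
             ordination = paste0(out_prefix, "_ordination.tsv"),
             diff_kmers = paste0(out_prefix, "_diff_kmers.tsv"),
             heatmap = paste0(out_prefix, "_heatmap.tsv"))
  readr::write_tsv(assignment$labels, paths["labels"])
  readr::write_tsv(assignment$ordination, paths["ordination"])
  readr::write_tsv(assignment$diff_kmers, paths["diff_kmers"])
  hmat <- assignment$heatmap_matrix
  hmat <- hmat[, head(seq_len(ncol(hmat)), heatmap_kmers), drop = FALSE]
  hm <- dplyr::bind_cols(
    tibble::tibble(chromosome = assignment$labels$chromosome),
    tibble::as_tibble(as.data.frame(hmat)))
  readr::write_tsv(hm, paths["heatmap"])
  if (plots) {
    paths <- c(paths,
               ordination_plot = paste0(out_prefix, "_ordination.pdf"),
               dendrogram_plot = paste0(out_prefix, "_dendrogram.pdf"))
    ggplot2::ggsave(paths[["ordination_plot"]], autoplot(assignment),
                    width = 6, height = 4)
    grDevices::pdf(paths[["dendrogram_plot"]], width = 8, height = 5)
    plot(assignment$dendrogram,
         main = "Differential k-mer dendrogram (Jaccard, average linkage)")
    grDevices::dev.off()
  }
  invisible(paths)
}
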