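# Feature-selection evaluation: classification quality (weighted F1 of a
# KNN classifier) and fraction of total variance explained for top-n gene
# sets.

#' Fraction of total variance explained by a gene subset
#'
#' Sum of per-gene variances over the selected genes divided by the sum over
#' all genes. Computed on raw counts by default; set `log1p = TRUE` to
#' compute both sums on log1p-transformed counts.
#'
#' @param mat a [cell_counts] object or count matrix.
#' @param selected_genes character vector of gene names (must be a subset of
#'   the matrix's genes).
#' @param log1p compute variances on log1p counts.
#' @return A single number in \[0, 1\]; an empty selection returns 0 with a
#'   warning.
#' @export
fraction_variance <- function(mat, selected_genes, log1p = FALSE) {
  X <- as_count_matrix(mat)
  if (log1p) X <- log1p(X)
  genes <- colnames(X)
  if (is.null(genes)) stop("count matrix must carry gene names")
  if (!length(selected_genes)) {
    warning("empty gene selection: fraction of variance is 0")
    return(0.0)
  }
  missing <- setdiff(selected_genes, genes)
  if (length(missing))
    stop("selected genes not in the matrix, e.g. ", missing[1])
  v <- apply(X, 2, stats::var)
  sum(v[genes %in% selected_genes]) / sum(v)
}

#' Weighted F1 of a KNN classifier on selected genes
#'
#' Stratified 80/20 train/test split, K-nearest-neighbour classification
#' (k = 15, Euclidean) on the selected gene columns, scored by weighted F1
#' on the held-out 20%. Deterministic given `split_seed`.
#'
#' @inheritParams fraction_variance
#' @param labels per-cell labels (>= 2 classes, >= 2 cells per class).
#' @param split_seed integer seed for the split.
#' @param k number of neighbours (default 15).
#' @return Weighted F1 on the held-out split.
#' @export
knn_f1 <- function(mat, labels, selected_genes, split_seed = 1L, k = 15L) {
  X <- as_count_matrix(mat)
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(X))
  if (length(unique(labels)) < 2) stop("knn_f1 needs >= 2 classes")
  if (min(table(labels)) < 2)
    stop("every class needs >= 2 cells for a stratified split")
  genes <- colnames(X)
  if (!all(selected_genes %in% genes))
    stop("selected genes not in the matrix")
  Xs <- X[, genes %in% selected_genes, drop = FALSE]
  split <- stratified_split(labels, 0.8, derive_seed(split_seed, 3L))
  k_use <- min(k, length(split$train))
  pred <- with_seed(derive_seed(split_seed, 4L),
                    class::knn(Xs[split$train, , drop = FALSE],
                               Xs[split$test, , drop = FALSE],
                               cl = factor(labels[split$train]), k = k_use))
  weighted_f1(labels[split$test], as.character(pred))
}

#' Feature-selection evaluation curve
#'
#' For each n in `n_list`, takes the top-n genes of a marker ranking and
#' reports the KNN weighted F1 and the fraction of total variance explained,
#' plus a baseline row using every gene.
#'
#' @inheritParams knn_f1
#' @param ranking a `cellattn_markers` data.frame (see [global_markers]) or
#'   a character vector of genes in ranked order.
#' @param n_list sizes of the nested top-n gene sets, sorted ascending
#'   (default `c(10, 25, 50, 100, 200, 300)` truncated to the ranking
#'   length).
#' @param log1p compute variance fractions on log1p counts.
#' @return data.frame of class `cellattn_feature_eval` with columns `n`,
#'   `weighted_f1`, `fraction_variance`; the last row (`n` = all genes) is
#'   the full-gene-space baseline. Metadata attribute `"log1p"` records the
#'   variance transform.
#' @export
feature_curve <- function(mat, labels, ranking,
                          n_list = c(10L, 25L, 50L, 100L, 200L, 300L),
                          split_seed = 1L, k = 15L, log1p = FALSE) {
  X <- as_count_matrix(mat)
  genes_ranked <- if (is.data.frame(ranking)) ranking$gene else as.character(ranking)
  n_list <- sort(unique(as.integer(n_list)))
  if (max(n_list) > length(genes_ranked))
    stop("max(n_list) (", max(n_list), ") exceeds the ranking length (",
         length(genes_ranked), ")")
  rows <- lapply(n_list, function(n) {
    sel <- genes_ranked[seq_len(n)]
    data.frame(n = n,
               weighted_f1 = knn_f1(X, labels, sel, split_seed, k),
               fraction_variance = fraction_variance(X, sel, log1p))
  })
  all_genes <- colnames(X)
  rows <- c(rows, list(data.frame(
    n = length(all_genes),
    weighted_f1 = knn_f1(X, labels, all_genes, split_seed, k),
    fraction_variance = fraction_variance(X, all_genes, log1p))))
  out <- do.call(rbind, rows)
  attr(out, "log1p") <- log1p
  class(out) <- c("cellattn_feature_eval", "data.frame")
  out
}
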