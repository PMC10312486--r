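#' Quality-control configuration
#'
#' Default thresholds follow standard scRNA-seq practice: keep cells
#' expressing at least 200 genes with strictly less than 10% mitochondrial
#' reads, genes expressed in at least 3 cells, label classes with at least
#' 100 cells, and the top 5000 highly variable genes.
#'
#' @param min_genes_per_cell minimum expressed genes per retained cell.
#' @param min_cells_per_gene minimum expressing cells per retained gene
#'   (evaluated after cell filtering).
#' @param max_mito_fraction cells with a mitochondrial read fraction at or
#'   above this value are removed (strict `<` keeps).
#' @param min_cells_per_class labeled classes below this size are dropped.
#' @param n_hvg number of highly variable genes for [select_hvg].
#' @param mito_prefixes gene-name prefixes identifying mitochondrial genes.
#' @return A list of class `cellattn_qc_config`.
#' @export
qc_config <- function(min_genes_per_cell = 200L, min_cells_per_gene = 3L,
                      max_mito_fraction = 0.10, min_cells_per_class = 100L,
                      n_hvg = 5000L, mito_prefixes = c("MT-", "mt-")) {
  stopifnot(min_genes_per_cell >= 0, min_cells_per_gene >= 0,
            max_mito_fraction >= 0, max_mito_fraction <= 1,
            min_cells_per_class >= 0, n_hvg >= 1)
  structure(list(min_genes_per_cell = as.integer(min_genes_per_cell),
                 min_cells_per_gene = as.integer(min_cells_per_gene),
                 max_mito_fraction = max_mito_fraction,
                 min_cells_per_class = as.integer(min_cells_per_class),
                 n_hvg = as.integer(n_hvg),
                 mito_prefixes = mito_prefixes),
            class = "cellattn_qc_config")
}

#' Filter a count matrix by QC rules
#'
#' Rules are applied in a fixed, documented order: (1) cells expressing
#' fewer than `min_genes_per_cell` genes are removed; (2) of the remaining
#' cells, those with a mitochondrial read fraction `>= max_mito_fraction`
#' are removed; (3) genes expressed in fewer than `min_cells_per_gene` of
#' the remaining cells are removed; (4) if labels are present, classes with
#' fewer than `min_cells_per_class` cells are removed. Mitochondrial genes
#' are identified by name prefix; genes without a recognized prefix
#' contribute zero to the mitochondrial fraction.
#'
#' @param mat a [cell_counts] object.
#' @param cfg a [qc_config].
#' @return List with `data` (the filtered [cell_counts]) and `report`
#'   (per-rule removal counts: `cells_removed_min_genes`,
#'   `cells_removed_mito`, `genes_removed`, `classes_removed`,
#'   `cells_removed_class`).
#' @export
filter_counts <- function(mat, cfg = qc_config()) {
  stopifnot(inherits(mat, "cell_counts"))
  counts <- mat$counts
  report <- list()

  expressed <- rowSums(counts > 0)
  keep1 <- expressed >= cfg$min_genes_per_cell
  report$cells_removed_min_genes <- sum(!keep1)
  counts1 <- counts[keep1, , drop = FALSE]
  if (nrow(counts1) == 0) stop("no cells survive the min-genes QC rule")

  mito <- Reduce(`|`, lapply(cfg$mito_prefixes,
                             function(p) startsWith(colnames(counts1), p)))
  total <- rowSums(counts1)
  mito_frac <- ifelse(total > 0, rowSums(counts1[, mito, drop = FALSE]) / total, 0)
  keep2 <- mito_frac < cfg$max_mito_fraction
  report$cells_removed_mito <- sum(!keep2)
  counts2 <- counts1[keep2, , drop = FALSE]
  if (nrow(counts2) == 0) stop("no cells survive the mitochondrial QC rule")

  gene_keep <- colSums(counts2 > 0) >= cfg$min_cells_per_gene
  report$genes_removed <- sum(!gene_keep)
  counts3 <- counts2[, gene_keep, drop = FALSE]
  if (ncol(counts3) == 0) stop("no genes survive QC")

  labels <- mat$labels
  if (!is.null(labels)) labels <- labels[mat$cell_ids %in% rownames(counts3)]
  if (!is.null(labels)) {
    tab <- table(labels)
    keep_classes <- names(tab)[tab >= cfg$min_cells_per_class]
    report$classes_removed <- length(tab) - length(keep_classes)
    keep4 <- labels %in% keep_classes
    report$cells_removed_class <- sum(!keep4)
    counts3 <- counts3[keep4, , drop = FALSE]
    labels <- labels[keep4]
    if (nrow(counts3) == 0)
      stop("no cells survive QC: every label class is below min_cells_per_class")
  } else {
    report$classes_removed <- 0L
    report$cells_removed_class <- 0L
  }
  list(data = cell_counts(counts3, colnames(counts3), rownames(counts3),
                          labels),
       report = report)
}

#' Select highly variable genes
#'
#' Ranks genes by a standardized-variance criterion in the style of the vst
#' method: per-gene means and variances are computed on raw counts, a
#' quadratic polynomial trend of log10(variance) on log10(mean) predicts the
#' expected variance, counts are standardized by the trend sd and clipped at
#' sqrt(C), and genes are ranked by the variance of the clipped standardized
#' values (descending, ties broken by gene index). A plain log1p-variance
#' ranking is available as `method = "logvar"`.
#'
#' @param mat a [cell_counts] object.
#' @param n_hvg number of genes to keep (`<=` the number of genes).
#' @param method `"vst"` (default) or `"logvar"`.
#' @return List with `data` (the [cell_counts] restricted to the selected
#'   genes, in ranked order) and `ranking` (data.frame of gene, score, rank
#'   for all genes).
#' @export
select_hvg <- function(mat, n_hvg, method = c("vst", "logvar")) {
  stopifnot(inherits(mat, "cell_counts"))
  method <- match.arg(method)
  N <- ncol(mat$counts)
  if (n_hvg > N)
    stop("n_hvg (", n_hvg, ") exceeds the number of genes (", N, ")")
  score <- hvg_scores(mat$counts, method)
  ord <- order(-score, seq_len(N))          # stable index tie-break
  ranking <- data.frame(gene = mat$gene_names[ord], score = score[ord],
                        rank = seq_len(N), stringsAsFactors = FALSE)
  sel <- sort(ord[seq_len(n_hvg)])
  keep_order <- ord[seq_len(n_hvg)]
  list(data = subset_counts(mat, genes = keep_order), ranking = ranking)
}

hvg_scores <- function(counts, method) {
  C <- nrow(counts)
  if (method == "logvar")
    return(apply(log1p(counts), 2, stats::var))
  mu <- colMeans(counts)
  v <- apply(counts, 2, stats::var)
  score <- numeric(ncol(counts))
  ok <- mu > 0 & v > 0
  if (sum(ok) >= 3 && C >= 2) {
    lm10 <- log10(mu[ok]); lv10 <- log10(v[ok])
    deg <- min(2L, length(unique(lm10)) - 1L)
    fit <- stats::lm(lv10 ~ stats::poly(lm10, degree = max(1L, deg), raw = TRUE))
    sd_exp <- sqrt(10^stats::fitted(fit))
    clip <- sqrt(C)
    z <- sweep(counts[, ok, drop = FALSE], 2, mu[ok], "-")
    z <- sweep(z, 2, sd_exp, "/")
    z <- pmin(pmax(z, -clip), clip)
    score[ok] <- apply(z, 2, function(col) sum((col - mean(col))^2) / (C - 1))
  } else if (any(ok)) {
    score[ok] <- v[ok]
  }
  score
}
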