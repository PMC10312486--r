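# Interpretation of the trained attention tensor: marker rankings,
# attention-correlation structure, and enrichment-based cluster annotation.

#' Global marker ranking from attention weights
#'
#' Scores each gene by its mean attention weight over all cells and returns
#' the descending ranking (ties broken by gene index, so a uniform attention
#' tensor reproduces the input gene order).
#'
#' @param A C x N attention matrix (e.g. `predict(fit, x, type =
#'   "attention")`).
#' @param gene_names character vector of N gene names; defaults to
#'   `colnames(A)`.
#' @return A data.frame of class `cellattn_markers` with columns `gene` and
#'   `score`, ordered by decreasing score; attribute `"scope"` is
#'   `"global"`.
#' @export
global_markers <- function(A, gene_names = colnames(A)) {
  A <- as.matrix(A)
  if (is.null(gene_names)) gene_names <- paste0("gene", seq_len(ncol(A)))
  score <- colMeans(A)
  ord <- order(-score, seq_len(ncol(A)))
  out <- data.frame(gene = gene_names[ord], score = score[ord],
                    stringsAsFactors = FALSE)
  attr(out, "scope") <- "global"
  class(out) <- c("cellattn_markers", "data.frame")
  out
}

#' Per-cluster marker extraction
#'
#' For each label class, genes are scored by their mean attention weight over
#' that class's cells and the `top_n` highest-scoring genes are returned.
#'
#' @inheritParams global_markers
#' @param labels per-cell labels covering all rows of `A`.
#' @param top_n markers per cluster (default 50; must be `<=` N).
#' @return Named list (one `cellattn_markers` data.frame per class).
#' @export
cluster_markers <- function(A, labels, top_n = 50L,
                            gene_names = colnames(A)) {
  A <- as.matrix(A)
  stopifnot(length(labels) == nrow(A))
  if (top_n > ncol(A))
    stop("top_n (", top_n, ") exceeds the number of genes (", ncol(A), ")")
  if (is.null(gene_names)) gene_names <- paste0("gene", seq_len(ncol(A)))
  labels <- as.character(labels)
  out <- lapply(sort(unique(labels)), function(cl) {
    rows <- which(labels == cl)
    score <- colMeans(A[rows, , drop = FALSE])
    ord <- order(-score, seq_len(ncol(A)))[seq_len(top_n)]
    m <- data.frame(gene = gene_names[ord], score = score[ord],
                    stringsAsFactors = FALSE)
    attr(m, "scope") <- cl
    class(m) <- c("cellattn_markers", "data.frame")
    m
  })
  names(out) <- sort(unique(labels))
  out
}

#' Correlation of attention profiles between classes
#'
#' Pearson correlation between the per-class mean attention vectors —
#' classes whose learned gene-importance profiles are similar (e.g. related
#' cell types) correlate highly.
#'
#' @inheritParams cluster_markers
#' @return T x T symmetric correlation matrix with unit diagonal; a class
#'   whose mean attention vector has zero variance yields `NA` entries
#'   (correlation undefined), never 0.
#' @export
attention_correlation <- function(A, labels) {
  A <- as.matrix(A)
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(A))
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("attention_correlation needs >= 2 classes")
  means <- vapply(classes, function(cl)
    colMeans(A[labels == cl, , drop = FALSE]), numeric(ncol(A)))
  sds <- apply(means, 2, stats::sd)
  cm <- suppressWarnings(stats::cor(means))
  cm[sds == 0, ] <- NA_real_
  cm[, sds == 0] <- NA_real_
  diag(cm) <- ifelse(sds == 0, NA_real_, 1)
  dimnames(cm) <- list(classes, classes)
  cm
}

#' Hypergeometric gene-set enrichment
#'
#' One-sided over-representation test of a query gene list against each term
#' of a GMT library: with background size M, term size K, query size n and
#' overlap k, the raw p-value is P(X >= k) for X ~ Hypergeometric(M, K, n),
#' adjusted across terms by Benjamini-Hochberg. Gene matching is
#' case-insensitive; query genes absent from the background are dropped
#' with a message.
#'
#' @param query_genes character vector of query genes (non-empty).
#' @param library named list of gene sets (see [read_gmt]).
#' @param background character vector defining the gene universe (typically
#'   the genes of the trained matrix); term genes outside it are ignored.
#' @return data.frame with columns `term`, `overlap`, `query_size`,
#'   `term_size`, `background_size`, `p_value`, `p_adjusted`, sorted by
#'   adjusted then raw p-value (ties keep library order).
#' @export
enrich <- function(query_genes, library, background) {
  if (!length(query_genes)) stop("empty query gene list")
  if (!length(library)) stop("empty gene-set library")
  bg <- unique(toupper(background))
  M <- length(bg)
  q <- unique(toupper(query_genes))
  dropped <- sum(!q %in% bg)
  if (dropped > 0)
    message(dropped, " query gene(s) absent from the background were dropped")
  q <- intersect(q, bg)
  if (!length(q)) stop("no query genes remain in the background")
  n <- length(q)
  res <- do.call(rbind, lapply(names(library), function(term) {
    set <- intersect(unique(toupper(library[[term]])), bg)
    K <- length(set)
    k <- length(intersect(q, set))
    # upper-tail P(X >= k); phyper(k-1, ...) with lower.tail = FALSE
    p <- stats::phyper(k - 1, K, M - K, n, lower.tail = FALSE)
    data.frame(term = term, overlap = k, query_size = n, term_size = K,
               background_size = M, p_value = p, stringsAsFactors = FALSE)
  }))
  res$p_adjusted <- stats::p.adjust(res$p_value, method = "BH")
  res[order(res$p_adjusted, res$p_value), , drop = FALSE]
}

#' Enrichment-based unsupervised cluster annotation
#'
#' Extracts each cluster's top attentive genes ([cluster_markers]) and
#' queries them against a gene-set library ([enrich]); the term with the
#' smallest adjusted p-value becomes the cluster's primary call. When no
#' term overlaps the markers the cluster is flagged `"unassigned"`, and
#' tied best terms are all reported rather than silently broken.
#'
#' @inheritParams cluster_markers
#' @param library named list of gene sets (terms are candidate cell types).
#' @param background gene universe for the test; defaults to `gene_names`.
#' @return List of class `cellattn_annotation`: per cluster, a list with
#'   `call` (primary term or `"unassigned"`), `tied_calls` (all terms tying
#'   the best adjusted p), `p_adjusted`, and `table` (the full enrichment
#'   data.frame for disambiguation).
#' @export
annotate_clusters <- function(A, labels, library, top_n = 50L,
                              gene_names = colnames(A),
                              background = gene_names) {
  markers <- cluster_markers(A, labels, top_n = top_n,
                             gene_names = gene_names)
  out <- lapply(names(markers), function(cl) {
    tab <- enrich(markers[[cl]]$gene, library, background)
    best <- tab[1, ]
    tied <- tab$term[tab$p_adjusted == best$p_adjusted &
                       tab$p_value == best$p_value]
    call <- if (best$overlap == 0) "unassigned" else best$term
    list(cluster = cl, call = call, tied_calls = tied,
         p_adjusted = best$p_adjusted, table = tab)
  })
  names(out) <- names(markers)
  class(out) <- "cellattn_annotation"
  out
}

#' @export
print.cellattn_annotation <- function(x, ...) {
  cat("Cluster annotation (top enrichment call per cluster):\n")
  for (cl in names(x)) {
    ann <- x[[cl]]
    extra <- if (length(ann$tied_calls) > 1)
      paste0(" [tied: ", paste(ann$tied_calls, collapse = ", "), "]") else ""
    cat(sprintf("  %s -> %s (adjusted p = %.3g)%s\n", cl, ann$call,
                ann$p_adjusted, extra))
  }
  invisible(x)
}
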