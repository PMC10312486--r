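#' Construct a cell-by-gene count container
#'
#' The package's basic data object: a dense non-negative integer matrix with
#' cells as rows and genes as columns, plus unique gene names, unique cell
#' ids, and an optional per-cell label vector.
#'
#' @param counts numeric matrix, C cells x N genes, finite and >= 0.
#' @param gene_names character vector of N unique gene names. Defaults to
#'   `colnames(counts)`.
#' @param cell_ids character vector of C unique cell ids. Defaults to
#'   `rownames(counts)` or `cell1..cellC`.
#' @param labels optional per-cell labels (factor or character), length C.
#' @return An object of class `cell_counts`: a list with elements `counts`,
#'   `gene_names`, `cell_ids`, `labels`.
#' @export
cell_counts <- function(counts, gene_names = colnames(counts),
                        cell_ids = rownames(counts), labels = NULL) {
  counts <- as.matrix(counts)
  if (is.null(gene_names)) gene_names <- paste0("gene", seq_len(ncol(counts)))
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(nrow(counts)))
  gene_names <- as.character(gene_names)
  cell_ids <- as.character(cell_ids)
  if (length(gene_names) != ncol(counts))
    stop("gene_names length (", length(gene_names), ") != ncol(counts) (",
         ncol(counts), ")")
  if (length(cell_ids) != nrow(counts))
    stop("cell_ids length (", length(cell_ids), ") != nrow(counts) (",
         nrow(counts), ")")
  if (anyDuplicated(gene_names)) stop("duplicate gene names")
  if (anyDuplicated(cell_ids)) stop("duplicate cell ids")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  if (!is.null(labels)) {
    if (length(labels) != nrow(counts))
      stop("labels length (", length(labels), ") != number of cells (",
           nrow(counts), ")")
    labels <- as.character(labels)
  }
  dimnames(counts) <- list(cell_ids, gene_names)
  structure(list(counts = counts, gene_names = gene_names,
                 cell_ids = cell_ids, labels = labels),
            class = "cell_counts")
}

#' @export
print.cell_counts <- function(x, ...) {
  cat("cell_counts: ", nrow(x$counts), " cells x ", ncol(x$counts),
      " genes\n", sep = "")
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat("labels (", length(tab), " classes): ",
        paste0(names(tab), "=", tab, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
dim.cell_counts <- function(x) dim(x$counts)

# Row/column subsetting that keeps the container consistent.
subset_counts <- function(mat, cells = NULL, genes = NULL) {
  counts <- mat$counts
  labels <- mat$labels
  if (!is.null(cells)) {
    counts <- counts[cells, , drop = FALSE]
    if (!is.null(labels)) labels <- labels[cells]
  }
  if (!is.null(genes)) counts <- counts[, genes, drop = FALSE]
  cell_counts(counts, colnames(counts), rownames(counts), labels)
}
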