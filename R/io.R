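#' Read a count matrix from MatrixMarket or CSV
#'
#' MatrixMarket input follows the 10x convention: the `.mtx` file stores genes
#' as rows and cells as columns and is transposed on read; sidecar files
#' `genes.tsv` and `barcodes.tsv` next to the matrix (or given explicitly)
#' provide gene names and cell ids. CSV input is dense with cells as rows and
#' a header of gene names; the first column holds cell ids.
#'
#' @param path path to the `.mtx` or `.csv` file.
#' @param format `"mtx"` or `"csv"`; guessed from the file extension when
#'   missing.
#' @param genes_file,barcodes_file optional sidecar paths (mtx only).
#' @return A [cell_counts] object (without labels; see [read_labels]).
#' @export
read_counts <- function(path, format = c("auto", "mtx", "csv"),
                        genes_file = NULL, barcodes_file = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.mtx$", path)) "mtx" else "csv"
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "mtx") {
    if (is.null(genes_file)) genes_file <- file.path(dirname(path), "genes.tsv")
    if (is.null(barcodes_file))
      barcodes_file <- file.path(dirname(path), "barcodes.tsv")
    m <- Matrix::readMM(path)
    genes <- readLines(genes_file)
    genes <- vapply(strsplit(genes, "\t"), `[`, character(1), 1L)
    barcodes <- readLines(barcodes_file)
    if (nrow(m) != length(genes))
      stop("matrix has ", nrow(m), " gene rows but ", genes_file, " lists ",
           length(genes), " genes")
    if (ncol(m) != length(barcodes))
      stop("matrix has ", ncol(m), " cell columns but ", barcodes_file,
           " lists ", length(barcodes), " barcodes")
    counts <- t(as.matrix(m))
    if (all(counts == round(counts))) storage.mode(counts) <- "integer"
    cell_counts(counts, gene_names = genes, cell_ids = barcodes)
  } else {
    df <- utils::read.csv(path, check.names = FALSE, row.names = 1)
    if (anyDuplicated(colnames(df))) stop("duplicate gene column in ", path)
    counts <- as.matrix(df)
    if (all(counts == round(counts))) storage.mode(counts) <- "integer"
    cell_counts(counts, gene_names = colnames(df), cell_ids = rownames(df))
  }
}

#' Write a count matrix to MatrixMarket or CSV
#'
#' The inverse of [read_counts]; MTX output is genes x cells with `genes.tsv`
#' and `barcodes.tsv` sidecars in `dir`. Round-trips are lossless for integer
#' counts.
#'
#' @param mat a [cell_counts] object.
#' @param path output path; for `"mtx"` this is the `.mtx` file and sidecars
#'   are written next to it.
#' @param format `"mtx"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_counts <- function(mat, path, format = c("auto", "mtx", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.mtx$", path)) "mtx" else "csv"
  if (format == "mtx") {
    m <- Matrix::Matrix(t(mat$counts), sparse = TRUE)
    Matrix::writeMM(m, path)
    writeLines(mat$gene_names, file.path(dirname(path), "genes.tsv"))
    writeLines(mat$cell_ids, file.path(dirname(path), "barcodes.tsv"))
  } else {
    df <- as.data.frame(mat$counts, check.names = FALSE)
    utils::write.csv(df, path, row.names = TRUE)
  }
  invisible(path)
}

#' Read or write a per-cell label vector
#'
#' Two-column CSV `cell_id,label`. On read, labels are returned in the order
#' of `cell_ids` when given.
#'
#' @param path CSV path.
#' @param cell_ids optional cell ids to align the labels to; an error is
#'   raised if any id is missing from the file.
#' @return Named character vector of labels.
#' @export
read_labels <- function(path, cell_ids = NULL) {
  df <- utils::read.csv(path, colClasses = "character")
  if (ncol(df) < 2) stop("label file needs two columns (cell_id,label): ", path)
  labels <- stats::setNames(df[[2]], df[[1]])
  if (!is.null(cell_ids)) {
    missing <- setdiff(cell_ids, names(labels))
    if (length(missing))
      stop(length(missing), " cell ids have no label, e.g. ", missing[1])
    labels <- labels[cell_ids]
  }
  labels
}

#' @rdname read_labels
#' @param labels named character vector (names are cell ids).
#' @export
write_labels <- function(labels, path) {
  utils::write.csv(data.frame(cell_id = names(labels),
                              label = as.character(labels)),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set library
#'
#' Standard tab-separated GMT: term, description, then one gene per field.
#' Duplicate genes within a term are dropped (with a message giving the
#' count); empty descriptions are allowed.
#'
#' @param path GMT file path.
#' @return Named list of character vectors (gene sets); term descriptions in
#'   attribute `"description"`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path)
  sets <- list(); desc <- character(0); n_dup <- 0L
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop("malformed GMT line ", i, ": need term, description and >= 1 gene")
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (!length(genes)) stop("malformed GMT line ", i, ": no genes")
    n_dup <- n_dup + (length(genes) - length(unique(genes)))
    sets[[fields[1]]] <- unique(genes)
    desc <- c(desc, fields[2])
  }
  if (n_dup > 0)
    message(n_dup, " duplicate gene entries dropped while reading ", path)
  attr(sets, "description") <- desc
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description")
  if (is.null(desc)) desc <- rep("", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], desc[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
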