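# Negative-binomial simulator with planted per-type marker genes: the ground
# truth against which training, marker recovery, annotation and transfer are
# exercised without any external data.

#' Simulation configuration
#'
#' Counts are drawn from a negative binomial with per-cell log-normal library
#' scaling: gene j in cell i has mean
#' `base_mean * libsize_i * (marker_fold if j is a marker of cell i's type
#' else 1)`, with inverse-dispersion `dispersion` (variance mu + mu^2 /
#' dispersion). A configurable fraction of genes carries a mitochondrial
#' name prefix so QC filters are exercised end-to-end.
#'
#' @param n_cells,n_genes,n_types dataset dimensions.
#' @param markers_per_type planted marker genes per type (disjoint across
#'   types; `markers_per_type * n_types <= n_genes`).
#' @param marker_fold mean fold-change of a marker in its own type
#'   (default 8).
#' @param base_mean background NB mean (default 1).
#' @param dispersion NB inverse-dispersion / size parameter (default 2).
#' @param libsize_sigma sd of the per-cell log-normal library factor
#'   (default 0.3).
#' @param mito_fraction_genes fraction of genes given an `MT-` name prefix
#'   (default 0.02).
#' @param seed integer seed.
#' @return A list of class `cellattn_sim_config`.
#' @export
simulation_config <- function(n_cells, n_genes, n_types,
                              markers_per_type, marker_fold = 8,
                              base_mean = 1.0, dispersion = 2.0,
                              libsize_sigma = 0.3,
                              mito_fraction_genes = 0.02, seed = 1L) {
  if (n_cells < 1 || n_genes < 1 || n_types < 1)
    stop("n_cells, n_genes and n_types must be positive")
  if (markers_per_type < 0) stop("markers_per_type must be >= 0")
  if (markers_per_type * n_types > n_genes)
    stop("markers_per_type * n_types (", markers_per_type * n_types,
         ") exceeds n_genes (", n_genes, ")")
  if (marker_fold <= 0 || base_mean <= 0 || dispersion <= 0)
    stop("marker_fold, base_mean and dispersion must be positive")
  if (libsize_sigma < 0) stop("libsize_sigma must be >= 0")
  if (mito_fraction_genes < 0 || mito_fraction_genes > 1)
    stop("mito_fraction_genes must be in [0, 1]")
  structure(list(n_cells = as.integer(n_cells),
                 n_genes = as.integer(n_genes),
                 n_types = as.integer(n_types),
                 markers_per_type = as.integer(markers_per_type),
                 marker_fold = marker_fold, base_mean = base_mean,
                 dispersion = dispersion, libsize_sigma = libsize_sigma,
                 mito_fraction_genes = mito_fraction_genes,
                 seed = as.integer(seed)),
            class = "cellattn_sim_config")
}

# Gene names: plain GENE0001... with the first ceil(f*N) non-marker genes
# renamed to MT-like decoys. Marker assignments are by gene index.
sim_gene_names <- function(cfg, marker_idx) {
  nm <- sprintf("GENE%04d", seq_len(cfg$n_genes))
  n_mito <- round(cfg$mito_fraction_genes * cfg$n_genes)
  if (n_mito > 0) {
    pool <- setdiff(seq_len(cfg$n_genes), unlist(marker_idx))
    mito <- pool[seq_len(min(n_mito, length(pool)))]
    nm[mito] <- sprintf("MT-G%03d", seq_along(mito))
  }
  nm
}

#' Simulate a labeled count matrix with planted markers
#'
#' @param cfg a [simulation_config].
#' @return A list of class `cellattn_sim` with elements `data` (a
#'   [cell_counts] with balanced type labels), `markers` (named list: planted
#'   marker gene names per type) and `gmt` (a demo gene-set library with one
#'   term per type, equal to its planted markers).
#' @export
simulate_counts <- function(cfg) {
  stopifnot(inherits(cfg, "cellattn_sim_config"))
  marker_idx <- split(seq_len(cfg$n_types * cfg$markers_per_type),
                      rep(seq_len(cfg$n_types), each = cfg$markers_per_type))
  types <- paste0("type", seq_len(cfg$n_types))
  labels <- rep(types, length.out = cfg$n_cells)
  gene_names <- sim_gene_names(cfg, marker_idx)
  counts <- with_seed(cfg$seed, {
    lib <- exp(stats::rnorm(cfg$n_cells, 0, cfg$libsize_sigma))
    mu <- matrix(cfg$base_mean * lib, cfg$n_cells, cfg$n_genes)
    for (t in seq_len(cfg$n_types)) {
      rows <- which(labels == types[t])
      mu[rows, marker_idx[[t]]] <- mu[rows, marker_idx[[t]]] * cfg$marker_fold
    }
    matrix(stats::rnbinom(length(mu), mu = mu, size = cfg$dispersion),
           cfg$n_cells, cfg$n_genes)
  })
  markers <- lapply(marker_idx, function(ix) gene_names[ix])
  names(markers) <- types
  gmt <- markers
  attr(gmt, "description") <- paste("planted markers of", types)
  structure(list(data = cell_counts(counts, gene_names = gene_names,
                                    cell_ids = sprintf("cell%05d",
                                                       seq_len(cfg$n_cells)),
                                    labels = labels),
                 markers = markers, gmt = gmt, config = cfg),
            class = "cellattn_sim")
}

#' Simulate a reference/query dataset pair for transfer learning
#'
#' The query dataset reuses the reference's generative structure exactly —
#' same gene space and identical marker sets and fold-changes for the shared
#' types — and adds `novel_types` extra types with fresh, disjoint markers,
#' mirroring transfer from a broad reference atlas to a query with more
#' subpopulations.
#'
#' @param cfg_ref a [simulation_config] for the reference dataset.
#' @param novel_types number of additional query-only types (>= 0).
#' @param n_cells_query query size (default: same as reference).
#' @param seed_query seed for the query draw (default `cfg_ref$seed + 1`).
#' @return List with elements `reference` and `query`, both `cellattn_sim`
#'   objects sharing marker structure.
#' @export
make_transfer_pair <- function(cfg_ref, novel_types = 0L,
                               n_cells_query = cfg_ref$n_cells,
                               seed_query = cfg_ref$seed + 1L) {
  stopifnot(inherits(cfg_ref, "cellattn_sim_config"), novel_types >= 0)
  cfg_query <- simulation_config(
    n_cells = n_cells_query, n_genes = cfg_ref$n_genes,
    n_types = cfg_ref$n_types + as.integer(novel_types),
    markers_per_type = cfg_ref$markers_per_type,
    marker_fold = cfg_ref$marker_fold, base_mean = cfg_ref$base_mean,
    dispersion = cfg_ref$dispersion, libsize_sigma = cfg_ref$libsize_sigma,
    mito_fraction_genes = cfg_ref$mito_fraction_genes,
    seed = as.integer(seed_query))
  reference <- simulate_counts(cfg_ref)
  query <- simulate_counts(cfg_query)
  list(reference = reference, query = query)
}

#' Write a simulated dataset to disk
#'
#' Writes the MTX matrix with sidecars, the label CSV, the planted-marker
#' JSON and the demo GMT library into `dir`.
#'
#' @param sim a `cellattn_sim` from [simulate_counts].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_counts(sim$data, file.path(dir, "matrix.mtx"))
  write_labels(stats::setNames(sim$data$labels, sim$data$cell_ids),
               file.path(dir, "labels.csv"))
  jsonlite::write_json(sim$markers, file.path(dir, "markers.json"))
  write_gmt(sim$gmt, file.path(dir, "types.gmt"))
  invisible(dir)
}
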