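test_that("toy matrix: under-expressing cell then under-supported gene removed", {
  # 6 cells x 5 genes; with min_genes_per_cell = 3 one cell (2 expressed
  # genes) fails; gene G5 is then expressed in only 2 remaining cells.
  counts <- rbind(
    c(1, 1, 0, 0, 0),   # 2 expressed genes -> removed
    c(1, 1, 1, 0, 1),
    c(1, 1, 1, 1, 1),
    c(2, 1, 1, 1, 0),
    c(1, 2, 1, 1, 0),
    c(1, 1, 2, 1, 0))
  mat <- cell_counts(counts, paste0("G", 1:5), paste0("c", 1:6))
  res <- filter_counts(mat, qc_config(min_genes_per_cell = 3,
                                      min_cells_per_gene = 3,
                                      max_mito_fraction = 1,
                                      min_cells_per_class = 0))
  expect_identical(res$report$cells_removed_min_genes, 1L)
  expect_identical(res$report$genes_removed, 1L)
  expect_identical(dim(res$data$counts), c(5L, 4L))
  expect_false("G5" %in% res$data$gene_names)
  expect_false("c1" %in% res$data$cell_ids)

  # report counts equal the dimension drops along each axis
  expect_identical(nrow(mat$counts) - nrow(res$data$counts),
                   res$report$cells_removed_min_genes +
                     res$report$cells_removed_mito +
                     res$report$cells_removed_class)
  expect_identical(ncol(mat$counts) - ncol(res$data$counts),
                   res$report$genes_removed)
})

test_that("cell boundary: 199 expressed genes removed, 200 kept", {
  N <- 250
  counts <- rbind(
    c(rep(1, 199), rep(0, N - 199)),
    c(rep(1, 200), rep(0, N - 200)),
    matrix(1, 8, N))
  mat <- cell_counts(counts, sprintf("G%03d", 1:N), paste0("c", 1:10))
  res <- filter_counts(mat, qc_config(min_cells_per_class = 0))
  expect_false("c1" %in% res$data$cell_ids)
  expect_true("c2" %in% res$data$cell_ids)
  expect_identical(res$report$cells_removed_min_genes, 1L)
})

test_that("mito boundary is strict: fraction exactly 0.10 removed", {
  # 3 genes incl. one MT- gene; min_genes relaxed so only the mito rule acts
  counts <- rbind(
    c(45, 45, 10),   # 10% mito -> removed
    c(46, 45, 9),    # 9% -> kept
    c(50, 50, 0))
  mat <- cell_counts(counts, c("G1", "G2", "MT-ND1"), paste0("c", 1:3))
  res <- filter_counts(mat, qc_config(min_genes_per_cell = 0,
                                      min_cells_per_gene = 0,
                                      min_cells_per_class = 0))
  expect_identical(res$report$cells_removed_mito, 1L)
  expect_false("c1" %in% res$data$cell_ids)
  expect_true(all(c("c2", "c3") %in% res$data$cell_ids))
})

test_that("class filter drops a 99-cell class and keeps a 100-cell class", {
  C <- 199
  labels <- c(rep("big", 100), rep("small", 99))
  set.seed(1)
  counts <- matrix(rpois(C * 5, 5) + 1, C, 5)
  mat <- cell_counts(counts, paste0("G", 1:5), paste0("c", 1:C), labels)
  res <- filter_counts(mat, qc_config(min_genes_per_cell = 0,
                                      min_cells_per_gene = 0))
  expect_identical(res$report$classes_removed, 1L)
  expect_identical(res$report$cells_removed_class, 99L)
  expect_setequal(unique(res$data$labels), "big")
})

test_that("filtering is idempotent on simulated data", {
  sim <- simulate_counts(simulation_config(400, 80, 3, 5, seed = 6))
  cfg <- qc_config(min_genes_per_cell = 10, min_cells_per_gene = 3,
                   max_mito_fraction = 0.2, min_cells_per_class = 50)
  once <- filter_counts(sim$data, cfg)
  twice <- filter_counts(once$data, cfg)
  expect_identical(twice$data$counts, once$data$counts)
  expect_true(all(unlist(twice$report) == 0))
})

test_that("fully filtered input raises an explicit error", {
  mat <- cell_counts(matrix(0:1, 2, 4), paste0("G", 1:4), c("a", "b"))
  expect_error(filter_counts(mat, qc_config(min_genes_per_cell = 100)),
               "no cells survive")
})

test_that("HVG selection: identity, dominant gene, and error cases", {
  mat <- toy_counts(C = 20, N = 8, seed = 2)
  all_sel <- select_hvg(mat, 8)
  expect_setequal(all_sel$data$gene_names, mat$gene_names)
  expect_identical(nrow(all_sel$ranking), 8L)

  # one gene with variance far above the mean-variance trend
  set.seed(4)
  counts <- matrix(rpois(100 * 40, 2), 100, 40)
  counts[, 17] <- rep(c(0, 4), 50)   # same mean as background, 2x variance
  m2 <- cell_counts(counts, paste0("G", 1:40), paste0("c", 1:100))
  expect_identical(select_hvg(m2, 1)$data$gene_names, "G17")

  expect_error(select_hvg(mat, 9), "exceeds the number of genes")
})

test_that("HVG ranking matches an independent standardized-variance oracle", {
  sim <- simulate_counts(simulation_config(300, 50, 3, 5, seed = 8))
  X <- sim$data$counts
  # independent recomputation: quadratic trend of log10 var on log10 mean,
  # clipped standardized values, ranked by their variance
  mu <- colMeans(X); v <- apply(X, 2, var)
  stopifnot(all(mu > 0 & v > 0))
  fit <- lm(log10(v) ~ poly(log10(mu), 2, raw = TRUE))
  sd_exp <- sqrt(10^fitted(fit))
  clip <- sqrt(nrow(X))
  sc <- vapply(seq_len(ncol(X)), function(j) {
    z <- (X[, j] - mu[j]) / sd_exp[j]
    z <- pmin(pmax(z, -clip), clip)
    var(z)
  }, numeric(1))
  expected <- sim$data$gene_names[order(-sc, seq_len(ncol(X)))][1:10]
  got <- select_hvg(sim$data, 10)$ranking$gene[1:10]
  expect_identical(got, expected)
})

test_that("HVG selection is invariant to cell and gene order", {
  sim <- simulate_counts(simulation_config(200, 40, 2, 4, seed = 3))
  sel <- select_hvg(sim$data, 12)$data$gene_names
  set.seed(10)
  perm_cells <- sample(nrow(sim$data$counts))
  perm_genes <- sample(ncol(sim$data$counts))
  shuffled <- cell_counts(sim$data$counts[perm_cells, perm_genes],
                          sim$data$gene_names[perm_genes],
                          sim$data$cell_ids[perm_cells])
  sel2 <- select_hvg(shuffled, 12)$data$gene_names
  expect_setequal(sel2, sel)
})
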