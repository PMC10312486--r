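# Shared fixtures, memoized so expensive trainings run once per suite.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# The planted-marker study fixture: 2000 cells, 200 genes, 5 balanced types,
# 10 markers per type at fold 8; trained 50 epochs on the true labels.
trained_fixture <- function(seed) {
  memo(paste0("trained_", seed), {
    sim <- simulate_counts(simulation_config(
      n_cells = 2000, n_genes = 200, n_types = 5, markers_per_type = 10,
      marker_fold = 8, seed = seed))
    fit <- cellattn(sim$data, config = train_config(epochs = 50, seed = seed))
    A <- predict(fit, sim$data, type = "attention")
    list(sim = sim, fit = fit, A = A)
  })
}

# A small, quick fit for tests that only need a trained model.
quick_fixture <- function() {
  memo("quick", {
    sim <- simulate_counts(simulation_config(
      n_cells = 600, n_genes = 80, n_types = 3, markers_per_type = 8,
      marker_fold = 8, seed = 5))
    fit <- cellattn(sim$data, config = train_config(epochs = 15, seed = 5))
    A <- predict(fit, sim$data, type = "attention")
    list(sim = sim, fit = fit, A = A)
  })
}

# Small labeled matrix for plumbing tests.
toy_counts <- function(C = 8, N = 6, seed = 3, labels = NULL) {
  set.seed(seed)
  cell_counts(matrix(rpois(C * N, 2), C, N),
              gene_names = paste0("G", seq_len(N)),
              cell_ids = paste0("c", seq_len(C)),
              labels = labels)
}
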