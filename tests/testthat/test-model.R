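test_that("zero-parameter attention is uniform and gene scores scale counts", {
  st <- init_model(arch_config(n_genes = 4, n_classes = 2, n_branches = 2,
                               bottleneck = 8, seed = 1))
  st$params[["attn.w"]][] <- 0
  st$params[["attn.b"]][] <- 0
  X <- matrix(c(4, 0, 2, 6, 1, 3, 5, 7), 2, 4)
  fw <- attention_forward(X, st)
  expect_true(all(fw$A == 0.25))
  expect_equal(fw$gamma, X / 4)

  # single gene: attention is identically 1 and gamma = X
  st1 <- init_model(arch_config(n_genes = 1, n_classes = 2, n_branches = 1,
                                bottleneck = 4, seed = 1))
  X1 <- matrix(c(3, 0, 7), 3, 1)
  fw1 <- attention_forward(X1, st1)
  expect_true(all(fw1$A == 1))
  expect_equal(fw1$gamma, X1)
})

test_that("softmax arithmetic: logits (ln 2, 0) give weights (2/3, 1/3)", {
  st <- init_model(arch_config(n_genes = 2, n_classes = 2, n_branches = 1,
                               bottleneck = 4, seed = 1))
  st$params[["attn.w"]][] <- 0
  st$params[["attn.b"]] <- c(log(2), 0)
  X <- matrix(c(3, 3), 1, 2)
  fw <- attention_forward(X, st)
  expect_equal(as.numeric(fw$A), c(2 / 3, 1 / 3))
  expect_equal(as.numeric(fw$gamma), c(2, 1))
})

test_that("gene-dimension mismatch raises an error naming both dimensions", {
  st <- init_model(arch_config(n_genes = 5, n_classes = 2, n_branches = 1,
                               bottleneck = 4))
  expect_error(model_forward(matrix(0, 2, 7), st), "7 genes.*expects.*5")
})

test_that("zero projection weights reduce a block to LayerNorm of the scores", {
  st <- init_model(arch_config(n_genes = 6, n_classes = 2, n_blocks = 1,
                               n_branches = 2, bottleneck = 4, seed = 2))
  for (nm in grep("^blk1\\.(br|W|b)", names(st$params), value = TRUE))
    st$params[[nm]][] <- 0        # linear maps zero; LN gain stays at 1
  gamma <- matrix(c(1, 5, 2, 0, 3, 4, 6, 1, 2, 0, 7, 2), 2, 6)
  out <- projection_forward(gamma, st)
  manual <- t(apply(gamma, 1, function(r)
    (r - mean(r)) / sqrt(mean((r - mean(r))^2) + 1e-5)))
  expect_equal(out, manual, tolerance = 1e-12)
  expect_equal(rowMeans(out), c(0, 0), tolerance = 1e-12)
})

test_that("configuration head computes LeakyReLU of a linear map", {
  st <- init_model(arch_config(n_genes = 3, n_classes = 2, n_branches = 1,
                               bottleneck = 4, seed = 3))
  st$params[["head.W"]][] <- 0
  st$params[["head.b"]][] <- 0
  rep <- matrix(rnorm(6), 2, 3)
  expect_true(all(configuration_forward(rep, st) == 0))

  W <- matrix(c(1, -1, 0.5, 0.2, 0.3, -0.7), 3, 2)
  b <- c(0.1, -0.2)
  st$params[["head.W"]] <- W
  st$params[["head.b"]] <- b
  raw <- rep %*% W + matrix(b, 2, 2, byrow = TRUE)
  expect_equal(configuration_forward(rep, st),
               ifelse(raw > 0, raw, 0.01 * raw))

  # single-class head is a column vector of logits
  st1 <- init_model(arch_config(n_genes = 3, n_classes = 1, n_branches = 1,
                                bottleneck = 4))
  expect_identical(dim(configuration_forward(rep, st1)), c(2L, 1L))
})

test_that("model_forward matches the straight-line oracle on seeded fixtures", {
  set.seed(99)
  X <- matrix(rpois(5 * 8, 4), 5, 8)
  for (form in c("diag", "dense", "lowrank")) {
    st <- init_model(arch_config(
      n_genes = 8, n_classes = 3, n_blocks = 2, n_branches = 4,
      bottleneck = 16, attention_form = form,
      attention_rank = if (form == "lowrank") 3 else NULL, seed = 42))
    got <- model_forward(X, st)
    want <- oracle_forward(st, X)
    expect_equal(got$logits, want$logits, tolerance = 1e-6)
    expect_equal(got$A, want$A, tolerance = 1e-6)
  }
})

test_that("forward pass is deterministic and shape-correct", {
  st <- init_model(arch_config(n_genes = 10, n_classes = 4, seed = 7))
  set.seed(1)
  X <- matrix(rpois(60, 3), 6, 10)
  f1 <- model_forward(X, st)
  f2 <- model_forward(X, st)
  expect_identical(f1$logits, f2$logits)
  expect_identical(dim(f1$logits), c(6L, 4L))
})

test_that("permuting cells permutes all outputs identically", {
  st <- init_model(arch_config(n_genes = 12, n_classes = 3, seed = 8))
  set.seed(2)
  X <- matrix(rpois(8 * 12, 5), 8, 12)
  perm <- c(5, 2, 8, 1, 7, 3, 6, 4)
  f <- model_forward(X, st)
  fp <- model_forward(X[perm, ], st)
  expect_equal(fp$logits, f$logits[perm, ], tolerance = 1e-12)
  expect_equal(fp$A, f$A[perm, ], tolerance = 1e-12)
})

test_that("attention rows are stochastic and shift-invariant across random states", {
  for (trial in 1:25) {
    set.seed(trial)
    N <- sample(3:40, 1); C <- sample(2:16, 1)
    form <- sample(c("diag", "dense"), 1)
    st <- init_model(arch_config(n_genes = N, n_classes = 2,
                                 n_branches = sample(1:min(4, N), 1),
                                 bottleneck = 8, attention_form = form,
                                 seed = trial))
    X <- matrix(rpois(C * N, 4), C, N)
    A <- attention_forward(X, st)$A
    expect_lt(max(abs(rowSums(A) - 1)), 1e-6)
    expect_true(all(A > 0))

    # adding a constant to every attention logit leaves A unchanged
    st2 <- st
    st2$params[["attn.b"]] <- st$params[["attn.b"]] + 37.5
    expect_lt(max(abs(attention_forward(X, st2)$A - A)), 1e-6)
  }
})

test_that("analytic gradients match central finite differences", {
  set.seed(1)
  X <- matrix(rpois(4 * 6, 3), 4, 6)
  y <- c(1L, 2L, 3L, 1L)
  for (form in c("diag", "dense")) {
    st <- init_model(arch_config(n_genes = 6, n_classes = 3, n_blocks = 2,
                                 n_branches = 2, bottleneck = 5,
                                 attention_form = form, seed = 42))
    gr <- cellattn:::model_grad(st, X, y)
    loss_at <- function(s) {
      fw <- cellattn:::forward_pass(s, X)
      p <- cellattn:::softmax_rows(fw$logits)
      -mean(log(p[cbind(1:4, y)]))
    }
    eps <- 1e-6
    worst <- 0
    for (nm in names(st$params)) {
      idx <- seq_len(min(length(st$params[[nm]]), 5L))
      for (ii in idx) {
        s2 <- st
        s2$params[[nm]][ii] <- st$params[[nm]][ii] + eps
        up <- loss_at(s2)
        s2$params[[nm]][ii] <- st$params[[nm]][ii] - eps
        dn <- loss_at(s2)
        num <- (up - dn) / (2 * eps)
        an <- gr$grads[[nm]][ii]
        worst <- max(worst, abs(num - an) / max(1e-6, abs(num), abs(an)))
      }
    }
    expect_lt(worst, 1e-4)
  }
})

test_that("checkpoints round-trip bitwise and reject damaged files", {
  st <- init_model(arch_config(n_genes = 7, n_classes = 3, n_branches = 2,
                               bottleneck = 6, seed = 12))
  set.seed(3)
  X <- matrix(rpois(21, 2), 3, 7)
  path <- tempfile(fileext = ".bin")
  save_checkpoint(st, path)
  st2 <- load_checkpoint(path)
  expect_identical(model_forward(X, st2)$logits, model_forward(X, st)$logits)
  expect_identical(st2$params, st$params)

  # truncation
  raw <- readBin(path, "raw", file.size(path))
  writeBin(raw[1:(length(raw) - 50)], trunc_path <- tempfile())
  expect_error(load_checkpoint(trunc_path), "truncated")

  # version mismatch
  bad <- tempfile()
  hdr <- charToRaw(as.character(jsonlite::toJSON(
    list(magic = "cellattn-checkpoint", version = 99L), auto_unbox = TRUE)))
  con <- file(bad, "wb")
  writeBin(length(hdr), con, size = 4L, endian = "little")
  writeBin(hdr, con)
  close(con)
  expect_error(load_checkpoint(bad), "incompatible checkpoint version")

  # architecture/array shape mismatch
  st_bad <- st
  st_bad$params[["head.W"]] <- st_bad$params[["head.W"]][, 1:2]
  mis_path <- tempfile()
  save_checkpoint(st_bad, mis_path)
  expect_error(load_checkpoint(mis_path), "shape")
})
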