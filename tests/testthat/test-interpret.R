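test_that("global markers rank genes by mean attention with stable ties", {
  A <- rbind(c(0.5, 0.3, 0.2), c(0.1, 0.6, 0.3))
  gm <- global_markers(A, c("g1", "g2", "g3"))
  expect_identical(gm$gene, c("g2", "g1", "g3"))
  expect_equal(gm$score, c(0.45, 0.3, 0.25))

  # uniform attention: tie-break preserves the input gene order
  Au <- matrix(1 / 4, 3, 4)
  expect_identical(global_markers(Au, paste0("g", 1:4))$gene,
                   paste0("g", 1:4))

  # one cell: ranking is its attention row sorted
  A1 <- matrix(c(0.1, 0.7, 0.2), 1, 3)
  expect_identical(global_markers(A1, c("a", "b", "c"))$gene,
                   c("b", "c", "a"))
})

test_that("cluster markers reduce to global markers for a single class", {
  fx <- quick_fixture()
  cm <- cluster_markers(fx$A, rep("all", nrow(fx$A)), top_n = 20)
  gm <- global_markers(fx$A)
  expect_identical(cm$all$gene, gm$gene[1:20])

  # a singleton class reports that cell's own top genes
  labs <- c("solo", rep("rest", nrow(fx$A) - 1))
  cm2 <- cluster_markers(fx$A, labs, top_n = 5)
  expect_identical(cm2$solo$gene,
                   colnames(fx$A)[order(-fx$A[1, ])[1:5]])

  expect_error(cluster_markers(fx$A, labs, top_n = 10000),
               "exceeds the number of genes")
})

test_that("marker rankings are invariant under cell permutation", {
  fx <- quick_fixture()
  set.seed(31)
  perm <- sample(nrow(fx$A))
  expect_identical(global_markers(fx$A[perm, ]), global_markers(fx$A))
  cm1 <- cluster_markers(fx$A, fx$sim$data$labels, top_n = 10)
  cm2 <- cluster_markers(fx$A[perm, ], fx$sim$data$labels[perm], top_n = 10)
  expect_identical(cm1, cm2)
})

test_that("attention correlation is symmetric with unit diagonal", {
  # hand Pearson: (0.5,0.3,0.2) vs (0.2,0.3,0.5) -> r = -13/14
  A <- rbind(c(0.5, 0.3, 0.2), c(0.2, 0.3, 0.5))
  cm <- attention_correlation(A, c("x", "y"))
  expect_equal(cm["x", "y"], -13 / 14)
  expect_equal(cm, t(cm))
  expect_equal(unname(diag(cm)), c(1, 1))

  # identical mean vectors give correlation 1
  A2 <- rbind(c(0.5, 0.3, 0.2), c(0.5, 0.3, 0.2))
  expect_equal(attention_correlation(A2, c("p", "q"))["p", "q"], 1)

  # zero-variance mean vector: undefined, reported as NA (never 0)
  A3 <- rbind(c(1 / 3, 1 / 3, 1 / 3), c(0.5, 0.3, 0.2))
  c3 <- attention_correlation(A3, c("flat", "var"))
  expect_true(is.na(c3["flat", "var"]))
  expect_false(is.na(c3["var", "var"]))
})

test_that("enrichment reproduces exact hypergeometric tail probabilities", {
  # worked case: M = 20, K = 5, n = 4, k = 4
  bg <- paste0("G", 1:20)
  lib <- list(TERM = paste0("G", 1:5))
  res <- enrich(paste0("G", 1:4), lib, bg)
  expect_equal(res$p_value, choose(5, 4) * choose(15, 0) / choose(20, 4),
               tolerance = 1e-12)
  expect_equal(res$p_value, 5 / 4845, tolerance = 1e-12)
  expect_identical(res$overlap, 4L)
  # single-term library: BH leaves the p-value unchanged
  expect_equal(res$p_adjusted, res$p_value)

  # zero overlap: P(X >= 0) = 1
  res0 <- enrich(paste0("G", 10:13), list(T1 = paste0("G", 1:5)), bg)
  expect_equal(res0$p_value, 1)
})

test_that("enrichment matches exhaustive enumeration for all overlaps, M <= 30", {
  for (M in c(12, 20, 30)) {
    bg <- paste0("G", seq_len(M))
    for (K in c(3, 7)) {
      for (n in c(2, 5)) {
        kmax <- min(n, K)
        for (k in 0:kmax) {
          # query with exactly k genes inside the term
          q <- c(paste0("G", seq_len(k)),
                 paste0("G", K + seq_len(n - k)))
          res <- enrich(q, setNames(list(paste0("G", seq_len(K))), "t"), bg)
          # independent enumeration of the upper tail
          p_exact <- sum(vapply(k:kmax, function(j)
            choose(K, j) * choose(M - K, n - j) / choose(M, n), numeric(1)))
          expect_equal(res$p_value, p_exact, tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("BH-adjusted p-values are monotone in the raw ordering", {
  set.seed(77)
  bg <- paste0("G", 1:40)
  lib <- lapply(1:8, function(i) sample(bg, 6))
  names(lib) <- paste0("T", 1:8)
  res <- enrich(sample(bg, 10), lib, bg)
  expect_true(all(res$p_adjusted >= res$p_value - 1e-15))
  expect_true(all(diff(res$p_adjusted[order(res$p_value)]) >= -1e-15))
})

test_that("query genes outside the background are dropped with a message", {
  bg <- paste0("G", 1:10)
  expect_message(enrich(c("G1", "G2", "NOPE"), list(t = bg[1:3]), bg),
                 "absent from the background")
  expect_error(enrich(character(0), list(t = bg), bg), "empty query")
  expect_error(enrich("G1", list(), bg), "empty gene-set library")
})

test_that("cluster annotation calls planted types, flags ties and no-overlap", {
  fx <- quick_fixture()
  labs <- fx$sim$data$labels
  ann <- annotate_clusters(fx$A, labs, fx$sim$gmt, top_n = 20)
  for (cl in names(ann)) expect_identical(ann[[cl]]$call, cl)

  # library with no overlap: all adjusted p = 1, flagged unassigned
  off_lib <- list(alien = paste0("ZZ", 1:5))
  bg2 <- c(colnames(fx$A), paste0("ZZ", 1:5))
  ann2 <- annotate_clusters(fx$A, labs, off_lib, top_n = 10,
                            background = bg2)
  for (cl in names(ann2)) {
    expect_identical(ann2[[cl]]$call, "unassigned")
    expect_equal(ann2[[cl]]$p_adjusted, 1)
  }

  # duplicated terms tie and the tie is reported
  dup_lib <- fx$sim$gmt[c(1, 1)]
  names(dup_lib) <- c("copyA", "copyB")
  ann3 <- annotate_clusters(fx$A, labs, dup_lib, top_n = 20)
  first <- names(ann3)[1]
  expect_setequal(ann3[[first]]$tied_calls, c("copyA", "copyB"))
})
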