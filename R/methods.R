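#' @export
print.cellattn <- function(x, ...) {
  a <- x$state$arch
  cat("Additive-attention cell classifier\n")
  cat("  genes:", a$n_genes, " classes:", a$n_classes,
      " blocks:", a$n_blocks, " branches:", a$n_branches,
      " bottleneck:", a$bottleneck, "\n")
  if (nrow(x$history) > 0) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  trained %d epochs (%d train / %d validation cells)\n",
                nrow(x$history), x$n_train, x$n_val))
    cat(sprintf("  final: loss %.4f, validation accuracy %.3f, weighted F1 %.3f\n",
                last$loss, last$val_accuracy, last$val_weighted_f1))
  }
  invisible(x)
}

#' @export
summary.cellattn <- function(object, ...) {
  out <- list(arch = object$state$arch, levels = object$levels,
              history = object$history,
              n_params = sum(vapply(object$state$params, length, numeric(1))),
              trainable = object$state$trainable,
              n_train = object$n_train, n_val = object$n_val)
  class(out) <- "summary.cellattn"
  out
}

#' @export
print.summary.cellattn <- function(x, ...) {
  a <- x$arch
  cat("Additive-attention cell classifier\n\n")
  cat("Architecture: N =", a$n_genes, "genes -> attention -> ",
      a$n_blocks, "projection blocks (", a$n_branches, "branches, bottleneck",
      a$bottleneck, ") ->", a$n_classes, "classes\n")
  cat("Parameters:", format(x$n_params, big.mark = ","), "  trainable modules:",
      paste(names(Filter(isTRUE, x$trainable)), collapse = ", "), "\n")
  cat("Classes:", paste(x$levels, collapse = ", "), "\n\n")
  h <- x$history
  show <- unique(c(1L, seq(5L, nrow(h), by = 5L), nrow(h)))
  cat("Training history (selected epochs):\n")
  print(h[show, ], row.names = FALSE, digits = 4)
  invisible(x)
}

#' Predict from a fitted attention classifier
#'
#' @param object a fitted `cellattn` model.
#' @param newdata a [cell_counts] object or count matrix with the model's
#'   gene space (use [align_genes] first if the query genes differ).
#' @param type `"class"` (default) for predicted labels, `"prob"` for
#'   class probabilities, `"logits"` for raw head outputs, `"attention"`
#'   for the per-cell gene-attention matrix, or `"scores"` for the gene
#'   scores Gamma = A (.) X.
#' @param ... unused.
#' @return A vector (class), or a matrix (other types) with appropriate
#'   dimnames.
#' @export
predict.cellattn <- function(object, newdata,
                             type = c("class", "prob", "logits",
                                      "attention", "scores"), ...) {
  type <- match.arg(type)
  X <- as_count_matrix(newdata)
  check_gene_dim(X, object$state)
  if (!is.null(colnames(X)) && !is.null(object$gene_names) &&
      !identical(colnames(X), object$gene_names))
    stop("gene names of newdata do not match the model's gene space; ",
         "use align_genes() first")
  fw <- forward_pass(object$state, X)
  switch(type,
    class = {
      out <- object$levels[max.col(fw$logits, ties.method = "first")]
      names(out) <- rownames(X)
      out
    },
    prob = {
      p <- softmax_rows(fw$logits)
      dimnames(p) <- list(rownames(X), object$levels)
      p
    },
    logits = {
      dimnames(fw$logits) <- list(rownames(X), object$levels)
      fw$logits
    },
    attention = {
      dimnames(fw$A) <- list(rownames(X), object$gene_names)
      fw$A
    },
    scores = {
      dimnames(fw$gamma) <- list(rownames(X), object$gene_names)
      fw$gamma
    })
}

#' Extract the configuration-head coefficients
#'
#' Returns the final linear layer's weight matrix with the bias as the first
#' row, analogous to coefficient extraction from a multinomial linear model.
#'
#' @param object a fitted `cellattn` model.
#' @param ... unused.
#' @return (N + 1) x T numeric matrix; rows are `(Intercept)` and genes,
#'   columns are classes.
#' @export
coef.cellattn <- function(object, ...) {
  W <- object$state$params[["head.W"]]
  b <- object$state$params[["head.b"]]
  out <- rbind(`(Intercept)` = b, W)
  rownames(out)[-1] <- object$gene_names %||% paste0("gene", seq_len(nrow(W)))
  colnames(out) <- object$levels
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Plot training history of a fitted attention classifier
#'
#' Draws the per-epoch training loss and validation weighted F1.
#'
#' @param x a fitted `cellattn` model.
#' @param ... passed to [graphics::plot].
#' @return `x`, invisibly.
#' @export
plot.cellattn <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mar = c(4, 4, 2, 4))
  on.exit(graphics::par(op))
  graphics::plot(h$epoch, h$loss, type = "l", col = "firebrick",
                 xlab = "epoch", ylab = "training loss",
                 main = "Training history", ...)
  graphics::par(new = TRUE)
  graphics::plot(h$epoch, h$val_weighted_f1, type = "l", col = "steelblue",
                 axes = FALSE, xlab = "", ylab = "", ylim = c(0, 1))
  graphics::axis(4)
  graphics::mtext("validation weighted F1", side = 4, line = 2.5)
  graphics::legend("right", legend = c("loss", "val weighted F1"),
                   col = c("firebrick", "steelblue"), lty = 1, bty = "n")
  invisible(x)
}
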