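# Freeze-and-finetune transfer learning: the attention and projection
# modules of a pretrained model are frozen, the configuration head is
# replaced or warm-started, and only the head is trained on the query data.

#' Freeze the attention and projection modules
#'
#' Marks the feature-extraction modules non-trainable so subsequent
#' fine-tuning updates only the configuration head. Idempotent.
#'
#' @param object a fitted `cellattn` model or a `cellattn_state`.
#' @return The object with `trainable$attention` and `trainable$projection`
#'   set to `FALSE`.
#' @export
freeze_feature_modules <- function(object) {
  if (inherits(object, "cellattn")) {
    object$state <- freeze_feature_modules(object$state)
    return(object)
  }
  stopifnot(inherits(object, "cellattn_state"))
  object$trainable$attention <- FALSE
  object$trainable$projection <- FALSE
  object
}

#' Replace the configuration head
#'
#' Installs a freshly initialized head of width `n_classes_query`, leaving
#' the attention and projection parameters untouched — used when the query
#' dataset has a different number of cell populations than the reference.
#'
#' @param object a fitted `cellattn` model or a `cellattn_state`.
#' @param n_classes_query number of query classes (>= 2).
#' @param seed seed for the fresh head initialization.
#' @param levels optional class labels for the new head (stored on fitted
#'   models).
#' @return The object with a re-initialized head.
#' @export
replace_head <- function(object, n_classes_query, seed = 1L, levels = NULL) {
  stopifnot(n_classes_query >= 2)
  if (inherits(object, "cellattn")) {
    object$state <- replace_head(object$state, n_classes_query, seed)
    object$levels <- levels %||% paste0("class", seq_len(n_classes_query))
    return(object)
  }
  stopifnot(inherits(object, "cellattn_state"))
  arch <- object$arch
  arch$n_classes <- as.integer(n_classes_query)
  object$arch <- arch
  with_seed(seed, {
    object$params[["head.W"]] <- init_mat(arch$n_genes, arch$n_classes)
    object$params[["head.b"]] <- numeric(arch$n_classes)
  })
  object
}

#' Align a query count matrix to a reference gene space
#'
#' Reorders the query's gene columns to the reference order, zero-fills
#' reference genes absent from the query and drops query-only genes, so a
#' model trained on the reference can be applied directly. Errors when the
#' gene overlap falls below `min_overlap` (attention weights over a mostly
#' missing gene space would be meaningless).
#'
#' @param query a [cell_counts] object.
#' @param reference_gene_names character vector of reference gene names.
#' @param min_overlap minimum fraction of reference genes that must be
#'   present in the query (default 0.5).
#' @return List with `data` (the aligned [cell_counts]) and `report`
#'   (`n_matched`, `n_zero_filled`, `n_dropped`).
#' @export
align_genes <- function(query, reference_gene_names, min_overlap = 0.5) {
  stopifnot(inherits(query, "cell_counts"))
  ref <- as.character(reference_gene_names)
  matched <- intersect(ref, query$gene_names)
  overlap <- length(matched) / length(ref)
  if (overlap < min_overlap)
    stop(sprintf(paste0("only %.1f%% of reference genes found in the query ",
                        "(floor %.1f%%); alignment refused"),
                 100 * overlap, 100 * min_overlap))
  fill <- if (is.integer(query$counts)) 0L else 0
  out <- matrix(fill, nrow(query$counts), length(ref),
                dimnames = list(query$cell_ids, ref))
  out[, matched] <- query$counts[, matched, drop = FALSE]
  list(data = cell_counts(out, ref, query$cell_ids, query$labels),
       report = list(n_matched = length(matched),
                     n_zero_filled = length(ref) - length(matched),
                     n_dropped = length(setdiff(query$gene_names, ref))))
}

#' Fine-tune the configuration head on a query dataset
#'
#' Trains only the head of a frozen model on labeled query cells with the
#' same optimizer and learning-rate schedule as pre-training. By default
#' only `finetune_fraction` (20%) of the query cells are used for training
#' and the rest are held out, mimicking label transfer to a small study.
#' The model must be frozen explicitly ([freeze_feature_modules]) first;
#' when the query class count differs from the head width, call
#' [replace_head] beforehand.
#'
#' @param object a fitted `cellattn` model with frozen feature modules.
#' @param query a [cell_counts] object with labels, gene-aligned to the
#'   model (see [align_genes]).
#' @param epochs fine-tuning epochs (the published protocol uses 10 or 50).
#' @param config a [train_config] for optimizer/schedule settings; its
#'   `train_fraction` is overridden by `finetune_fraction`.
#' @param finetune_fraction fraction of query cells used for head training
#'   (default 0.2; the remaining cells are the held-out test set).
#' @return A fitted `cellattn` model for the query (with `$history` of the
#'   fine-tuning run); `epochs = 0` returns the model with parameters
#'   untouched and an empty history.
#' @export
fine_tune <- function(object, query, epochs = 10L, config = train_config(),
                      finetune_fraction = 0.2) {
  stopifnot(inherits(object, "cellattn"), inherits(query, "cell_counts"))
  state <- object$state
  if (isTRUE(state$trainable$attention) || isTRUE(state$trainable$projection))
    stop("feature modules are trainable; call freeze_feature_modules() first")
  if (is.null(query$labels)) stop("query labels are required for fine-tuning")
  y <- factor(query$labels)
  if (nlevels(y) != state$arch$n_classes)
    stop("query has ", nlevels(y), " classes but the head expects ",
         state$arch$n_classes, "; use replace_head() first")
  if (!identical(query$gene_names, object$gene_names))
    stop("query genes do not match the model's gene space; use align_genes()")
  cfg <- config
  cfg$epochs <- as.integer(epochs)
  cfg$train_fraction <- finetune_fraction
  out <- object
  out$levels <- levels(y)
  if (epochs == 0) {
    out$history <- out$history[0, ]
    return(out)
  }
  res <- train_loop(state, query$counts, y, cfg)
  out$state <- res$state
  out$history <- res$history
  out$n_train <- length(res$split$train)
  out$n_val <- length(res$split$test)
  out$holdout <- res$split$test
  out$call <- match.call()
  out
}

#' Evaluate a model on labeled data
#'
#' Convenience wrapper computing accuracy and weighted F1 of the model's
#' predictions on a labeled [cell_counts] object.
#'
#' @param object a fitted `cellattn` model.
#' @param data a labeled [cell_counts] object.
#' @param cells optional cell indices to evaluate on.
#' @return List with `accuracy` and `weighted_f1`.
#' @export
evaluate_model <- function(object, data, cells = NULL) {
  stopifnot(inherits(data, "cell_counts"), !is.null(data$labels))
  if (!is.null(cells)) data <- subset_counts(data, cells = cells)
  pred <- predict(object, data, type = "class")
  truth <- as.character(data$labels)
  list(accuracy = mean(pred == truth), weighted_f1 = weighted_f1(truth, pred))
}
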