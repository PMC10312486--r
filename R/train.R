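#' Training configuration
#'
#' Defaults follow the published protocol: Adam at learning rate 1e-4 for 50
#' epochs with an exponential schedule that first decays at epoch 10 and then
#' every 5 epochs (gamma = 0.95), mini-batches of 128 cells, and a stratified
#' 80/20 train/validation split.
#'
#' @param lr base learning rate (> 0).
#' @param epochs number of training epochs (>= 1).
#' @param schedule_start_epoch 0-based epoch of the first decay event.
#' @param schedule_interval epochs between subsequent decay events.
#' @param gamma multiplicative decay factor in (0, 1].
#' @param batch_size mini-batch size.
#' @param train_fraction fraction of cells used for training (rest for
#'   validation), in (0, 1).
#' @param seed integer seed controlling the split, shuffling and any model
#'   initialization derived from it.
#' @return A list of class `cellattn_train_config`.
#' @export
train_config <- function(lr = 1e-4, epochs = 50L, schedule_start_epoch = 10L,
                         schedule_interval = 5L, gamma = 0.95,
                         batch_size = 128L, train_fraction = 0.8, seed = 1L) {
  stopifnot(lr > 0, epochs >= 1, schedule_start_epoch >= 0,
            schedule_interval >= 1, gamma > 0, gamma <= 1, batch_size >= 1,
            train_fraction > 0, train_fraction < 1)
  structure(list(lr = lr, epochs = as.integer(epochs),
                 schedule_start_epoch = as.integer(schedule_start_epoch),
                 schedule_interval = as.integer(schedule_interval),
                 gamma = gamma, batch_size = as.integer(batch_size),
                 train_fraction = train_fraction, seed = as.integer(seed)),
            class = "cellattn_train_config")
}

#' Learning rate at a given epoch
#'
#' Exponential schedule: the learning rate is `lr * gamma^d`, where `d` is
#' the number of decay events at or before the (0-based) epoch; events fall
#' at `schedule_start_epoch`, then every `schedule_interval` epochs (with the
#' defaults: epochs 10, 15, 20, ...).
#'
#' @param epoch 0-based epoch index.
#' @param cfg a [train_config].
#' @return The learning rate used for that epoch.
#' @export
schedule_lr <- function(epoch, cfg = train_config()) {
  d <- ifelse(epoch < cfg$schedule_start_epoch, 0,
              (epoch - cfg$schedule_start_epoch) %/% cfg$schedule_interval + 1)
  cfg$lr * cfg$gamma^d
}

# Adam step over the trainable subset of parameters. `opt` carries first and
# second moment estimates plus the step counter.
adam_step <- function(params, grads, opt, lr, trainable,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  c1 <- 1 - beta1^opt$t
  c2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    if (!trainable[[param_module(nm)]]) next
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / c1) / (sqrt(opt$v[[nm]] / c2) + eps)
  }
  list(params = params, opt = opt)
}

# Core mini-batch loop shared by cellattn() and fine_tune(). X: C x N matrix,
# y: factor over all cells. Returns list(state, history, split).
train_loop <- function(state, X, y, cfg, verbose = FALSE) {
  stopifnot(is.factor(y), nrow(X) == length(y))
  if (nlevels(y) < 2) stop("training needs >= 2 label classes")
  if (nlevels(y) != state$arch$n_classes)
    stop("labels have ", nlevels(y), " classes but the head has ",
         state$arch$n_classes)
  split <- stratified_split(y, cfg$train_fraction, derive_seed(cfg$seed, 1L))
  if (length(setdiff(levels(y), unique(as.character(y[split$train])))))
    stop("a class is absent from the training split; too few cells per class")
  ytr <- as.integer(y[split$train]); Xtr <- X[split$train, , drop = FALSE]
  yva <- y[split$test]; Xva <- X[split$test, , drop = FALSE]
  opt <- list(t = 0L,
              m = lapply(state$params, function(p) p * 0),
              v = lapply(state$params, function(p) p * 0))
  n_tr <- length(ytr)
  hist <- data.frame(epoch = seq_len(cfg$epochs) - 1L, loss = NA_real_,
                     val_accuracy = NA_real_, val_weighted_f1 = NA_real_,
                     lr = NA_real_)
  for (ep in seq_len(cfg$epochs) - 1L) {
    lr_ep <- schedule_lr(ep, cfg)
    ord <- with_seed(derive_seed(cfg$seed, 100L + ep), sample.int(n_tr))
    losses <- numeric(0)
    for (b0 in seq(1L, n_tr, by = cfg$batch_size)) {
      idx <- ord[b0:min(b0 + cfg$batch_size - 1L, n_tr)]
      gr <- model_grad(state, Xtr[idx, , drop = FALSE], ytr[idx])
      upd <- adam_step(state$params, gr$grads, opt, lr_ep, state$trainable)
      state$params <- upd$params; opt <- upd$opt
      losses <- c(losses, gr$loss)
    }
    pv <- forward_pass(state, Xva)$logits
    pred <- levels(y)[max.col(pv, ties.method = "first")]
    hist$loss[ep + 1L] <- mean(losses)
    hist$val_accuracy[ep + 1L] <- mean(pred == as.character(yva))
    hist$val_weighted_f1[ep + 1L] <- weighted_f1(yva, pred)
    hist$lr[ep + 1L] <- lr_ep
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  val acc %.3f  val F1 %.3f  lr %.3g",
                      ep, hist$loss[ep + 1L], hist$val_accuracy[ep + 1L],
                      hist$val_weighted_f1[ep + 1L], lr_ep))
  }
  list(state = state, history = hist, split = split)
}

#' Fit the additive-attention classifier
#'
#' Trains the three-module network (attention, projection blocks,
#' configuration head) on a labeled count matrix by minimizing cross-entropy
#' with Adam under the exponential learning-rate schedule of
#' [train_config]. The split, shuffling and initialization all derive from
#' `config$seed`, so a fit is exactly reproducible.
#'
#' @param x a [cell_counts] object with labels, or a C x N count matrix.
#' @param labels per-cell labels; defaults to `x$labels`.
#' @param arch an [arch_config]; by default one is built for the data with
#'   the standard architecture (k = 2 blocks, h = 4 branches, bottleneck
#'   128) and seed derived from `config$seed`.
#' @param config a [train_config].
#' @param verbose print per-epoch progress.
#' @return An object of class `cellattn` with elements `state` (parameters),
#'   `history` (per-epoch loss, validation accuracy, weighted F1, learning
#'   rate), `levels` (class labels), `gene_names`, `config` and `call`.
#' @seealso [predict.cellattn], [fine_tune], [global_markers]
#' @examples
#' sim <- simulate_counts(simulation_config(n_cells = 300, n_genes = 60,
#'                                          n_types = 3, markers_per_type = 5,
#'                                          seed = 7))
#' fit <- cellattn(sim$data, config = train_config(epochs = 3, seed = 7))
#' fit
#' @export
cellattn <- function(x, labels = NULL, arch = NULL, config = train_config(),
                     verbose = FALSE) {
  X <- as_count_matrix(x)
  if (is.null(labels) && inherits(x, "cell_counts")) labels <- x$labels
  if (is.null(labels)) stop("labels are required (or use pseudo_label())")
  y <- factor(labels)
  if (nlevels(y) < 2) stop("training needs >= 2 label classes")
  if (is.null(arch))
    arch <- arch_config(ncol(X), nlevels(y), seed = derive_seed(config$seed, 7L))
  if (arch$n_classes != nlevels(y))
    stop("arch$n_classes (", arch$n_classes, ") != number of label classes (",
         nlevels(y), ")")
  state <- init_model(arch)
  res <- train_loop(state, X, y, config, verbose = verbose)
  structure(list(state = res$state, history = res$history,
                 levels = levels(y),
                 gene_names = colnames(X), config = config,
                 n_train = length(res$split$train),
                 n_val = length(res$split$test),
                 holdout = res$split$test,
                 call = match.call()),
            class = "cellattn")
}

#' K-means pseudo-labels on a PCA embedding
#'
#' A deterministic fallback so the pipeline can run fully unsupervised
#' without external clustering tools: log1p-transform, PCA, then k-means.
#' Intended as plumbing, not as a high-fidelity clustering method.
#'
#' @param mat a [cell_counts] object or count matrix.
#' @param n_clusters number of clusters (>= 2, <= number of cells).
#' @param seed integer seed.
#' @param n_pcs number of principal components (default 20, capped by the
#'   data dimensions).
#' @return Character vector of cluster labels `"c1"..."ck"`.
#' @export
pseudo_label <- function(mat, n_clusters, seed = 1L, n_pcs = 20L) {
  X <- as_count_matrix(mat)
  C <- nrow(X)
  if (n_clusters < 2) stop("n_clusters must be >= 2")
  if (n_clusters > C)
    stop("n_clusters (", n_clusters, ") exceeds the number of cells (", C, ")")
  if (n_clusters == C) return(paste0("c", seq_len(C)))
  Xl <- log1p(X)
  keep <- which(apply(Xl, 2, stats::sd) > 0)
  n_pcs <- min(n_pcs, length(keep) - 1L, C - 1L)
  emb <- with_seed(derive_seed(seed, 11L),
                   stats::prcomp(Xl[, keep, drop = FALSE], center = TRUE,
                                 scale. = FALSE)$x[, seq_len(n_pcs), drop = FALSE])
  km <- with_seed(derive_seed(seed, 12L),
                  stats::kmeans(emb, centers = n_clusters, nstart = 10L,
                                iter.max = 100L))
  paste0("c", km$cluster)
}
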