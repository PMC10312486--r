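# Additive-attention network: three serial modules operating on a C x N
# count matrix X (cells x genes).
#
#   1. Attention: per-cell gene logits from a linear map of the cell's
#      expression row; row-softmax gives the attention weights A in (0,1)^{CxN}
#      (rows sum to 1), and the gene scores are Gamma = A (.) X. The default
#      map is diagonal-affine (one gain and one shift per gene), which keeps
#      the attention a monotone function of the gene's own expression; dense
#      and low-rank dense maps are available.
#   2. Projection: k serial blocks. Each block runs h parallel linear branches
#      on its input, concatenates back to width N, passes an N -> bottleneck
#      -> N subnetwork with a ReLU in between, adds a residual connection from
#      the gene scores, and applies per-cell LayerNorm with learned affine.
#   3. Configuration head: linear map N -> T classes with a Leaky ReLU,
#      producing the class logits. This is the only module retrained in
#      transfer learning.

#' Architecture configuration
#'
#' @param n_genes number of genes N the model expects.
#' @param n_classes number of output classes T.
#' @param n_blocks number of projection blocks k (default 2).
#' @param n_branches parallel linear branches h per block (default 4). Each
#'   branch maps N to floor(N/h) features, the last absorbing the remainder,
#'   so the concatenation has width exactly N.
#' @param bottleneck width of the block subnetwork (default 128).
#' @param leaky_slope negative slope of the head's Leaky ReLU (default 0.01).
#' @param layernorm_eps LayerNorm variance floor (default 1e-5).
#' @param attention_form form of the linear map producing the attention
#'   logits from the cell's expression row: `"diag"` (default) uses one gain
#'   and one shift per gene (`logit_ij = w_j x_ij + b_j`), so attention is a
#'   monotone function of the gene's own expression; `"dense"` uses a full
#'   N x N affine map; `"lowrank"` factorizes the dense map N -> r -> N.
#' @param attention_rank rank r of the `"lowrank"` attention map.
#' @param attention_gain initial value of the diagonal attention gains
#'   (default 0.1); ignored by the other forms, which use the fan-in scheme.
#' @param input_transform `"identity"` (default: the network consumes raw
#'   counts) or `"log1p"`.
#' @param seed integer seed for parameter initialization.
#' @return A list of class `cellattn_arch`.
#' @export
arch_config <- function(n_genes, n_classes, n_blocks = 2L, n_branches = 4L,
                        bottleneck = 128L, leaky_slope = 0.01,
                        layernorm_eps = 1e-5,
                        attention_form = c("diag", "dense", "lowrank"),
                        attention_rank = NULL, attention_gain = 0.1,
                        input_transform = c("identity", "log1p"), seed = 1L) {
  input_transform <- match.arg(input_transform)
  attention_form <- match.arg(attention_form)
  stopifnot(n_genes >= 1, n_classes >= 1, n_blocks >= 1, n_branches >= 1,
            bottleneck >= 1, leaky_slope > 0, layernorm_eps > 0)
  if (n_branches > n_genes)
    stop("n_branches (", n_branches, ") exceeds n_genes (", n_genes, ")")
  if (attention_form == "lowrank") {
    if (is.null(attention_rank))
      stop("attention_form = 'lowrank' needs attention_rank")
    stopifnot(attention_rank >= 1)
  } else attention_rank <- NULL
  structure(list(n_genes = as.integer(n_genes),
                 n_classes = as.integer(n_classes),
                 n_blocks = as.integer(n_blocks),
                 n_branches = as.integer(n_branches),
                 bottleneck = as.integer(bottleneck),
                 leaky_slope = leaky_slope, layernorm_eps = layernorm_eps,
                 attention_form = attention_form,
                 attention_rank = if (is.null(attention_rank)) NULL
                                  else as.integer(attention_rank),
                 attention_gain = attention_gain,
                 input_transform = input_transform,
                 seed = as.integer(seed)),
            class = "cellattn_arch")
}

# Branch output widths: floor(N/h) each, last branch absorbs the remainder.
branch_widths <- function(n_genes, n_branches) {
  w <- rep(n_genes %/% n_branches, n_branches)
  w[n_branches] <- n_genes - sum(w[-n_branches])
  w
}

# Uniform fan-in initialization: U(-1/sqrt(fan_in), 1/sqrt(fan_in)).
init_mat <- function(n_in, n_out) {
  a <- 1 / sqrt(n_in)
  matrix(stats::runif(n_in * n_out, -a, a), n_in, n_out)
}

#' Initialize model parameters
#'
#' All linear maps use a seeded uniform fan-in scheme with zero biases;
#' LayerNorm gains start at 1 and shifts at 0. Initialization is fully
#' deterministic given `arch$seed`.
#'
#' @param arch an [arch_config] object.
#' @return A model-state list (class `cellattn_state`) with elements `arch`,
#'   `params` (named list of matrices/vectors) and `trainable` (logical flags
#'   per module: attention, projection, head).
#' @export
init_model <- function(arch) {
  stopifnot(inherits(arch, "cellattn_arch"))
  N <- arch$n_genes; Tn <- arch$n_classes; B <- arch$bottleneck
  params <- list()
  with_seed(arch$seed, {
    if (arch$attention_form == "diag") {
      params[["attn.w"]] <- rep(arch$attention_gain, N)
    } else if (arch$attention_form == "dense") {
      params[["attn.W"]] <- init_mat(N, N)
    } else {
      r <- arch$attention_rank
      params[["attn.U"]] <- init_mat(N, r)
      params[["attn.V"]] <- init_mat(r, N)
    }
    params[["attn.b"]] <- numeric(N)
    w <- branch_widths(N, arch$n_branches)
    for (i in seq_len(arch$n_blocks)) {
      for (j in seq_len(arch$n_branches)) {
        params[[sprintf("blk%d.br%d.W", i, j)]] <- init_mat(N, w[j])
        params[[sprintf("blk%d.br%d.b", i, j)]] <- numeric(w[j])
      }
      params[[sprintf("blk%d.W1", i)]] <- init_mat(N, B)
      params[[sprintf("blk%d.b1", i)]] <- numeric(B)
      params[[sprintf("blk%d.W2", i)]] <- init_mat(B, N)
      params[[sprintf("blk%d.b2", i)]] <- numeric(N)
      params[[sprintf("blk%d.ln.g", i)]] <- rep(1, N)
      params[[sprintf("blk%d.ln.b", i)]] <- numeric(N)
    }
    params[["head.W"]] <- init_mat(N, Tn)
    params[["head.b"]] <- numeric(Tn)
  })
  structure(list(arch = arch, params = params,
                 trainable = list(attention = TRUE, projection = TRUE,
                                  head = TRUE)),
            class = "cellattn_state")
}

# Module owning a parameter, from its name prefix.
param_module <- function(name) {
  if (startsWith(name, "attn.")) "attention"
  else if (startsWith(name, "head.")) "head"
  else "projection"
}

# ---- numerics helpers -------------------------------------------------------

softmax_rows <- function(x) {
  # subtract per-row max for stability (mathematically identical)
  m <- x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]
  e <- exp(x - m)
  e / rowSums(e)
}

scale_cols <- function(x, g) x * rep(g, each = nrow(x))

shift_cols <- function(x, b) x + rep(b, each = nrow(x))

as_count_matrix <- function(x) {
  if (inherits(x, "cell_counts")) x$counts else as.matrix(x)
}

check_gene_dim <- function(X, state) {
  if (ncol(X) != state$arch$n_genes)
    stop("input has ", ncol(X), " genes but the model expects ",
         state$arch$n_genes)
}

# ---- forward pass -----------------------------------------------------------

#' Attention module forward pass
#'
#' Computes per-cell gene attention weights A (row-softmax of a learned
#' affine map of the expression row) and the gene scores Gamma = A (.) X.
#'
#' @param X a [cell_counts] object or C x N numeric matrix of counts.
#' @param state a model state from [init_model] or a fitted model's `$state`.
#' @return List with `A` (C x N, rows summing to 1) and `gamma` (C x N).
#' @export
attention_forward <- function(X, state) {
  X <- as_count_matrix(X)
  check_gene_dim(X, state)
  fw <- forward_pass(state, X)
  list(A = fw$A, gamma = fw$gamma)
}

#' Projection blocks forward pass
#'
#' Applies the k projection blocks to a gene-score matrix: parallel branches,
#' concatenation, bottleneck subnetwork, residual from the gene scores,
#' LayerNorm.
#'
#' @param gamma C x N gene-score matrix (residual source for every block).
#' @param state a model state.
#' @return C x N projected representation.
#' @export
projection_forward <- function(gamma, state) {
  gamma <- as.matrix(gamma)
  check_gene_dim(gamma, state)
  projection_pass(state, gamma, cache = FALSE)$out
}

#' Configuration head forward pass
#'
#' @param rep C x N representation from the projection blocks.
#' @param state a model state.
#' @return C x T class logits (Leaky ReLU of a linear map).
#' @export
configuration_forward <- function(rep, state) {
  rep <- as.matrix(rep)
  check_gene_dim(rep, state)
  p <- state$params
  P <- shift_cols(rep %*% p[["head.W"]], p[["head.b"]])
  ifelse(P > 0, P, state$arch$leaky_slope * P)
}

#' Full model forward pass
#'
#' Composition of the attention module, the projection blocks and the
#' configuration head; returns the class logits together with the attention
#' tensor so interpretation needs no second pass.
#'
#' @inheritParams attention_forward
#' @return List with `logits` (C x T) and `A` (C x N attention weights).
#' @export
model_forward <- function(X, state) {
  X <- as_count_matrix(X)
  check_gene_dim(X, state)
  fw <- forward_pass(state, X)
  list(logits = fw$logits, A = fw$A)
}

# Shared forward with optional caches for backprop.
forward_pass <- function(state, X, cache = FALSE) {
  arch <- state$arch; p <- state$params
  Xin <- if (arch$input_transform == "log1p") log1p(X) else X
  M <- NULL
  if (arch$attention_form == "diag") {
    L <- shift_cols(scale_cols(Xin, p[["attn.w"]]), p[["attn.b"]])
  } else if (arch$attention_form == "dense") {
    L <- shift_cols(Xin %*% p[["attn.W"]], p[["attn.b"]])
  } else {
    M <- Xin %*% p[["attn.U"]]
    L <- shift_cols(M %*% p[["attn.V"]], p[["attn.b"]])
  }
  A <- softmax_rows(L)
  gamma <- A * Xin
  proj <- projection_pass(state, gamma, cache = cache)
  P3 <- shift_cols(proj$out %*% p[["head.W"]], p[["head.b"]])
  logits <- ifelse(P3 > 0, P3, arch$leaky_slope * P3)
  out <- list(A = A, gamma = gamma, rep = proj$out, logits = logits)
  if (cache) {
    out$Xin <- Xin; out$M <- M; out$P3 <- P3; out$blocks <- proj$blocks
  }
  out
}

projection_pass <- function(state, gamma, cache = FALSE) {
  arch <- state$arch; p <- state$params
  N <- arch$n_genes; h <- arch$n_branches
  w <- branch_widths(N, h)
  ends <- cumsum(w); starts <- ends - w + 1L
  Z <- gamma
  blocks <- if (cache) vector("list", arch$n_blocks) else NULL
  for (i in seq_len(arch$n_blocks)) {
    Bm <- matrix(0, nrow(Z), N)
    for (j in seq_len(h)) {
      Bm[, starts[j]:ends[j]] <-
        shift_cols(Z %*% p[[sprintf("blk%d.br%d.W", i, j)]],
                   p[[sprintf("blk%d.br%d.b", i, j)]])
    }
    P <- shift_cols(Bm %*% p[[sprintf("blk%d.W1", i)]],
                    p[[sprintf("blk%d.b1", i)]])
    H <- pmax(P, 0)
    S <- shift_cols(H %*% p[[sprintf("blk%d.W2", i)]],
                    p[[sprintf("blk%d.b2", i)]])
    R <- S + gamma                      # residual from the gene scores
    mu <- rowMeans(R)
    v <- rowMeans((R - mu)^2)           # population variance per cell
    sd <- sqrt(v + arch$layernorm_eps)
    Rhat <- (R - mu) / sd
    out <- shift_cols(scale_cols(Rhat, p[[sprintf("blk%d.ln.g", i)]]),
                      p[[sprintf("blk%d.ln.b", i)]])
    if (cache)
      blocks[[i]] <- list(Zin = Z, Bm = Bm, P = P, H = H, sd = sd, Rhat = Rhat)
    Z <- out
  }
  list(out = Z, blocks = blocks)
}

# ---- backward pass ----------------------------------------------------------

# Mean cross-entropy loss and gradients for a labeled batch.
# y: integer class indices in 1..T. Returns list(loss, grads).
model_grad <- function(state, X, y) {
  arch <- state$arch; p <- state$params
  C <- nrow(X); N <- arch$n_genes; Tn <- arch$n_classes
  fw <- forward_pass(state, X, cache = TRUE)
  probs <- softmax_rows(fw$logits)
  loss <- -mean(log(pmax(probs[cbind(seq_len(C), y)], 1e-300)))
  g <- list()

  dlogits <- probs
  dlogits[cbind(seq_len(C), y)] <- dlogits[cbind(seq_len(C), y)] - 1
  dlogits <- dlogits / C
  dP3 <- dlogits * ifelse(fw$P3 > 0, 1, arch$leaky_slope)
  g[["head.W"]] <- crossprod(fw$rep, dP3)
  g[["head.b"]] <- colSums(dP3)
  dZ <- dP3 %*% t(p[["head.W"]])

  h <- arch$n_branches
  w <- branch_widths(N, h)
  ends <- cumsum(w); starts <- ends - w + 1L
  dGamma <- matrix(0, C, N)
  for (i in rev(seq_len(arch$n_blocks))) {
    bl <- fw$blocks[[i]]
    ln_g <- p[[sprintf("blk%d.ln.g", i)]]
    g[[sprintf("blk%d.ln.g", i)]] <- colSums(dZ * bl$Rhat)
    g[[sprintf("blk%d.ln.b", i)]] <- colSums(dZ)
    dRhat <- scale_cols(dZ, ln_g)
    dR <- (dRhat - rowMeans(dRhat) -
             bl$Rhat * rowMeans(dRhat * bl$Rhat)) / bl$sd
    dGamma <- dGamma + dR               # residual path
    W2 <- p[[sprintf("blk%d.W2", i)]]
    g[[sprintf("blk%d.W2", i)]] <- crossprod(bl$H, dR)
    g[[sprintf("blk%d.b2", i)]] <- colSums(dR)
    dP <- (dR %*% t(W2)) * (bl$P > 0)
    W1 <- p[[sprintf("blk%d.W1", i)]]
    g[[sprintf("blk%d.W1", i)]] <- crossprod(bl$Bm, dP)
    g[[sprintf("blk%d.b1", i)]] <- colSums(dP)
    dB <- dP %*% t(W1)
    dZin <- matrix(0, C, N)
    for (j in seq_len(h)) {
      idx <- starts[j]:ends[j]
      Wb <- p[[sprintf("blk%d.br%d.W", i, j)]]
      g[[sprintf("blk%d.br%d.W", i, j)]] <- crossprod(bl$Zin, dB[, idx, drop = FALSE])
      g[[sprintf("blk%d.br%d.b", i, j)]] <- colSums(dB[, idx, drop = FALSE])
      dZin <- dZin + dB[, idx, drop = FALSE] %*% t(Wb)
    }
    dZ <- dZin
  }
  dGamma <- dGamma + dZ                 # block 1 consumed gamma as its input

  dA <- dGamma * fw$Xin
  dL <- fw$A * (dA - rowSums(dA * fw$A))
  if (arch$attention_form == "diag") {
    g[["attn.w"]] <- colSums(dL * fw$Xin)
  } else if (arch$attention_form == "dense") {
    g[["attn.W"]] <- crossprod(fw$Xin, dL)
  } else {
    g[["attn.V"]] <- crossprod(fw$M, dL)
    g[["attn.U"]] <- crossprod(fw$Xin, dL %*% t(p[["attn.V"]]))
  }
  g[["attn.b"]] <- colSums(dL)
  list(loss = loss, grads = g)
}
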