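# Straight-line re-implementation of the network algebra, written against
# the published description rather than the package's forward code: softmax
# attention -> gene scores -> per-block branches/concatenation/bottleneck
# subnet with ReLU -> residual from the gene scores -> LayerNorm -> linear
# head with Leaky ReLU. Works cell by cell; used to cross-check
# model_forward.
oracle_forward <- function(state, X) {
  p <- state$params
  a <- state$arch
  N <- a$n_genes
  wdt <- rep(N %/% a$n_branches, a$n_branches)
  wdt[a$n_branches] <- N - sum(wdt[-a$n_branches])
  C <- nrow(X)
  logits <- matrix(NA_real_, C, a$n_classes)
  A <- matrix(NA_real_, C, N)
  for (i in seq_len(C)) {
    x <- X[i, ]
    if (a$input_transform == "log1p") x <- log1p(x)
    l <- switch(a$attention_form,
                diag = p[["attn.w"]] * x + p[["attn.b"]],
                dense = as.numeric(x %*% p[["attn.W"]]) + p[["attn.b"]],
                lowrank = as.numeric((x %*% p[["attn.U"]]) %*% p[["attn.V"]]) +
                  p[["attn.b"]])
    e <- exp(l - max(l))
    att <- e / sum(e)
    gam <- att * x
    z <- gam
    for (k in seq_len(a$n_blocks)) {
      cc <- numeric(0)
      for (j in seq_len(a$n_branches)) {
        Wb <- p[[sprintf("blk%d.br%d.W", k, j)]]
        bb <- p[[sprintf("blk%d.br%d.b", k, j)]]
        cc <- c(cc, as.numeric(z %*% Wb) + bb)
      }
      pre <- as.numeric(cc %*% p[[sprintf("blk%d.W1", k)]]) +
        p[[sprintf("blk%d.b1", k)]]
      hid <- ifelse(pre > 0, pre, 0)
      s <- as.numeric(hid %*% p[[sprintf("blk%d.W2", k)]]) +
        p[[sprintf("blk%d.b2", k)]]
      r <- s + gam
      m <- mean(r)
      v <- mean((r - m)^2)
      rh <- (r - m) / sqrt(v + a$layernorm_eps)
      z <- rh * p[[sprintf("blk%d.ln.g", k)]] + p[[sprintf("blk%d.ln.b", k)]]
    }
    hl <- as.numeric(z %*% p[["head.W"]]) + p[["head.b"]]
    logits[i, ] <- ifelse(hl > 0, hl, a$leaky_slope * hl)
    A[i, ] <- att
  }
  list(logits = logits, A = A)
}

# Zero out every parameter of a module (for analytic-limit tests).
zero_module <- function(state, module) {
  for (nm in names(state$params))
    if (cellattn:::param_module(nm) == module) state$params[[nm]][] <- 0
  state
}
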