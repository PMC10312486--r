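# Checkpoint format (version 1): a single binary file holding
#   [int32 header_length][JSON header][float64 parameter arrays]
# The JSON header records the format version, the architecture, the
# per-module trainable flags, class levels (if any) and a manifest of
# parameter names and dimensions; arrays follow in manifest order as
# little-endian doubles, so a save/load round-trip is bit-exact.

CHECKPOINT_VERSION <- 1L

#' Save or load a model checkpoint
#'
#' @param state a `cellattn_state` (or a fitted `cellattn` object, whose
#'   state and class levels are stored).
#' @param path file path for the checkpoint.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns a `cellattn_state` with attribute `"levels"` when class levels
#'   were stored.
#' @export
save_checkpoint <- function(state, path) {
  levels <- NULL
  if (inherits(state, "cellattn")) {
    levels <- state$levels
    state <- state$state
  }
  stopifnot(inherits(state, "cellattn_state"))
  manifest <- lapply(names(state$params), function(nm) {
    p <- state$params[[nm]]
    list(name = nm, dim = if (is.matrix(p)) dim(p) else length(p))
  })
  header <- jsonlite::toJSON(
    list(magic = "cellattn-checkpoint", version = CHECKPOINT_VERSION,
         arch = unclass(state$arch), trainable = state$trainable,
         levels = levels, manifest = manifest),
    auto_unbox = TRUE, null = "null", digits = NA)
  hb <- charToRaw(as.character(header))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(length(hb), con, size = 4L, endian = "little")
  writeBin(hb, con)
  for (nm in names(state$params))
    writeBin(as.numeric(state$params[[nm]]), con, size = 8L,
             endian = "little")
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hlen <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (length(hlen) != 1L || is.na(hlen) || hlen <= 0L ||
      hlen > file.size(path))
    stop("corrupt checkpoint header in ", path)
  hb <- readBin(con, "raw", hlen)
  if (length(hb) != hlen) stop("truncated checkpoint: ", path)
  header <- jsonlite::fromJSON(rawToChar(hb), simplifyVector = TRUE)
  if (!identical(header$magic, "cellattn-checkpoint"))
    stop("not a cellattn checkpoint: ", path)
  if (!identical(as.integer(header$version), CHECKPOINT_VERSION))
    stop("incompatible checkpoint version ", header$version,
         " (this build reads version ", CHECKPOINT_VERSION, ")")
  a <- header$arch
  arch <- arch_config(a$n_genes, a$n_classes, a$n_blocks, a$n_branches,
                      a$bottleneck, a$leaky_slope, a$layernorm_eps,
                      a$attention_form, a$attention_rank, a$attention_gain,
                      a$input_transform, a$seed)
  manifest <- header$manifest
  params <- list()
  for (i in seq_len(nrow(manifest))) {
    nm <- manifest$name[i]
    dm <- manifest$dim[[i]]
    n <- prod(dm)
    vals <- readBin(con, "numeric", n, size = 8L, endian = "little")
    if (length(vals) != n)
      stop("truncated checkpoint: array '", nm, "' incomplete in ", path)
    params[[nm]] <- if (length(dm) == 2L) matrix(vals, dm[1], dm[2]) else vals
  }
  state <- structure(list(arch = arch, params = params,
                          trainable = lapply(header$trainable, isTRUE)),
                     class = "cellattn_state")
  validate_state(state)
  if (!is.null(header$levels)) attr(state, "levels") <- header$levels
  state
}

# Shape consistency between the architecture header and parameter arrays.
validate_state <- function(state) {
  arch <- state$arch
  N <- arch$n_genes; Tn <- arch$n_classes; B <- arch$bottleneck
  expect_dim <- function(nm, d) {
    p <- state$params[[nm]]
    if (is.null(p)) stop("checkpoint missing parameter '", nm, "'")
    got <- if (is.matrix(p)) dim(p) else length(p)
    if (!identical(as.integer(got), as.integer(d)))
      stop("parameter '", nm, "' has shape (", paste(got, collapse = "x"),
           ") but the architecture implies (", paste(d, collapse = "x"), ")")
  }
  if (arch$attention_form == "diag") expect_dim("attn.w", N)
  else if (arch$attention_form == "dense") expect_dim("attn.W", c(N, N))
  else {
    expect_dim("attn.U", c(N, arch$attention_rank))
    expect_dim("attn.V", c(arch$attention_rank, N))
  }
  expect_dim("attn.b", N)
  w <- branch_widths(N, arch$n_branches)
  for (i in seq_len(arch$n_blocks)) {
    for (j in seq_len(arch$n_branches)) {
      expect_dim(sprintf("blk%d.br%d.W", i, j), c(N, w[j]))
      expect_dim(sprintf("blk%d.br%d.b", i, j), w[j])
    }
    expect_dim(sprintf("blk%d.W1", i), c(N, B))
    expect_dim(sprintf("blk%d.b1", i), B)
    expect_dim(sprintf("blk%d.W2", i), c(B, N))
    expect_dim(sprintf("blk%d.b2", i), N)
    expect_dim(sprintf("blk%d.ln.g", i), N)
    expect_dim(sprintf("blk%d.ln.b", i), N)
  }
  expect_dim("head.W", c(N, Tn))
  expect_dim("head.b", Tn)
  invisible(state)
}
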