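#' @keywords internal
"_PACKAGE"

# Run code with a temporary RNG state seeded at `seed`, restoring the caller's
# stream afterwards so library functions never perturb user-level randomness.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic fan-out of one user seed into named sub-seeds (kept < 2^31).
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1009L + as.integer(offset) %% 1009L
}

#' Weighted F1 score
#'
#' F1 averaged over classes with weights proportional to the class support in
#' `truth` (the headline classification metric used throughout the package).
#' Classes absent from `truth` contribute zero weight; a class with no
#' predicted and no true positives has F1 defined as 0.
#'
#' @param truth factor or vector of reference labels.
#' @param pred factor or vector of predicted labels, same length.
#' @return A single number in \[0, 1\].
#' @export
weighted_f1 <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  truth <- as.character(truth)
  pred <- as.character(pred)
  classes <- sort(unique(truth))
  f1 <- vapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    if (tp == 0 && (fp + fn) > 0) return(0)
    if (tp == 0) return(0)
    prec <- tp / (tp + fp)
    rec <- tp / (tp + fn)
    2 * prec * rec / (prec + rec)
  }, numeric(1))
  support <- vapply(classes, function(cl) sum(truth == cl), numeric(1))
  sum(f1 * support) / sum(support)
}

# Stratified index split: returns list(train=, test=) with `frac` of each class
# in train (at least 1 per class in each part when the class allows it).
stratified_split <- function(labels, frac, seed) {
  labels <- as.character(labels)
  idx_by_class <- split(seq_along(labels), labels)
  train <- integer(0)
  with_seed(seed, {
    for (idx in idx_by_class) {
      n_tr <- round(length(idx) * frac)
      n_tr <- max(1L, min(length(idx) - 1L, n_tr))
      train <- c(train, sample(idx, n_tr))
    }
  })
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}
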