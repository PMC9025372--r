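#' @useDynLib cellmark, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats predict rnbinom runif sd setNames pbinom
#' @importFrom utils write.table read.table head
NULL

# One global seed drives one named stream per operation: each stage hashes
# its name into a sub-seed so stages stay reproducible independently of how
# many random draws earlier stages consumed. Kept well below 2^31.
stream_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream))) %% 4096L
  (as.integer(seed) %% 524287L) * 4096L + as.integer(h)
}

# Evaluate `code` under a temporary RNG state seeded from (seed, stream),
# restoring the caller's RNG state afterwards.
with_stream <- function(seed, stream, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(stream_seed(seed, stream))
  force(code)
}

# Stratified fold assignment. Returns an integer vector of fold ids in
# 1..n_folds. Within each class, samples are shuffled and dealt round-robin
# starting from a rotating fold, so classes with fewer samples than folds
# still land in distinct folds (each such sample is tested exactly once).
stratified_folds <- function(labels, n_folds) {
  labels <- as.factor(labels)
  fold <- integer(length(labels))
  offset <- 0L
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- ((offset + seq_along(idx) - 1L) %% n_folds) + 1L
    offset <- offset + length(idx)
  }
  fold
}

# Stratified train/test split: returns logical vector, TRUE = train.
# Guarantees at least one training sample per class present in `labels`.
stratified_split <- function(labels, train_fraction) {
  labels <- as.factor(labels)
  train <- logical(length(labels))
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    n_tr <- max(1L, round(length(idx) * train_fraction))
    train[idx[sample.int(length(idx))[seq_len(n_tr)]]] <- TRUE
  }
  train
}
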