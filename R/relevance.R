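#' Discretize a gene's expression into three states
#'
#' Continuous expression values are mapped to `low` / `mid` / `high` by
#' their distance from the gene's mean: values below
#' `mean - alpha * sd` are `low`, above `mean + alpha * sd` are `high`,
#' and `mid` otherwise. The standard deviation uses denominator `n`
#' (population form). A constant gene (sd = 0) is all `mid`. This is the
#' classic three-state preprocessing used by mutual-information feature
#' filters on expression data.
#'
#' @param values numeric vector of one gene's expression across cells.
#' @param alpha positive multiplier on the standard deviation.
#' @return factor with levels `low`, `mid`, `high`.
#' @export
discretize_gene <- function(values, alpha = 1.0) {
  if (length(values) == 0) stop("empty expression vector")
  if (alpha <= 0) stop("alpha must be positive")
  m <- mean(values)
  s <- sqrt(mean((values - m)^2))  # denominator n
  states <- rep("mid", length(values))
  if (s > 0) {
    states[values < m - alpha * s] <- "low"
    states[values > m + alpha * s] <- "high"
  }
  factor(states, levels = c("low", "mid", "high"))
}

#' Mutual information between two categorical vectors (bits)
#'
#' Plug-in estimate from the empirical joint table:
#' `sum p(x, y) * log2( p(x, y) / (p(x) p(y)) )`, with zero-probability
#' cells contributing 0. Symmetric in its arguments and non-negative up to
#' floating-point rounding.
#'
#' @param x,y equal-length categorical (factor/character/integer) vectors.
#' @return mutual information in bits.
#' @examples
#' mutual_information(c(1, 1, 2, 2), c(1, 1, 2, 2))  # 1 bit
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y)) {
    stop("x (", length(x), ") and y (", length(y), ") differ in length")
  }
  if (length(x) == 0) stop("empty input")
  joint <- table(x = as.character(x), y = as.character(y))
  n <- sum(joint)
  pxy <- joint / n
  px <- rowSums(pxy)
  py <- colSums(pxy)
  terms <- pxy * log2(pxy / outer(px, py))
  sum(terms[pxy > 0])
}

#' Maximum-relevance filter: retain genes informative about the label
#'
#' Scores every gene by the mutual information (bits) between its
#' three-state discretization and the cell-type label, and retains genes
#' scoring strictly above `threshold`. This implements the
#' maximum-relevance screening criterion alone — no redundancy term — as a
#' cheap first pass that removes only the clearly label-independent genes.
#'
#' @param matrix expression matrix (cells x genes).
#' @param labels label factor aligned to the rows of `matrix`.
#' @param threshold retention threshold on MI; a gene is kept when
#'   `MI > threshold` (strict).
#' @param alpha discretization width multiplier (see [discretize_gene()]).
#' @return list with `mi_scores` (named numeric, one per gene, input
#'   order), `retained` (character vector of retained gene ids, input order
#'   preserved), and `threshold`.
#' @export
max_relevance_filter <- function(matrix, labels, threshold = 0.001,
                                 alpha = 1.0) {
  if (nrow(matrix) != length(labels)) {
    stop("matrix and labels are not aligned")
  }
  if (threshold < 0) stop("threshold must be >= 0")
  y <- as.factor(labels)
  mi <- vapply(seq_len(ncol(matrix)), function(j) {
    mutual_information(discretize_gene(matrix[, j], alpha = alpha), y)
  }, numeric(1))
  names(mi) <- colnames(matrix)
  retained <- colnames(matrix)[mi > threshold]
  if (length(retained) == 0) {
    warning("no gene passed the relevance threshold ", threshold)
  }
  list(mi_scores = mi, retained = retained, threshold = threshold)
}
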