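#' SMOTE configuration
#' @param k_neighbors number of same-class nearest neighbours considered
#'   when interpolating (>= 1).
#' @param seed integer seed.
#' @return a `smote_config` list.
#' @export
smote_config <- function(k_neighbors = 5L, seed = 0L) {
  if (k_neighbors < 1) stop("k_neighbors must be >= 1")
  structure(list(k_neighbors = as.integer(k_neighbors),
                 seed = as.integer(seed)),
            class = "smote_config")
}

#' Balance classes by synthetic minority oversampling (SMOTE)
#'
#' Minority classes are oversampled until every class matches the majority
#' count. Each synthetic sample is built by picking a random minority
#' sample `x`, one of its `k` nearest same-class neighbours `y` (Euclidean
#' distance on the supplied features), and emitting the convex combination
#' `z = x + lambda * (y - x)` with `lambda ~ Uniform(0, 1)`. Original
#' samples are preserved, in order, ahead of the synthetic ones.
#'
#' @param x numeric matrix (samples x features).
#' @param labels class factor aligned to the rows of `x`.
#' @param config a [smote_config()].
#' @param lambda optional fixed interpolation weight in `[0, 1]` (test
#'   hook); `NULL` draws `Uniform(0, 1)` per synthetic sample.
#' @return list with `matrix` (original rows then synthetic rows),
#'   `labels` (aligned factor), `is_synthetic` (logical provenance tag per
#'   row, so synthetic samples can be kept out of evaluation) and
#'   `provenance` (one row per synthetic sample: original-row indices
#'   `base` and `neighbor`, and the drawn `lambda`).
#' @export
smote_balance <- function(x, labels, config = smote_config(),
                          lambda = NULL) {
  x <- as.matrix(x)
  labels <- as.factor(labels)
  if (nrow(x) != length(labels)) stop("matrix and labels are not aligned")
  counts <- table(labels)
  counts <- counts[counts > 0]
  target <- max(counts)
  if (all(counts == target)) {
    return(list(matrix = x, labels = labels,
                is_synthetic = rep(FALSE, nrow(x)),
                provenance = data.frame(base = integer(0),
                                        neighbor = integer(0),
                                        lambda = numeric(0))))
  }
  if (any(counts == 1)) {
    stop("class(es) with a single sample cannot be oversampled: ",
         paste(names(counts)[counts == 1], collapse = ", "))
  }
  with_stream(config$seed, "smote", {
    new_rows <- list()
    new_labels <- character(0)
    prov <- list()
    for (cl in names(counts)[counts < target]) {
      idx <- which(labels == cl)
      n_new <- target - length(idx)
      k <- config$k_neighbors
      if (k > length(idx) - 1) {
        k <- length(idx) - 1
        warning("k_neighbors clamped to ", k, " for class '", cl,
                "' (class size ", length(idx), ")")
      }
      xc <- x[idx, , drop = FALSE]
      d <- as.matrix(stats::dist(xc))
      diag(d) <- Inf
      # k nearest neighbours per sample; ties broken by row index
      nn <- t(apply(d, 1, function(row) order(row)[seq_len(k)]))
      if (k == 1) nn <- matrix(nn, ncol = 1)
      base <- sample.int(length(idx), n_new, replace = TRUE)
      pick <- sample.int(k, n_new, replace = TRUE)
      lam <- if (is.null(lambda)) runif(n_new) else rep(lambda, n_new)
      z <- xc[base, , drop = FALSE] +
        lam * (xc[nn[cbind(base, pick)], , drop = FALSE] -
                 xc[base, , drop = FALSE])
      rownames(z) <- sprintf("synth_%s_%04d", cl, seq_len(n_new))
      new_rows[[cl]] <- z
      new_labels <- c(new_labels, rep(cl, n_new))
      prov[[cl]] <- data.frame(base = idx[base],
                               neighbor = idx[nn[cbind(base, pick)]],
                               lambda = lam)
    }
    synth <- do.call(rbind, new_rows)
    out_x <- rbind(x, synth)
    out_labels <- factor(c(as.character(labels), new_labels),
                         levels = levels(labels))
    names(out_labels) <- rownames(out_x)
    list(matrix = out_x, labels = out_labels,
         is_synthetic = c(rep(FALSE, nrow(x)), rep(TRUE, nrow(synth))),
         provenance = do.call(rbind, c(prov, list(make.row.names = FALSE))))
  })
}
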