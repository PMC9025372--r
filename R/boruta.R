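#' Boruta configuration
#'
#' @param max_iter maximum number of random-forest iterations.
#' @param alpha significance level of the binomial hit test.
#' @param n_trees trees per random-forest iteration.
#' @param two_step_correction when `TRUE` (default) each iteration's
#'   binomial tests are corrected two ways at once — Benjamini-Hochberg
#'   across the undecided features and Bonferroni across the iterations a
#'   feature has been tested — and a decision requires passing both; when
#'   `FALSE` a plain Bonferroni correction across all candidate features
#'   is applied instead.
#' @param seed integer seed.
#' @return a `boruta_config` list.
#' @export
boruta_config <- function(max_iter = 100L, alpha = 0.05, n_trees = 100L,
                          two_step_correction = TRUE, seed = 0L) {
  if (max_iter < 1) stop("max_iter must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  structure(list(max_iter = as.integer(max_iter), alpha = alpha,
                 n_trees = as.integer(n_trees),
                 two_step_correction = isTRUE(two_step_correction),
                 seed = as.integer(seed)),
            class = "boruta_config")
}

#' Append shadow features to an expression matrix
#'
#' Each gene gets a shuffled duplicate (`shadow_<gene>`): the same values,
#' independently permuted across cells, so the shadow keeps the gene's
#' marginal distribution but loses any association with the labels. Shadow
#' importances provide the null against which real importances are judged.
#'
#' @param matrix expression matrix (cells x genes).
#' @param seed integer seed for the permutations.
#' @return matrix with `2 * ncol(matrix)` columns: the originals followed
#'   by their shadows.
#' @export
make_shadows <- function(matrix, seed = 0L) {
  if (ncol(matrix) < 1) stop("need at least one gene")
  with_stream(seed, "shadows", {
    shadows <- apply(matrix, 2, function(col) col[sample.int(length(col))])
    colnames(shadows) <- paste0("shadow_", colnames(matrix))
    cbind(matrix, shadows)
  })
}

#' All-relevant feature selection with shadow features (Boruta)
#'
#' Iteratively fits a random forest on the candidate genes plus freshly
#' re-shuffled shadow copies and records a *hit* for every undecided gene
#' whose impurity-decrease importance exceeds the maximum shadow
#' importance. After each iteration every undecided gene's hit count is
#' tested against Binomial(iterations, 0.5): significantly above chance
#' confirms the gene, significantly below rejects it. The loop stops when
#' no gene is undecided or `max_iter` is reached; genes still undecided
#' are *tentative*.
#'
#' @param matrix expression matrix restricted to the candidate genes
#'   (typically the relevance-filter survivors).
#' @param labels class factor aligned to rows.
#' @param config a [boruta_config()].
#' @return list with character vectors `confirmed`, `rejected`,
#'   `tentative` (a partition of the candidates), `hit_history` (per gene,
#'   logical hits over the iterations while it was undecided) and
#'   `n_iter` (iterations run).
#' @export
run_boruta <- function(matrix, labels, config = boruta_config()) {
  labels <- as.factor(labels)
  if (nrow(matrix) != length(labels)) {
    stop("matrix and labels are not aligned")
  }
  if (nlevels(droplevels(labels)) < 2) stop("need at least 2 classes")
  if (nrow(matrix) < nlevels(labels)) {
    stop("fewer cells (", nrow(matrix), ") than classes (",
         nlevels(labels), ")")
  }
  genes <- colnames(matrix)
  status <- setNames(rep("tentative", length(genes)), genes)
  hits <- setNames(integer(length(genes)), genes)
  trials <- setNames(integer(length(genes)), genes)
  hit_history <- setNames(vector("list", length(genes)), genes)
  n_cand <- length(genes)

  iter <- 0L
  while (iter < config$max_iter && any(status == "tentative")) {
    iter <- iter + 1L
    undecided <- names(status)[status == "tentative"]
    sub <- matrix[, undecided, drop = FALSE]
    shadowed <- make_shadows(sub, seed = stream_seed(config$seed,
                                                     paste0("iter", iter)))
    fit <- ranger::ranger(
      x = shadowed, y = labels, num.trees = config$n_trees,
      importance = "impurity", num.threads = 1L,
      seed = stream_seed(config$seed, paste0("rf", iter)))
    imp <- fit$variable.importance
    shadow_max <- max(imp[startsWith(names(imp), "shadow_")])
    hit_now <- imp[undecided] > shadow_max
    for (g in undecided) {
      hits[g] <- hits[g] + as.integer(hit_now[[g]])
      trials[g] <- trials[g] + 1L
      hit_history[[g]] <- c(hit_history[[g]], unname(hit_now[[g]]))
    }
    # two-sided decision on hit counts vs Binomial(trials, 0.5)
    p_hi <- pbinom(hits[undecided] - 1L, trials[undecided], 0.5,
                   lower.tail = FALSE)
    p_lo <- pbinom(hits[undecided], trials[undecided], 0.5)
    if (config$two_step_correction) {
      accept <- stats::p.adjust(p_hi, "BH") <= config$alpha &
        p_hi <= config$alpha / iter
      reject <- stats::p.adjust(p_lo, "BH") <= config$alpha &
        p_lo <= config$alpha / iter
    } else {
      accept <- p_hi <= config$alpha / n_cand
      reject <- p_lo <= config$alpha / n_cand
    }
    status[undecided[accept]] <- "confirmed"
    status[undecided[reject & !accept]] <- "rejected"
  }
  list(
    confirmed = genes[status[genes] == "confirmed"],
    rejected = genes[status[genes] == "rejected"],
    tentative = genes[status[genes] == "tentative"],
    hit_history = hit_history,
    n_iter = iter
  )
}
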