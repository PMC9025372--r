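#' Configuration for the synthetic expression generator
#'
#' The generator emulates the situation the pipeline is built for: a
#' multi-class single-cell dataset with strong class imbalance, a small set
#' of class-specific informative (marker) genes among many uninformative
#' ones, and sparse count-like values. Counts are drawn from a
#' zero-inflated negative binomial: every gene has baseline mean
#' `baseline_mean`, markers of a cell's own class have their mean shifted
#' up by a factor `exp(effect_size)`, and each value is independently
#' zeroed with probability `dropout_rate`.
#'
#' When `class_sizes` is `NULL`, per-class sizes are drawn once (from the
#' seed) log-uniformly between `size_range[1]` and `size_range[2]`,
#' mimicking the orders-of-magnitude spread between the most and least
#' abundant cell types in real atlases.
#'
#' @param n_classes number of cell types (>= 2).
#' @param class_sizes explicit integer vector of cells per class, or `NULL`
#'   to draw log-uniform sizes from `size_range`.
#' @param size_range two-tier bound for drawn class sizes.
#' @param n_genes total genes.
#' @param markers_per_class planted class-exclusive markers per class.
#' @param effect_size mean log-shift of a marker within its class.
#' @param baseline_mean negative-binomial baseline mean.
#' @param dispersion negative-binomial dispersion (variance =
#'   mean + dispersion * mean^2).
#' @param dropout_rate zero-inflation probability in `[0, 1)`.
#' @param seed integer seed; identical seeds give identical datasets.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_classes = 6L, class_sizes = NULL,
                         size_range = c(50L, 1000L), n_genes = 500L,
                         markers_per_class = 5L, effect_size = 2.0,
                         baseline_mean = 1.0, dispersion = 0.5,
                         dropout_rate = 0.3, seed = 0L) {
  cfg <- list(n_classes = as.integer(n_classes), class_sizes = class_sizes,
              size_range = as.integer(size_range),
              n_genes = as.integer(n_genes),
              markers_per_class = as.integer(markers_per_class),
              effect_size = effect_size, baseline_mean = baseline_mean,
              dispersion = dispersion, dropout_rate = dropout_rate,
              seed = as.integer(seed))
  if (cfg$n_classes < 2) stop("need at least 2 classes")
  if (cfg$markers_per_class * cfg$n_classes > cfg$n_genes) {
    stop("markers_per_class * n_classes exceeds n_genes: infeasible")
  }
  if (!is.null(class_sizes)) {
    cfg$class_sizes <- as.integer(class_sizes)
    if (length(cfg$class_sizes) != cfg$n_classes) {
      stop("class_sizes must have one entry per class")
    }
    if (any(cfg$class_sizes < 2)) {
      stop("every class needs >= 2 cells (oversampling and ",
           "cross-validation require neighbours)")
    }
  }
  if (cfg$dropout_rate < 0 || cfg$dropout_rate >= 1) {
    stop("dropout_rate must be in [0, 1)")
  }
  if (cfg$baseline_mean <= 0 || cfg$dispersion <= 0) {
    stop("baseline_mean and dispersion must be positive")
  }
  if (cfg$effect_size < 0) stop("effect_size must be non-negative")
  structure(cfg, class = "synth_config")
}

#' Simulate labelled expression profiles with planted markers
#'
#' Generates a cells x genes matrix, a label factor, and the ground truth
#' of which genes were planted as markers of which class. Markers are
#' class-exclusive (disjoint across classes), so recovery metrics are
#' unambiguous; all remaining genes are uninformative noise.
#'
#' @param config a [synth_config()].
#' @return list with elements `matrix` (expression matrix, cells x genes),
#'   `labels` (named factor), and `truth` (list with `marker_map`: class ->
#'   character vector of marker gene ids, and `noise_genes`).
#' @export
simulate_profiles <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  with_stream(config$seed, "simulate", {
    sizes <- config$class_sizes
    if (is.null(sizes)) {
      lo <- log(config$size_range[1]); hi <- log(config$size_range[2])
      sizes <- as.integer(round(exp(runif(config$n_classes, lo, hi))))
      sizes <- pmax(sizes, 2L)
    }
    classes <- sprintf("type%02d", seq_len(config$n_classes))
    gene_ids <- sprintf("gene%04d", seq_len(config$n_genes))
    n_cells <- sum(sizes)
    cell_ids <- sprintf("cell%06d", seq_len(n_cells))
    labels <- label_vector(rep(classes, times = sizes), cell_ids)

    n_mark <- config$markers_per_class * config$n_classes
    marker_map <- split(gene_ids[seq_len(n_mark)],
                        rep(classes, each = config$markers_per_class))
    marker_map <- marker_map[classes]
    noise_genes <- gene_ids[-seq_len(n_mark)]
    if (n_mark == 0) noise_genes <- gene_ids

    size_nb <- 1 / config$dispersion
    mu <- matrix(config$baseline_mean, nrow = n_cells,
                 ncol = config$n_genes)
    for (cl in classes) {
      rows <- which(labels == cl)
      cols <- match(marker_map[[cl]], gene_ids)
      if (length(cols) > 0) {
        mu[rows, cols] <- config$baseline_mean * exp(config$effect_size)
      }
    }
    values <- matrix(
      rnbinom(n_cells * config$n_genes, mu = as.vector(mu), size = size_nb),
      nrow = n_cells, ncol = config$n_genes)
    if (config$dropout_rate > 0) {
      drop <- runif(length(values)) < config$dropout_rate
      values[drop] <- 0
    }
    mat <- expression_matrix(values, gene_ids = gene_ids,
                             cell_ids = cell_ids)
    list(matrix = mat, labels = labels,
         truth = list(marker_map = marker_map, noise_genes = noise_genes))
  })
}

#' Class-imbalance ratio of a set of class sizes
#'
#' @param class_sizes positive numeric vector of per-class sample counts.
#' @return `max(class_sizes) / min(class_sizes)`.
#' @examples
#' imbalance_profile(c(35000, 111))  # atlas-scale imbalance
#' @export
imbalance_profile <- function(class_sizes) {
  if (length(class_sizes) == 0 || any(class_sizes <= 0)) {
    stop("class sizes must be a non-empty positive vector")
  }
  max(class_sizes) / min(class_sizes)
}
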