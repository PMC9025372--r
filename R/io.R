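#' Assemble and validate an expression matrix
#'
#' The pipeline's universal input is a plain numeric matrix of non-negative
#' expression values with cells as rows and genes as columns, carrying cell
#' identifiers as rownames and gene identifiers as colnames. Values are used
#' exactly as provided — counts, normalised, or log values are all accepted
#' as opaque non-negative reals; no normalisation is applied anywhere in the
#' pipeline.
#'
#' @param values numeric matrix, cells x genes.
#' @param gene_ids,cell_ids optional character vectors overriding the
#'   dimnames of `values`.
#' @return the validated matrix (cells x genes) with dimnames set.
#' @export
expression_matrix <- function(values, gene_ids = colnames(values),
                              cell_ids = rownames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids) || is.null(cell_ids)) {
    stop("expression matrix needs both gene and cell identifiers")
  }
  if (length(cell_ids) != nrow(values) || length(gene_ids) != ncol(values)) {
    stop("identifier lengths (", length(cell_ids), " cells, ",
         length(gene_ids), " genes) do not match matrix shape ",
         nrow(values), " x ", ncol(values))
  }
  if (anyDuplicated(gene_ids)) stop("duplicate gene identifiers")
  if (anyDuplicated(cell_ids)) stop("duplicate cell identifiers")
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    stop("negative expression value ", values[neg[1, 1], neg[1, 2]],
         " at cell '", cell_ids[neg[1, 1]], "', gene '",
         gene_ids[neg[1, 2]], "'")
  }
  dimnames(values) <- list(cell_ids, gene_ids)
  values
}

#' Read an expression matrix from disk
#'
#' Two on-disk layouts are supported:
#' * `tsv` — dense tab-separated text, first column `cell_id`, remaining
#'   columns one gene each (header row carries gene identifiers).
#' * `mtx` — MatrixMarket triplet file with co-located `genes.tsv` and
#'   `barcodes.tsv` sidecars (one identifier per line; `genes.tsv` may have
#'   extra columns, the first is used). Both orientations found in the wild
#'   (cells x genes and genes x cells) are auto-detected from the sidecar
#'   lengths; genes x cells input is transposed to the internal
#'   cells x genes form.
#'
#' @param path file path (`.tsv` or `.mtx`).
#' @param format `"auto"` (from the extension), `"tsv"` or `"mtx"`.
#' @return validated expression matrix (see [expression_matrix()]).
#' @export
read_expression <- function(path, format = c("auto", "tsv", "mtx")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path)) "mtx" else "tsv"
  }
  if (!file.exists(path)) stop("expression file not found: ", path)
  if (format == "tsv") {
    df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                     colClasses = "character", quote = "", comment.char = "")
    if (ncol(df) < 2) stop("dense TSV '", path, "' has no gene columns")
    cell_ids <- df[[1]]
    genes <- colnames(df)[-1]
    vals <- as.matrix(df[, -1, drop = FALSE])
    suppressWarnings(storage.mode(vals) <- "double")
    if (anyNA(vals)) {
      bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
      stop("non-numeric value in '", path, "' at cell '",
           cell_ids[bad[1]], "', gene '", genes[bad[2]], "'")
    }
    expression_matrix(vals, gene_ids = genes, cell_ids = cell_ids)
  } else {
    dir <- dirname(path)
    genes_file <- file.path(dir, "genes.tsv")
    cells_file <- file.path(dir, "barcodes.tsv")
    if (!file.exists(genes_file)) {
      stop("missing sidecar gene identifier file: ", genes_file)
    }
    if (!file.exists(cells_file)) {
      stop("missing sidecar cell identifier file: ", cells_file)
    }
    genes <- read.table(genes_file, sep = "\t", header = FALSE,
                        colClasses = "character", quote = "")[[1]]
    cells <- read.table(cells_file, sep = "\t", header = FALSE,
                        colClasses = "character", quote = "")[[1]]
    m <- as.matrix(Matrix::readMM(path))
    if (nrow(m) == length(cells) && ncol(m) == length(genes) &&
        length(cells) != length(genes)) {
      # stored cells x genes
    } else if (nrow(m) == length(genes) && ncol(m) == length(cells)) {
      m <- t(m)  # stored genes x cells (the common convention)
    } else if (nrow(m) == length(cells) && ncol(m) == length(genes)) {
      # square and consistent either way: keep as cells x genes
    } else {
      stop("MatrixMarket shape ", nrow(m), " x ", ncol(m),
           " matches neither sidecar (", length(cells), " barcodes, ",
           length(genes), " genes) in ", dir)
    }
    expression_matrix(m, gene_ids = genes, cell_ids = cells)
  }
}

#' Write an expression matrix to disk
#'
#' Inverse of [read_expression()]; both formats round-trip losslessly.
#'
#' @param x expression matrix (cells x genes with dimnames).
#' @param path output path (for `mtx`, sidecar `genes.tsv`/`barcodes.tsv`
#'   are written next to it).
#' @param format `"tsv"` or `"mtx"`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  x <- expression_matrix(x)
  if (format == "tsv") {
    con <- file(path, open = "wt")
    on.exit(close(con))
    writeLines(paste(c("cell_id", colnames(x)), collapse = "\t"), con)
    body <- vapply(seq_len(nrow(x)), function(i) {
      paste(c(rownames(x)[i], sprintf("%.17g", x[i, ])), collapse = "\t")
    }, character(1))
    writeLines(body, con)
  } else {
    dir <- dirname(path)
    Matrix::writeMM(Matrix::Matrix(unname(x), sparse = TRUE), path)
    writeLines(colnames(x), file.path(dir, "genes.tsv"))
    writeLines(rownames(x), file.path(dir, "barcodes.tsv"))
  }
  invisible(path)
}

#' Read per-cell class labels
#'
#' Reads a two-column tab-separated file (`cell_id`, `label`; a header line
#' is detected and skipped when its first field is `cell_id`). When
#' `cell_ids` is supplied the labels are re-ordered to that ordering and
#' every cell must be present.
#'
#' @param path label file path.
#' @param cell_ids optional character vector fixing the output order
#'   (typically `rownames` of the expression matrix).
#' @return a factor of labels, names = cell ids, levels sorted
#'   lexicographically (C locale).
#' @export
read_labels <- function(path, cell_ids = NULL) {
  if (!file.exists(path)) stop("label file not found: ", path)
  df <- read.table(path, header = FALSE, sep = "\t",
                   colClasses = "character", quote = "", comment.char = "")
  if (ncol(df) != 2) stop("label file '", path, "' must have two columns")
  if (nrow(df) > 0 && df[1, 1] == "cell_id") df <- df[-1, , drop = FALSE]
  ids <- df[[1]]
  labs <- df[[2]]
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    conflicting <- vapply(dup, function(d) {
      length(unique(labs[ids == d])) > 1
    }, logical(1))
    if (any(conflicting)) {
      stop("conflicting labels for cell id(s): ",
           paste(dup[conflicting], collapse = ", "))
    }
    keep <- !duplicated(ids)
    ids <- ids[keep]
    labs <- labs[keep]
  }
  if (!is.null(cell_ids)) {
    missing <- setdiff(cell_ids, ids)
    if (length(missing) > 0) {
      stop("cells missing from label file: ",
           paste(head(missing, 10), collapse = ", "),
           if (length(missing) > 10) sprintf(" (and %d more)",
                                             length(missing) - 10) else "")
    }
    labs <- labs[match(cell_ids, ids)]
    ids <- cell_ids
  }
  label_vector(labs, ids)
}

#' Build a validated label vector
#'
#' @param labels character/factor of class labels.
#' @param cell_ids cell identifiers, same length.
#' @return named factor; levels sorted lexicographically (C locale).
#' @export
label_vector <- function(labels, cell_ids = names(labels)) {
  labels <- as.character(labels)
  if (is.null(cell_ids)) stop("labels need cell identifiers")
  if (length(labels) != length(cell_ids)) {
    stop("labels and cell identifiers differ in length")
  }
  classes <- sort(unique(labels), method = "radix")
  if (length(classes) < 2) stop("at least 2 distinct classes are required")
  setNames(factor(labels, levels = classes), cell_ids)
}

#' Write per-cell labels
#' @param labels named factor (names = cell ids).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("cell_id\tlabel", con)
  writeLines(paste(names(labels), as.character(labels), sep = "\t"), con)
  invisible(path)
}

#' Write a ranked feature list
#'
#' Three columns: `rank`, `gene`, `RI` (relative importance, full
#' precision). Round-trips exactly through [read_ranked_features()].
#'
#' @param ranked data.frame with columns `gene`, `ri` in decreasing `ri`
#'   order (as produced by [run_mcfs()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ranked_features <- function(ranked, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("rank\tgene\tRI", con)
  if (nrow(ranked) > 0) {
    writeLines(paste(seq_len(nrow(ranked)), ranked$gene,
                     sprintf("%.17g", ranked$ri), sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_ranked_features
#' @export
read_ranked_features <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = c("integer", "character", "numeric"))
  data.frame(gene = df$gene, ri = df$RI, stringsAsFactors = FALSE)
}

#' Write an incremental-feature-selection curve
#'
#' One row per evaluated feature-subset size: `n_features`, `MCC`, `ACC`
#' and one per-class accuracy column per class. The selected sizes are kept
#' in `# optimal_k` / `# efficient_k` comment headers so the curve
#' round-trips through [read_ifs_curve()].
#'
#' @param curve an `ifs_curve` object from [run_ifs()], or a plain
#'   data.frame of records.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ifs_curve <- function(curve, path) {
  records <- if (inherits(curve, "ifs_curve")) curve$records else curve
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (inherits(curve, "ifs_curve")) {
    writeLines(sprintf("# optimal_k=%d", curve$optimal_k), con)
    writeLines(sprintf("# efficient_k=%d", curve$efficient_k), con)
  }
  cls <- setdiff(colnames(records), c("n_features", "mcc", "acc"))
  writeLines(paste(c("n_features", "MCC", "ACC", cls), collapse = "\t"), con)
  for (i in seq_len(nrow(records))) {
    writeLines(paste(c(sprintf("%d", records$n_features[i]),
                       sprintf("%.17g", unlist(records[i, c("mcc", "acc")])),
                       sprintf("%.17g", unlist(records[i, cls]))),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_ifs_curve
#' @export
read_ifs_curve <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  df <- read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                   sep = "\t", check.names = FALSE)
  names(df)[names(df) == "MCC"] <- "mcc"
  names(df)[names(df) == "ACC"] <- "acc"
  opt <- sub(".*optimal_k=", "", grep("optimal_k", meta, value = TRUE))
  eff <- sub(".*efficient_k=", "", grep("efficient_k", meta, value = TRUE))
  if (length(opt) == 1 && length(eff) == 1) {
    structure(list(records = df, optimal_k = as.integer(opt),
                   efficient_k = as.integer(eff)),
              class = "ifs_curve")
  } else {
    df
  }
}

#' Write a rule set
#'
#' `rules.json` stores the full-precision machine-readable rules;
#' `rules.txt` is a human-readable IF-THEN rendering (one rule per line,
#' thresholds rounded to 4 significant digits for display only).
#'
#' @param rules a `rule_set` from [extract_rules()].
#' @param json_path,txt_path output paths (`txt_path = NULL` skips the text
#'   rendering).
#' @return `json_path`, invisibly.
#' @export
write_rules <- function(rules, json_path, txt_path = NULL) {
  payload <- list(
    n_extracted = rules$n_extracted,
    rules = lapply(rules$rules, function(r) {
      list(
        conditions = lapply(seq_len(nrow(r$conditions)), function(i) {
          list(gene = r$conditions$gene[i], op = r$conditions$op[i],
               threshold = r$conditions$threshold[i])
        }),
        class = r$class,
        support = r$support,
        confidence = r$confidence
      )
    })
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
  writeLines(json, json_path)
  if (!is.null(txt_path)) {
    writeLines(format_rules(rules), txt_path)
  }
  invisible(json_path)
}

#' @rdname write_rules
#' @param path path of a `rules.json` file.
#' @export
read_rules <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  rules <- lapply(payload$rules, function(r) {
    conds <- if (length(r$conditions) == 0) {
      data.frame(gene = character(0), op = character(0),
                 threshold = numeric(0), stringsAsFactors = FALSE)
    } else {
      data.frame(
        gene = vapply(r$conditions, `[[`, character(1), "gene"),
        op = vapply(r$conditions, `[[`, character(1), "op"),
        threshold = vapply(r$conditions, `[[`, numeric(1), "threshold"),
        stringsAsFactors = FALSE
      )
    }
    list(conditions = conds, class = r$class,
         support = as.integer(r$support), confidence = r$confidence)
  })
  structure(list(rules = rules, n_extracted = as.integer(payload$n_extracted)),
            class = "rule_set")
}

#' Render rules as IF-THEN text
#' @param rules a `rule_set`.
#' @return character vector, one line per rule.
#' @export
format_rules <- function(rules) {
  vapply(seq_along(rules$rules), function(i) {
    r <- rules$rules[[i]]
    cond <- if (nrow(r$conditions) == 0) {
      "TRUE"
    } else {
      paste(sprintf("%s %s %.4g", r$conditions$gene, r$conditions$op,
                    r$conditions$threshold), collapse = " AND ")
    }
    sprintf("[%d] IF %s THEN class = %s (support=%d, confidence=%.4g)",
            i, cond, r$class, r$support, r$confidence)
  }, character(1))
}

#' Write the pipeline's result artifacts
#'
#' Writes `ranked_features.tsv`, `ifs_curve.tsv`, `rules.json` and
#' `rules.txt` into `dir`. Every file round-trips losslessly through the
#' matching reader.
#'
#' @param ranked ranked feature list ([run_mcfs()]).
#' @param curve IFS curve ([run_ifs()]).
#' @param rules rule set ([extract_rules()]).
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
write_outputs <- function(ranked, curve, rules, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (file.access(dir, mode = 2) != 0) stop("directory not writable: ", dir)
  paths <- c(
    ranked = file.path(dir, "ranked_features.tsv"),
    curve = file.path(dir, "ifs_curve.tsv"),
    rules_json = file.path(dir, "rules.json"),
    rules_txt = file.path(dir, "rules.txt")
  )
  write_ranked_features(ranked, paths[["ranked"]])
  write_ifs_curve(curve, paths[["curve"]])
  write_rules(rules, paths[["rules_json"]], paths[["rules_txt"]])
  invisible(paths)
}
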