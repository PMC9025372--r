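#' Pipeline configuration
#'
#' Bundles the per-stage configurations of the whole marker-discovery
#' flow: data (loaded from disk or simulated), mutual-information
#' relevance filter, shadow-feature confirmation, Monte Carlo feature
#' ranking, incremental feature selection with both classifiers, and rule
#' extraction. Every stage parameter is surfaced here with its standard
#' default (MI threshold 0.001, IFS step 5 with a top-1000 cap, 10 folds,
#' SMOTE with 5 neighbours).
#'
#' @param seed global integer seed; each stage derives its own named
#'   random stream from it.
#' @param input `NULL` to simulate data from `synth`, or a list with
#'   paths `matrix` (TSV or MTX) and `labels` (TSV).
#' @param synth a [synth_config()] used when `input` is `NULL`.
#' @param mi_threshold,mi_alpha relevance-filter threshold and
#'   discretization width.
#' @param mi_fallback_all proceed with all genes (with a warning) if no
#'   gene passes the relevance threshold.
#' @param boruta a [boruta_config()].
#' @param keep_tentative forward Boruta-tentative genes to the ranking
#'   stage (default) or drop them.
#' @param mcfs named list of [mcfs_config()] overrides (`m`, `s`, `t`,
#'   `u`, `v`, `train_fraction`); the feature count `d` is filled in at
#'   run time.
#' @param ifs_step,ifs_max_features,ifs_folds,ifs_delta IFS sweep
#'   parameters.
#' @param rf_trees trees in the random-forest classifier.
#' @param smote_k SMOTE neighbour count.
#' @param rules_top_n cap on extracted rules.
#' @param rules_balance SMOTE-balance the final rule tree's training data.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 0L, input = NULL,
                            synth = synth_config(seed = seed),
                            mi_threshold = 0.001, mi_alpha = 1.0,
                            mi_fallback_all = FALSE,
                            boruta = boruta_config(seed = seed),
                            keep_tentative = TRUE,
                            mcfs = list(),
                            ifs_step = 5L, ifs_max_features = 1000L,
                            ifs_folds = 10L, ifs_delta = 0.02,
                            rf_trees = 100L, smote_k = 5L,
                            rules_top_n = 1000L, rules_balance = TRUE) {
  structure(list(seed = as.integer(seed), input = input, synth = synth,
                 mi_threshold = mi_threshold, mi_alpha = mi_alpha,
                 mi_fallback_all = isTRUE(mi_fallback_all),
                 boruta = boruta, keep_tentative = isTRUE(keep_tentative),
                 mcfs = mcfs, ifs_step = as.integer(ifs_step),
                 ifs_max_features = as.integer(ifs_max_features),
                 ifs_folds = as.integer(ifs_folds), ifs_delta = ifs_delta,
                 rf_trees = as.integer(rf_trees),
                 smote_k = as.integer(smote_k),
                 rules_top_n = as.integer(rules_top_n),
                 rules_balance = isTRUE(rules_balance)),
            class = "pipeline_config")
}

# Internal: stable JSON rendering of a parameter list, for the manifest.
params_json <- function(x) {
  as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                null = "null", force = TRUE))
}

file_hashes <- function(files) {
  h <- tools::md5sum(files)
  names(h) <- basename(files)
  as.list(h)
}

#' Run the whole marker-discovery pipeline
#'
#' Executes the six stages in order — data, relevance filter, shadow
#' confirmation, Monte Carlo ranking, incremental feature selection (both
#' classifiers), rule extraction — writing each stage's artifact into
#' `out_dir` together with a manifest (`run_manifest.json`) recording
#' stage parameters and content hashes. Re-running with an identical
#' configuration is a no-op for completed stages: their artifacts are
#' loaded from disk instead. A stage failure halts the run naming the
#' stage and leaves prior artifacts intact.
#'
#' Artifacts: `expression.tsv`, `labels.tsv` (+ `truth.json` when
#' simulated), `mi_scores.tsv`, `boruta_result.json`,
#' `ranked_features.tsv`, `ifs_curve.tsv` (random forest),
#' `ifs_curve_dt.tsv` (decision tree), `rules.json`, `rules.txt`.
#'
#' @param config a [pipeline_config()].
#' @param out_dir artifact directory (created if needed).
#' @return list with `dir`, `executed` (names of stages actually run),
#'   `ranked`, `curve_rf`, `curve_dt`, `rules`, `boruta`, `mi` and the
#'   input `data`.
#' @export
run_all <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  manifest_path <- file.path(out_dir, "run_manifest.json")
  manifest <- if (file.exists(manifest_path)) {
    jsonlite::fromJSON(manifest_path, simplifyVector = FALSE)
  } else {
    list(stages = list())
  }
  executed <- character(0)
  art <- new.env(parent = emptyenv())

  path_of <- function(f) file.path(out_dir, f)

  stage_current <- function(name, params, inputs, outputs) {
    entry <- manifest$stages[[name]]
    if (is.null(entry)) return(FALSE)
    if (!identical(entry$params, params)) return(FALSE)
    in_files <- path_of(inputs)
    if (!all(file.exists(in_files)) ||
        !identical(entry$inputs, file_hashes(in_files))) {
      return(FALSE)  # upstream changed: recompute
    }
    out_files <- path_of(outputs)
    if (!all(file.exists(out_files))) return(FALSE)
    got <- file_hashes(out_files)
    if (!identical(entry$outputs, got)) {
      bad <- names(got)[!vapply(names(got), function(f) {
        identical(entry$outputs[[f]], got[[f]])
      }, logical(1))]
      stop("stage '", name, "': artifact '", bad[1],
           "' does not match the recorded manifest (corrupted?)",
           call. = FALSE)
    }
    TRUE
  }

  run_stage <- function(name, params, inputs, outputs, compute, load) {
    pj <- params_json(params)
    if (stage_current(name, pj, inputs, outputs)) {
      tryCatch(load(), error = function(e) {
        stop("stage '", name, "': failed to load artifact (",
             conditionMessage(e), ")", call. = FALSE)
      })
    } else {
      tryCatch(compute(), error = function(e) {
        stop("stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE)
      })
      manifest$stages[[name]] <<- list(
        params = pj,
        inputs = file_hashes(path_of(inputs)),
        outputs = file_hashes(path_of(outputs)))
      writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE,
                                  pretty = TRUE), manifest_path)
      executed <<- c(executed, name)
    }
  }

  ## stage 1: data ---------------------------------------------------------
  data_outputs <- c("expression.tsv", "labels.tsv")
  if (is.null(config$input)) data_outputs <- c(data_outputs, "truth.json")
  run_stage(
    "data",
    params = list(input = config$input,
                  synth = if (is.null(config$input)) {
                    unclass(config$synth)
                  } else NULL),
    inputs = character(0), outputs = data_outputs,
    compute = function() {
      if (is.null(config$input)) {
        sim <- simulate_profiles(config$synth)
        art$data <- sim[c("matrix", "labels")]
        art$truth <- sim$truth
        writeLines(jsonlite::toJSON(sim$truth, auto_unbox = FALSE,
                                    pretty = TRUE), path_of("truth.json"))
      } else {
        mat <- read_expression(config$input$matrix)
        labels <- read_labels(config$input$labels,
                              cell_ids = rownames(mat))
        art$data <- list(matrix = mat, labels = labels)
      }
      write_expression(art$data$matrix, path_of("expression.tsv"))
      write_labels(art$data$labels, path_of("labels.tsv"))
    },
    load = function() {
      mat <- read_expression(path_of("expression.tsv"))
      art$data <- list(matrix = mat,
                       labels = read_labels(path_of("labels.tsv"),
                                            cell_ids = rownames(mat)))
      if (file.exists(path_of("truth.json"))) {
        tr <- jsonlite::fromJSON(path_of("truth.json"),
                                 simplifyVector = TRUE)
        art$truth <- list(marker_map = as.list(tr$marker_map),
                          noise_genes = tr$noise_genes)
      }
    })

  ## stage 2: relevance filter --------------------------------------------
  run_stage(
    "relevance_filter",
    params = list(threshold = config$mi_threshold, alpha = config$mi_alpha,
                  fallback_all = config$mi_fallback_all),
    inputs = c("expression.tsv", "labels.tsv"),
    outputs = "mi_scores.tsv",
    compute = function() {
      res <- max_relevance_filter(art$data$matrix, art$data$labels,
                                  threshold = config$mi_threshold,
                                  alpha = config$mi_alpha)
      if (length(res$retained) == 0 && config$mi_fallback_all) {
        res$retained <- colnames(art$data$matrix)
      }
      art$mi <- res
      con <- file(path_of("mi_scores.tsv"), "wt")
      on.exit(close(con))
      writeLines("gene\tMI\tretained", con)
      writeLines(paste(names(res$mi_scores),
                       sprintf("%.17g", res$mi_scores),
                       as.integer(names(res$mi_scores) %in% res$retained),
                       sep = "\t"), con)
    },
    load = function() {
      df <- read.table(path_of("mi_scores.tsv"), header = TRUE, sep = "\t",
                       colClasses = c("character", "numeric", "integer"))
      art$mi <- list(mi_scores = setNames(df$MI, df$gene),
                     retained = df$gene[df$retained == 1],
                     threshold = config$mi_threshold)
    })

  ## stage 3: shadow-feature confirmation ---------------------------------
  run_stage(
    "boruta",
    params = unclass(config$boruta),
    inputs = c("expression.tsv", "labels.tsv", "mi_scores.tsv"),
    outputs = "boruta_result.json",
    compute = function() {
      sub <- art$data$matrix[, art$mi$retained, drop = FALSE]
      res <- run_boruta(sub, art$data$labels, config$boruta)
      art$boruta <- res
      writeLines(jsonlite::toJSON(
        res[c("confirmed", "rejected", "tentative", "n_iter")],
        auto_unbox = FALSE, pretty = TRUE), path_of("boruta_result.json"))
    },
    load = function() {
      res <- jsonlite::fromJSON(path_of("boruta_result.json"),
                                simplifyVector = TRUE)
      art$boruta <- list(confirmed = as.character(res$confirmed),
                         rejected = as.character(res$rejected),
                         tentative = as.character(res$tentative),
                         n_iter = res$n_iter)
    })

  ## stage 4: Monte Carlo ranking ------------------------------------------
  survivors_of <- function() {
    keep <- art$boruta$confirmed
    if (config$keep_tentative) keep <- c(keep, art$boruta$tentative)
    # original gene order for reproducible tie-breaks
    intersect(colnames(art$data$matrix), keep)
  }
  run_stage(
    "mcfs",
    params = c(config$mcfs, list(keep_tentative = config$keep_tentative,
                                 seed = config$seed)),
    inputs = c("expression.tsv", "labels.tsv", "boruta_result.json"),
    outputs = "ranked_features.tsv",
    compute = function() {
      survivors <- survivors_of()
      if (length(survivors) == 0) stop("no features survived confirmation")
      sub <- art$data$matrix[, survivors, drop = FALSE]
      cfg <- do.call(mcfs_config,
                     c(list(d = length(survivors), seed = config$seed),
                       config$mcfs))
      art$ranked <- run_mcfs(sub, art$data$labels, cfg)
      write_ranked_features(art$ranked, path_of("ranked_features.tsv"))
    },
    load = function() {
      art$ranked <- read_ranked_features(path_of("ranked_features.tsv"))
    })

  ## stage 5: incremental feature selection --------------------------------
  ifs_cfg <- function(kind) {
    ifs_config(step = config$ifs_step,
               max_features = config$ifs_max_features,
               n_folds = config$ifs_folds, delta = config$ifs_delta,
               classifier = classifier_spec(kind, n_trees = config$rf_trees,
                                            seed = config$seed),
               smote = smote_config(config$smote_k, seed = config$seed),
               seed = config$seed)
  }
  run_stage(
    "ifs",
    params = list(step = config$ifs_step,
                  max_features = config$ifs_max_features,
                  folds = config$ifs_folds, delta = config$ifs_delta,
                  rf_trees = config$rf_trees, smote_k = config$smote_k,
                  seed = config$seed),
    inputs = c("expression.tsv", "labels.tsv", "ranked_features.tsv"),
    outputs = c("ifs_curve.tsv", "ifs_curve_dt.tsv"),
    compute = function() {
      art$curve_rf <- run_ifs(art$data$matrix, art$data$labels,
                              art$ranked, ifs_cfg("random_forest"))
      art$curve_dt <- run_ifs(art$data$matrix, art$data$labels,
                              art$ranked, ifs_cfg("decision_tree"))
      write_ifs_curve(art$curve_rf, path_of("ifs_curve.tsv"))
      write_ifs_curve(art$curve_dt, path_of("ifs_curve_dt.tsv"))
    },
    load = function() {
      art$curve_rf <- read_ifs_curve(path_of("ifs_curve.tsv"))
      art$curve_dt <- read_ifs_curve(path_of("ifs_curve_dt.tsv"))
    })

  ## stage 6: rule extraction ----------------------------------------------
  run_stage(
    "rules",
    params = list(top_n = config$rules_top_n,
                  balance = config$rules_balance, smote_k = config$smote_k,
                  seed = config$seed),
    inputs = c("expression.tsv", "labels.tsv", "ranked_features.tsv",
               "ifs_curve_dt.tsv"),
    outputs = c("rules.json", "rules.txt"),
    compute = function() {
      features <- art$ranked$gene[seq_len(art$curve_dt$optimal_k)]
      tree <- fit_final_tree(art$data$matrix, art$data$labels, features,
                             balance = config$rules_balance,
                             smote = smote_config(config$smote_k),
                             seed = config$seed)
      art$rules <- extract_rules(tree, art$data$matrix, art$data$labels,
                                 top_n = config$rules_top_n)
      art$final_tree <- tree
      write_rules(art$rules, path_of("rules.json"), path_of("rules.txt"))
    },
    load = function() {
      art$rules <- read_rules(path_of("rules.json"))
    })

  list(dir = out_dir, executed = executed, data = art$data,
       truth = if (exists("truth", envir = art)) art$truth else NULL,
       mi = art$mi, boruta = art$boruta, ranked = art$ranked,
       curve_rf = art$curve_rf, curve_dt = art$curve_dt,
       rules = art$rules,
       final_tree = if (exists("final_tree", envir = art)) {
         art$final_tree
       } else NULL)
}
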