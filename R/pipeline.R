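#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis. The threshold defaults
#' are the printed values of the study design: single-cell signature
#' extraction at |log2FC| > 0.25, bulk DEGs at |log2FC| > 1, adjusted
#' p < 0.05 everywhere, pseudotime correlation r > 0.6, 19 scoring
#' algorithms, and a 7:3 train/test split of cohort 1 with cohort 2 held
#' out for validation.
#'
#' @param lfc_sc Single-cell log2 fold-change threshold (default 0.25).
#' @param lfc_bulk Bulk log2 fold-change threshold (default 1.0).
#' @param alpha Adjusted-p threshold used throughout (default 0.05).
#' @param r_thresh Pseudotime Pearson-correlation threshold (default 0.6).
#' @param k_scorers Registry size (default 19; gives 2k = 38 binary
#'   sub-scores per cell).
#' @param split_ratio Train fraction of cohort 1 (default 0.7).
#' @param center_cohorts Center each bulk cohort's features before model
#'   fitting (removes the constant batch offset; default TRUE).
#' @param seed Global seed for simulation, splitting, and model fitting.
#' @param sc_params,bulk_params Simulator parameter objects; defaults are
#'   [sc_sim_params()] and [bulk_sim_params()] reseeded from `seed`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(lfc_sc = 0.25, lfc_bulk = 1.0, alpha = 0.05,
                       r_thresh = 0.6, k_scorers = 19, split_ratio = 0.7,
                       center_cohorts = TRUE, seed = 1L,
                       sc_params = NULL, bulk_params = NULL) {
  for (v in c(lfc_sc, lfc_bulk, alpha, r_thresh))
    if (!is.finite(v) || v <= 0)
      stop("thresholds must be positive", call. = FALSE)
  if (split_ratio <= 0 || split_ratio >= 1)
    stop("'split_ratio' must be in (0, 1)", call. = FALSE)
  seed <- as.integer(seed)
  if (is.null(sc_params)) sc_params <- sc_sim_params(seed = seed)
  if (is.null(bulk_params)) bulk_params <- bulk_sim_params(seed = seed)
  structure(list(lfc_sc = lfc_sc, lfc_bulk = lfc_bulk, alpha = alpha,
                 r_thresh = r_thresh, k_scorers = as.integer(k_scorers),
                 split_ratio = split_ratio,
                 center_cohorts = isTRUE(center_cohorts), seed = seed,
                 sc_params = sc_params, bulk_params = bulk_params),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys are [run_config()] arguments; `sc_params` and
#' `bulk_params` sub-maps are passed to the simulator constructors.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("missing config file: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  seed <- if (!is.null(y$seed)) as.integer(y$seed) else 1L
  sc <- if (!is.null(y$sc_params))
    do.call(sc_sim_params, utils::modifyList(list(seed = seed),
                                             y$sc_params))
  else NULL
  bulk <- if (!is.null(y$bulk_params))
    do.call(bulk_sim_params, utils::modifyList(list(seed = seed),
                                               y$bulk_params))
  else NULL
  args <- y[setdiff(names(y), c("sc_params", "bulk_params"))]
  do.call(run_config, c(args, list(sc_params = sc, bulk_params = bulk)))
}

pipeline_stages <- function() c("simulate", "de", "score", "classify",
                                "pseudotime", "select", "ml", "report")

require_artifact <- function(dir, file, stage) {
  p <- file.path(dir, file)
  if (!file.exists(p))
    stop("missing artifact '", file, "': run stage '", stage, "' first",
         call. = FALSE)
  p
}

pipeline_datasets <- function() c("human", "mouse")

log_stage <- function(...) message("[cccf] ", sprintf(...))

stage_simulate <- function(dir, config) {
  sc_h <- simulate_sc(config$sc_params)
  mouse_params <- config$sc_params
  mouse_params$seed <- config$sc_params$seed + 1000L   # replicate dataset
  sc_m <- simulate_sc(mouse_params)
  # Bulk features live in the single-cell gene id space; the informative
  # genes are planted inside the trajectory gene set so the intersection
  # step has support.
  mono <- sc_h$truth$monotone_pseudotime_genes
  n_feat <- config$bulk_params$n_features
  other <- setdiff(sc_h$cells$genes, mono)
  feature_ids <- c(mono, other)[seq_len(n_feat)]
  bulk <- simulate_bulk(config$bulk_params, feature_ids = feature_ids,
                        informative_pool = sc_h$truth$monotone_up_genes)
  write_sc_dataset(sc_h$cells, file.path(dir, "sc_human"))
  write_sc_dataset(sc_m$cells, file.path(dir, "sc_mouse"))
  write_bulk_dataset(bulk, file.path(dir, "bulk.csv"))
  keep_truth <- c("sig_up_genes", "sig_down_genes",
                  "monotone_pseudotime_genes", "monotone_up_genes",
                  "monotone_down_genes", "high_risk_cell_ids")
  truth <- list(human = sc_h$truth[keep_truth],
                mouse = sc_m$truth[keep_truth],
                bulk = list(informative_genes =
                              bulk$truth$informative_genes))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log_stage("simulate: %d + %d cells x %d genes; bulk 2 x %d samples x %d features",
            nrow(sc_h$cells$x), nrow(sc_m$cells$x), ncol(sc_h$cells$x),
            config$bulk_params$n_samples_per_cohort, n_feat)
  invisible(NULL)
}

load_sc <- function(dir, ds) {
  read_mtx(require_artifact(dir, file.path(paste0("sc_", ds), "matrix.mtx"),
                            "simulate") |> dirname())
}

stage_de <- function(dir, config) {
  for (ds in pipeline_datasets()) {
    cm <- normalize_cells(load_sc(dir, ds))
    de <- rank_sum_de(cm, cm$cells$condition, case = "MB")
    utils::write.csv(de, file.path(dir, paste0("de_", ds, ".csv")),
                     row.names = FALSE)
    sig <- extract_signatures(de, lfc_thresh = config$lfc_sc,
                              alpha = config$alpha)
    jsonlite::write_json(unclass(sig),
                         file.path(dir, paste0("signatures_", ds, ".json")),
                         pretty = TRUE)
    log_stage("de [%s]: %d genes tested at |log2FC| > %g, adj. p < %g -> signature1 %d, signature2 %d",
              ds, nrow(de), config$lfc_sc, config$alpha,
              length(sig$signature1), length(sig$signature2))
  }
  invisible(NULL)
}

stage_score <- function(dir, config) {
  registry <- build_registry(config$k_scorers)
  for (ds in pipeline_datasets()) {
    sig <- jsonlite::read_json(
      require_artifact(dir, paste0("signatures_", ds, ".json"), "de"),
      simplifyVector = TRUE)
    cm <- normalize_cells(load_sc(dir, ds))
    tensor <- score_all(cm, sig, registry)
    for (s in 1:2) {
      df <- data.frame(cell = tensor$cells,
                       tensor$values[, , s, drop = TRUE],
                       check.names = FALSE, stringsAsFactors = FALSE)
      utils::write.csv(df,
                       file.path(dir, sprintf("scores_%s_sig%d.csv", ds, s)),
                       row.names = FALSE)
    }
    log_stage("score [%s]: %d cells x %d scorers x 2 signatures (%d scores per cell)",
              ds, length(tensor$cells), config$k_scorers,
              2L * config$k_scorers)
  }
  invisible(NULL)
}

read_score_tensor <- function(dir, ds) {
  dfs <- lapply(1:2, function(s)
    utils::read.csv(require_artifact(dir,
                                     sprintf("scores_%s_sig%d.csv", ds, s),
                                     "score"),
                    stringsAsFactors = FALSE, check.names = FALSE))
  scorers <- setdiff(names(dfs[[1]]), "cell")
  values <- array(NA_real_,
                  dim = c(nrow(dfs[[1]]), length(scorers), 2),
                  dimnames = list(dfs[[1]]$cell, scorers,
                                  c("signature1", "signature2")))
  for (s in 1:2)
    values[, , s] <- as.matrix(dfs[[s]][, scorers, drop = FALSE])
  structure(list(cells = dfs[[1]]$cell, scorers = scorers, values = values),
            class = "score_tensor")
}

stage_classify <- function(dir, config) {
  for (ds in pipeline_datasets()) {
    tensor <- read_score_tensor(dir, ds)
    res <- classify_cells(tensor)
    utils::write.csv(res, file.path(dir, paste0("consensus_", ds, ".csv")),
                     row.names = FALSE)
    cm <- load_sc(dir, ds)
    prop <- risk_proportions(res, cm$cells$condition)
    utils::write.csv(prop,
                     file.path(dir, paste0("proportions_", ds, ".csv")),
                     row.names = FALSE)
    log_stage("classify [%s]: high %d, low %d, filtered %d of %d cells",
              ds, sum(res$label == "high"), sum(res$label == "low"),
              sum(res$label == "filtered"), nrow(res))
  }
  invisible(NULL)
}

stage_pseudotime <- function(dir, config) {
  for (ds in pipeline_datasets()) {
    cons <- utils::read.csv(
      require_artifact(dir, paste0("consensus_", ds, ".csv"), "classify"),
      stringsAsFactors = FALSE)
    class(cons) <- c("consensus_result", "data.frame")
    cm <- normalize_cells(load_sc(dir, ds))
    pt <- pseudotime(cm, cons)
    utils::write.csv(pt, file.path(dir, paste0("pseudotime_", ds, ".csv")),
                     row.names = FALSE)
    corr <- correlate_pseudotime(cm, pt)
    utils::write.csv(corr,
                     file.path(dir, paste0("correlations_", ds, ".csv")),
                     row.names = FALSE)
    log_stage("pseudotime [%s]: %d genes correlated against the axis", ds,
              sum(!is.na(corr$r)))
  }
  invisible(NULL)
}

stage_select <- function(dir, config) {
  corr <- lapply(pipeline_datasets(), function(ds)
    utils::read.csv(require_artifact(dir,
                                     paste0("correlations_", ds, ".csv"),
                                     "pseudotime"),
                    stringsAsFactors = FALSE))
  bulk <- read_bulk_dataset(require_artifact(dir, "bulk.csv", "simulate"))
  # Per-cohort location alignment: shift cohort 2 so its grand mean matches
  # cohort 1, removing the constant batch offset before ratio-based DE.
  bulk$cohort2$x <- bulk$cohort2$x -
    (mean(bulk$cohort2$x) - mean(bulk$cohort1$x))
  degs <- lapply(bulk, function(co)
    bulk_de(co$x, co$labels, lfc_thresh = config$lfc_bulk,
            alpha = config$alpha))
  feats <- select_features(corr[[1]], corr[[2]], degs$cohort1, degs$cohort2,
                           r_thresh = config$r_thresh, alpha = config$alpha)
  jsonlite::write_json(list(degs_cohort1 = degs$cohort1,
                            degs_cohort2 = degs$cohort2,
                            features = feats),
                       file.path(dir, "features.json"), pretty = TRUE)
  log_stage("select: DEGs %d/%d per cohort; %d features pass r > %g in both datasets",
            length(degs$cohort1), length(degs$cohort2), length(feats),
            config$r_thresh)
  invisible(NULL)
}

center_features <- function(x) sweep(x, 2, colMeans(x))

stage_ml <- function(dir, config) {
  sel <- jsonlite::read_json(require_artifact(dir, "features.json",
                                              "select"),
                             simplifyVector = TRUE)
  bulk <- read_bulk_dataset(require_artifact(dir, "bulk.csv", "simulate"))
  feats <- sel$features
  x1 <- bulk$cohort1$x[, feats, drop = FALSE]
  x2 <- bulk$cohort2$x[, feats, drop = FALSE]
  if (config$center_cohorts) {
    x1 <- center_features(x1)
    x2 <- center_features(x2)
  }
  sp <- split_samples(bulk$cohort1$labels, ratio = config$split_ratio,
                      seed = config$seed)
  train <- list(x = x1[sp$train, , drop = FALSE],
                y = bulk$cohort1$labels[sp$train])
  test <- list(x = x1[sp$test, , drop = FALSE],
               y = bulk$cohort1$labels[sp$test])
  valid <- list(x = x2, y = bulk$cohort2$labels)
  specs <- enumerate_combinations()
  log_stage("ml: %d models on %d features (train %d / test %d / validation %d)",
            length(specs), length(feats), nrow(train$x), nrow(test$x),
            nrow(valid$x))
  results <- evaluate_models(specs, train, test, valid, seed = config$seed)
  ranked <- rank_models(results)
  utils::write.csv(model_summary(ranked), file.path(dir, "models.csv"),
                   row.names = FALSE)
  freq <- gene_frequency(results, genes = feats)
  utils::write.csv(data.frame(gene = names(freq), n_models = freq,
                              row.names = NULL),
                   file.path(dir, "gene_frequency.csv"), row.names = FALSE)
  best <- ranked[[1]]
  jsonlite::write_json(list(name = best$spec$name,
                            genes = best$genes_used,
                            coefficients = as.list(best$coefficients),
                            auc_train = best$auc_train,
                            auc_test = best$auc_test,
                            auc_valid = best$auc_valid,
                            mean_auc = best$mean_auc),
                       file.path(dir, "best_model.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_stage("ml: best model '%s' mean test/validation AUC %.3f with %d genes",
            best$spec$name, best$mean_auc, length(best$genes_used))
  invisible(NULL)
}

stage_report <- function(dir, config) {
  best <- jsonlite::read_json(require_artifact(dir, "best_model.json",
                                               "ml"),
                              simplifyVector = TRUE)
  prop <- utils::read.csv(require_artifact(dir, "proportions_human.csv",
                                           "classify"))
  sel <- jsonlite::read_json(require_artifact(dir, "features.json",
                                              "select"),
                             simplifyVector = TRUE)
  lines <- c(
    "cccf pipeline report",
    sprintf("registry: %d scorers -> %d binary sub-scores per cell",
            config$k_scorers, 2L * config$k_scorers),
    sprintf("high-risk fraction (human): %s",
            paste(sprintf("%s %.3f", prop$group, prop$high),
                  collapse = ", ")),
    sprintf("selected features: %d", length(sel$features)),
    sprintf("best model: %s (mean test/validation AUC %.3f, %d genes)",
            best$name, best$mean_auc, length(best$genes)))
  writeLines(lines, file.path(dir, "report.txt"))
  files <- setdiff(list.files(dir, recursive = TRUE), "manifest.json")
  manifest <- list(files = lapply(files, function(f)
    list(name = f, md5 = unname(tools::md5sum(file.path(dir, f))))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log_stage("report: %d artifacts in manifest", length(files))
  invisible(NULL)
}

#' Run one pipeline stage against a run directory
#'
#' Stages form the chain `simulate`, `de`, `score`, `classify`,
#' `pseudotime`, `select`, `ml`, `report`; each reads the artifacts of its
#' predecessors from `dir` and errors, naming the required prior stage, if
#' they are missing.
#'
#' @param stage Stage name.
#' @param dir Run directory.
#' @param config A [run_config()].
#' @return Invisibly NULL; artifacts are written into `dir`.
#' @export
run_stage <- function(stage, dir, config = run_config()) {
  stage <- match.arg(stage, pipeline_stages())
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  switch(stage,
         simulate = stage_simulate(dir, config),
         de = stage_de(dir, config),
         score = stage_score(dir, config),
         classify = stage_classify(dir, config),
         pseudotime = stage_pseudotime(dir, config),
         select = stage_select(dir, config),
         ml = stage_ml(dir, config),
         report = stage_report(dir, config))
}

#' Run the full pipeline end to end
#'
#' Executes every stage in order in `dir` (simulation through model
#' ranking and report), fully determined by the configuration seed.
#'
#' @param dir Run directory (created if missing).
#' @param config A [run_config()].
#' @return Invisibly, the parsed manifest.
#' @export
run_pipeline <- function(dir, config = run_config()) {
  for (stage in pipeline_stages()) run_stage(stage, dir, config)
  invisible(jsonlite::read_json(file.path(dir, "manifest.json"),
                                simplifyVector = TRUE))
}
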