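#' Resolved configuration for an end-to-end run
#'
#' Collects paths, stage toggles, nested module settings and the global seed.
#' Per-stage seeds are derived from the global seed by a fixed counter scheme
#' (`seed + 97 * stage_index`), so any stage can be rerun in isolation and
#' reproduce its output. The resolved configuration is persisted verbatim
#' next to the outputs.
#'
#' @param graph path to the PPI edge-list TSV.
#' @param omics character vector of omics matrix paths (each samples x nodes,
#'   header = node ids).
#' @param labels path to a two-column TSV (`sample`, `label`).
#' @param annotations optional GMT annotation file for enrichment.
#' @param out_dir output directory.
#' @param stages named logical toggles: `refine`, `train`, `explain`,
#'   `enrich`.
#' @param model a [model_config()].
#' @param score_threshold edge-score cutoff for reading the graph.
#' @param refine_count,refine_folds,prior_factor refinement settings
#'   (penalty-path length, CV folds, prior penalty discount).
#' @param shap_n_samples,shap_background,shap_n_explain explainer budget.
#' @param top_k subnetwork/enrichment cutoff, default 30.
#' @param seed global seed.
#' @param log_level `"info"` or `"quiet"`.
#' @return a `run_config` list.
#' @export
run_config <- function(graph, omics, labels, annotations = NULL,
                       out_dir = "spectromics_run",
                       stages = list(refine = TRUE, train = TRUE,
                                     explain = TRUE, enrich = TRUE),
                       model = model_config(),
                       score_threshold = 0.4,
                       refine_count = 40L, refine_folds = 4L,
                       prior_factor = 0.1,
                       shap_n_samples = 1200L, shap_background = 100L,
                       shap_n_explain = 20L, top_k = 30L, seed = 1L,
                       log_level = c("info", "quiet")) {
  def <- list(refine = TRUE, train = TRUE, explain = TRUE, enrich = TRUE)
  def[names(stages)] <- stages
  structure(list(graph = graph, omics = omics, labels = labels,
                 annotations = annotations, out_dir = out_dir, stages = def,
                 model = model, score_threshold = score_threshold,
                 refine_count = as.integer(refine_count),
                 refine_folds = as.integer(refine_folds),
                 prior_factor = prior_factor,
                 shap_n_samples = as.integer(shap_n_samples),
                 shap_background = as.integer(shap_background),
                 shap_n_explain = as.integer(shap_n_explain),
                 top_k = as.integer(top_k), seed = as.integer(seed),
                 log_level = match.arg(log_level)),
            class = "run_config")
}

stage_seed <- function(config, stage_index) config$seed + 97L * stage_index

pipeline_log <- function(config, fmt, ...) {
  if (config$log_level != "quiet")
    message(sprintf("[spectromics] %s", sprintf(fmt, ...)))
}

file_hash <- function(paths) {
  paths <- paths[!vapply(paths, is.null, logical(1))]
  unname(vapply(unlist(paths), function(p)
    as.character(tools::md5sum(p)), character(1)))
}

#' Run the end-to-end workflow: refine, train, explain, enrich
#'
#' Executes the enabled stages in order on the configured inputs:
#' (1) *refine* the prior network by prior-weighted sparse inverse-covariance
#' estimation on the first omics channel; (2) *train* the graph-convolutional
#' classifier under the test/CV protocol and score it; (3) *explain* the best
#' fold model with sampled Shapley values and extract the top-node
#' subnetwork; (4) *enrich* the top nodes against the annotation sets.
#' Each stage writes TSV outputs into `out_dir` and is recorded in a JSON
#' manifest (inputs hash, outputs, wall time). A halted run leaves the
#' manifest describing the stages that completed.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the manifest and in-memory stage results.
#' @export
run_pipeline <- function(config) {
  t_all <- Sys.time()
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  strip_class <- function(x) if (is.list(x)) lapply(x, strip_class) else x
  jsonlite::write_json(strip_class(unclass(config)),
                       file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  manifest <- list()
  add_stage <- function(name, inputs, outputs, t0) {
    manifest[[name]] <<- list(
      stage = name,
      inputs_md5 = file_hash(inputs),
      outputs = unname(unlist(outputs)),
      seconds = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 3))
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  on.exit(jsonlite::write_json(manifest,
                               file.path(config$out_dir, "manifest.json"),
                               auto_unbox = TRUE, digits = NA), add = TRUE)

  ## -- load inputs -----------------------------------------------------------
  t0 <- Sys.time()
  graph <- read_edge_list(config$graph, config$score_threshold)
  omics <- lapply(config$omics, read_omics_matrix)
  lab_df <- utils::read.table(config$labels, header = TRUE, sep = "\t")
  labels <- as.integer(lab_df[[2]])
  feats <- colnames(omics[[1]])
  nm <- map_features_to_nodes(feats, graph)
  kept <- nm$mapping$feature
  node_idx <- nm$mapping$node_index[order(nm$mapping$node_index)]
  kept <- nm$mapping$feature[order(nm$mapping$node_index)]
  graph <- induced_graph(graph, node_idx)
  omics <- lapply(omics, function(m) m[, kept, drop = FALSE])
  ch_names <- if (!is.null(names(config$omics))) names(config$omics) else
    tools::file_path_sans_ext(basename(config$omics))
  tensor <- omics_tensor(omics, labels, channel_names = ch_names,
                         node_ids = graph$node_ids)
  if (nrow(nm$dropped))
    write_drop_log(nm, file.path(config$out_dir, "dropped_features.tsv"))
  add_stage("load", config[c("graph", "omics", "labels")],
            file.path(config$out_dir, "config.json"), t0)
  pipeline_log(config, "loaded %d samples, %d nodes, %d channels",
               dim(tensor$x)[1], dim(tensor$x)[2], dim(tensor$x)[3])

  results <- list(tensor = tensor, graph = graph, node_map = nm)

  ## -- refine ----------------------------------------------------------------
  model_graph <- graph
  if (isTRUE(config$stages$refine)) {
    t0 <- Sys.time()
    ref <- refine_network(tensor$x[, , 1], graph,
                          folds = config$refine_folds,
                          prior_factor = config$prior_factor,
                          count = config$refine_count,
                          seed = stage_seed(config, 1L))
    model_graph <- ref$graph
    out1 <- file.path(config$out_dir, "refined_network.tsv")
    out2 <- file.path(config$out_dir, "lambda_selection.tsv")
    write_edge_list(ref$graph, out1)
    write_selection_report(ref$selection, out2)
    results$refine <- ref
    add_stage("refine", config["graph"], list(out1, out2), t0)
    pipeline_log(config, "refined network: lambda = %.4g, density %.4f",
                 ref$selection$chosen_lambda, graph_density(ref$graph))
  } else {
    pipeline_log(config, "refine disabled: training on the input graph")
  }
  results$model_graph <- model_graph

  ## -- train / evaluate ------------------------------------------------------
  if (isTRUE(config$stages$train)) {
    t0 <- Sys.time()
    cfg <- config$model
    cfg$seed <- stage_seed(config, 2L)
    cv <- cross_validate(tensor, model_graph, cfg)
    mt <- cv$fold_metrics
    mt <- rbind(mt, data.frame(fold = NA, accuracy = cv$mean_accuracy,
                               f1 = cv$mean_f1, TP = NA, TN = NA, FP = NA,
                               FN = NA))
    out1 <- file.path(config$out_dir, "metrics.tsv")
    utils::write.table(cbind(mt, se_accuracy = c(rep(NA, nrow(mt) - 1),
                                                 cv$se_accuracy)),
                       out1, sep = "\t", quote = FALSE, row.names = FALSE)
    out2 <- file.path(config$out_dir, "history.tsv")
    hist <- do.call(rbind, lapply(seq_along(cv$models), function(f)
      cbind(fold = f, cv$models[[f]]$history)))
    utils::write.table(hist, out2, sep = "\t", quote = FALSE, row.names = FALSE)
    results$cv <- cv
    add_stage("train", config[c("omics", "labels")], list(out1, out2), t0)
    pipeline_log(config, "test accuracy %.4f +/- %.4f over %d folds",
                 cv$mean_accuracy, cv$se_accuracy, nrow(cv$fold_metrics))
  }

  ## -- explain ---------------------------------------------------------------
  if (isTRUE(config$stages$explain) && !is.null(results$cv)) {
    t0 <- Sys.time()
    cv <- results$cv
    best_f <- which.max(cv$fold_metrics$accuracy)
    model <- cv$models[[best_f]]
    flat <- flatten_tensor(tensor)
    flat <- apply_flat_scaler(flat, model$scaler)
    tr_idx <- which(!is.na(cv$plan$fold))
    te_idx <- cv$plan$test
    explain_idx <- utils::head(te_idx, config$shap_n_explain)
    fn <- function(m) predict_proba(model, m)
    expl <- shap_explain(fn, flat[tr_idx, , drop = FALSE],
                         flat[explain_idx, , drop = FALSE],
                         n_samples = config$shap_n_samples,
                         seed = stage_seed(config, 3L),
                         max_background = config$shap_background)
    rk <- rank_features(expl)
    sub <- extract_subnetwork(rk, model_graph, top_k = config$top_k)
    outs <- write_shap_outputs(expl, rk, config$out_dir)
    out3 <- file.path(config$out_dir, "subnetwork.tsv")
    write_edge_list(weighted_graph(sub$nodes, sub$adjacency,
                                   sort_nodes = FALSE), out3)
    out4 <- file.path(config$out_dir, "local_report_sample1.tsv")
    lr <- local_report(expl, 1L)
    utils::write.table(lr$table, out4, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    results$explanation <- expl
    results$ranking <- rk
    results$subnetwork <- sub
    add_stage("explain", config[c("omics", "labels")],
              c(as.list(outs), out3, out4), t0)
    pipeline_log(config, "explained %d samples; %d-node subnetwork, %d components",
                 length(explain_idx), length(sub$nodes), length(sub$components))
  }

  ## -- enrich ----------------------------------------------------------------
  if (isTRUE(config$stages$enrich) && !is.null(config$annotations) &&
      !is.null(results$ranking)) {
    t0 <- Sys.time()
    map <- read_gmt(config$annotations, background = graph$node_ids)
    top_nodes <- results$subnetwork$selected
    et <- fisher_enrichment(top_nodes, map)
    out1 <- file.path(config$out_dir, "enrichment.tsv")
    utils::write.table(et, out1, sep = "\t", quote = FALSE, row.names = FALSE)
    results$enrichment <- et
    add_stage("enrich", config["annotations"], out1, t0)
    pipeline_log(config, "%d terms tested, %d at FDR < 0.05",
                 nrow(et), sum(et$fdr < 0.05))
  }

  pipeline_log(config, "pipeline finished in %.1f s",
               as.numeric(difftime(Sys.time(), t_all, units = "secs")))
  invisible(c(list(manifest = manifest), results))
}

apply_flat_scaler <- function(flat, scaler) {
  ctr <- as.vector(scaler$center)
  scl <- as.vector(scaler$scale)
  sweep(sweep(flat, 2, ctr), 2, scl, "/")
}

# induced subgraph on node indices, preserving their relative order
induced_graph <- function(graph, idx) {
  weighted_graph(graph$node_ids[idx],
                 graph$adjacency[idx, idx, drop = FALSE],
                 weighted = graph$weighted, sort_nodes = FALSE)
}
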