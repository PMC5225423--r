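#' Full run configuration for the discovery pipeline
#'
#' Defaults are the screening thresholds of the standard workflow:
#' p < 0.05, |log2FC| >= 0.8, FDR < 0.05 for the differential screen;
#' CE strata edges 0.6/0.7/0.8; 5-fold cross-validation; CPM clique
#' size k = 3; synergy significance alpha = 0.05.
#'
#' @param p_thr,lfc_thr,fdr_thr differential screening thresholds.
#' @param max_missing_frac missing-value screening threshold.
#' @param method differential test, `"moderated_t"` or `"welch_t"`.
#' @param ce_edges CE stratum edges (see [stratify_pairs()]).
#' @param cv `cv_config` for classifier evaluation.
#' @param n_top_features how many top differential miRNAs (by |log2fc|)
#'   to evaluate as single features and as a combined panel.
#' @param k CPM clique size.
#' @param alpha synergy significance level.
#' @param seed integer seed (cross-validation fold assignment).
#' @param out_dir optional output directory; when given, every
#'   intermediate table, SIF/GraphML exports and `summary.json` are
#'   written under it.
#' @return list of class `run_config`.
#' @export
run_config <- function(p_thr = 0.05, lfc_thr = 0.8, fdr_thr = 0.05,
                       max_missing_frac = 0.2,
                       method = c("moderated_t", "welch_t"),
                       ce_edges = c(0.6, 0.7, 0.8), cv = NULL,
                       n_top_features = 4, k = 3, alpha = 0.05,
                       seed = 1, out_dir = NULL) {
  method <- match.arg(method)
  if (is.null(cv)) cv <- cv_config(seed = seed)
  structure(list(p_thr = p_thr, lfc_thr = lfc_thr, fdr_thr = fdr_thr,
                 max_missing_frac = max_missing_frac, method = method,
                 ce_edges = ce_edges, cv = cv,
                 n_top_features = n_top_features, k = k, alpha = alpha,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Run the complete biomarker discovery pipeline
#'
#' Executes, in order: missing-value screening and imputation,
#' per-miRNA differential testing with BH FDR, threshold filtering,
#' pairwise Pearson CE over the differential miRNAs, CE stratification,
#' cross-validated RBF-SVM evaluation of feature sets (each CE stratum,
#' the top single differential miRNAs and their combined panel),
#' co-target hypergeometric synergy testing of all differential pairs,
#' network construction, CPM module detection and the global topology
#' summary.  When `config$out_dir` is set, all intermediate tables and
#' a reproducibility manifest (`summary.json`) are written there.
#'
#' @param expr `mirna_expr` with groups set.
#' @param targets `target_map` (set `NULL` to skip the synergy/network
#'   stages).
#' @param pathways named list of pathway gene sets (or `NULL`, as
#'   above).
#' @param config `run_config`.
#' @return list of class `discovery_run` with elements `results`
#'   (differential table), `demirs` (ids), `pairs`, `strata`,
#'   `auc_table`, `network`, `modules`, `topology`, `summary` (the
#'   manifest list).
#' @export
run_discovery <- function(expr, targets = NULL, pathways = NULL,
                          config = run_config()) {
  stopifnot(inherits(expr, "mirna_expr"), inherits(config, "run_config"))
  t0 <- Sys.time()
  log_lines <- character(0)
  say <- function(...) {
    msg <- paste0(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }

  run_stage <- function(stage, fn) {
    tryCatch(fn(), error = function(e)
      stop("stage '", stage, "' failed [E_", toupper(stage), "]: ",
           conditionMessage(e), call. = FALSE))
  }

  clean <- run_stage("preprocess", function()
    preprocess_expression(expr, config$max_missing_frac))
  say("preprocess: kept ", nrow(clean$values), "/", nrow(expr$values),
      " miRNAs after missing-value screening")

  results <- run_stage("differential_test", function()
    differential_test(clean, config$method))
  results <- filter_demirs(results, config$p_thr, config$lfc_thr,
                           config$fdr_thr)
  demirs <- results$mirna_id[results$passes]
  n_up <- attr(results, "n_up"); n_down <- attr(results, "n_down")
  say("differential: ", length(demirs), " DEmiRs (", n_up, " up, ",
      n_down, " down)")

  pairs <- NULL; strata <- NULL; auc_table <- NULL
  network <- NULL; modules <- NULL; topo <- NULL
  if (length(demirs) >= 2) {
    pairs <- run_stage("pairwise_ce", function()
      pairwise_ce(clean, demirs))
    strata <- stratify_pairs(pairs, config$ce_edges)
    say("correlation: ", nrow(pairs), " pairs (",
        sum(pairs$sign_class == "positive", na.rm = TRUE), " positive, ",
        sum(pairs$sign_class == "negative", na.rm = TRUE), " negative)")

    feature_sets <- list()
    for (nm in names(strata))
      if (nrow(strata[[nm]]) > 0)
        feature_sets[[paste0("stratum:", nm)]] <- pair_members(strata[[nm]])
    top <- results[results$passes, ]
    top <- top$mirna_id[order(-abs(top$log2fc))]
    top <- top[seq_len(min(config$n_top_features, length(top)))]
    for (id in top) feature_sets[[paste0("single:", id)]] <- id
    if (length(top) >= 2)
      feature_sets[["panel:top_combined"]] <- top
    auc_table <- run_stage("evaluate_feature_sets", function()
      evaluate_feature_sets(clean, feature_sets, config$cv))
    say("classifier: evaluated ", nrow(auc_table), " feature sets; best AUC ",
        sprintf("%.3f", max(auc_table$auc)))

    if (!is.null(targets) && !is.null(pathways)) {
      network <- run_stage("build_network", function()
        suppressWarnings(build_network(pairs, targets, pathways,
                                       config$alpha)))
      say("network: ", igraph::vcount(network$graph), " miRNAs, ",
          nrow(network$edges), " edges (", network$n_positive,
          " positive, ", network$n_negative, " negative)")
      if (nrow(network$edges) > 0) {
        modules <- run_stage("clique_percolation", function()
          clique_percolation(network$graph, config$k))
        say("modules: ", length(modules), " CPM modules at k=", config$k)
        topo <- run_stage("global_topology", function()
          global_topology(network$graph))
      }
    }
  } else {
    say("fewer than two DEmiRs; correlation and network stages skipped")
  }

  summary <- list(
    package_version = as.character(utils::packageVersion("miRpanel")),
    seed = config$seed,
    parameters = config[c("p_thr", "lfc_thr", "fdr_thr",
                          "max_missing_frac", "method", "ce_edges",
                          "n_top_features", "k", "alpha")],
    cv = list(n_folds = config$cv$n_folds, seed = config$cv$seed,
              kernel_width = config$cv$kernel_width,
              regularization = config$cv$regularization),
    n_mirnas_input = nrow(expr$values),
    n_mirnas_screened = nrow(clean$values),
    n_samples = ncol(expr$values),
    n_demirs = length(demirs), n_up = n_up, n_down = n_down,
    n_pairs = if (is.null(pairs)) 0L else nrow(pairs),
    n_pairs_positive = if (is.null(pairs)) 0L else
      sum(pairs$sign_class == "positive", na.rm = TRUE),
    n_pairs_negative = if (is.null(pairs)) 0L else
      sum(pairs$sign_class == "negative", na.rm = TRUE),
    auc = if (is.null(auc_table)) NULL else
      setNames(as.list(auc_table$auc), auc_table$set_name),
    network_nodes = if (is.null(network)) 0L else
      igraph::vcount(network$graph),
    network_edges = if (is.null(network)) 0L else nrow(network$edges),
    n_modules = if (is.null(modules)) 0L else length(modules),
    topology = if (is.null(topo)) NULL else as.list(topo))

  if (!is.null(config$out_dir)) {
    od <- config$out_dir
    dir.create(file.path(od, "tables"), recursive = TRUE,
               showWarnings = FALSE)
    dir.create(file.path(od, "networks"), showWarnings = FALSE)
    write_differential(results, file.path(od, "tables", "differential.tsv"))
    if (!is.null(pairs))
      write.table(pairs, file.path(od, "tables", "pairs.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    if (!is.null(auc_table))
      write.table(auc_table, file.path(od, "tables", "auc.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    if (!is.null(network) && nrow(network$edges) > 0) {
      write_edge_table(network, file.path(od, "tables", "edges.tsv"))
      write_network(network, file.path(od, "networks", "network.sif"), "sif")
      write_network(network, file.path(od, "networks", "network.graphml"),
                    "graphml")
    }
    if (!is.null(modules))
      write_modules(modules, file.path(od, "tables", "modules.tsv"))
    if (!is.null(topo))
      write_topology(topo, file.path(od, "tables", "topology.tsv"))
    jsonlite::write_json(summary, file.path(od, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(log_lines, file.path(od, "log.txt"))
  }
  say(sprintf("done in %.1f s", as.numeric(Sys.time() - t0, units = "secs")))

  structure(list(results = results, demirs = demirs, pairs = pairs,
                 strata = strata, auc_table = auc_table,
                 network = network, modules = modules, topology = topo,
                 summary = summary),
            class = "discovery_run")
}

#' @export
print.discovery_run <- function(x, ...) {
  s <- x$summary
  cat("discovery_run:\n")
  cat("  DEmiRs:", s$n_demirs, "(", s$n_up, "up,", s$n_down, "down )\n")
  cat("  pairs:", s$n_pairs, "(", s$n_pairs_positive, "positive,",
      s$n_pairs_negative, "negative )\n")
  cat("  network:", s$network_nodes, "nodes /", s$network_edges,
      "edges;", s$n_modules, "CPM modules\n")
  invisible(x)
}
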