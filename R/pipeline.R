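#' Pipeline run configuration
#'
#' Validates and freezes everything an end-to-end run needs. Either a
#' synthetic [cohort_design()] or paths to existing inputs (event tables CSV +
#' sample sheet CSV, or two feature-matrix CSVs) must be given. All paths are
#' checked up front so a misconfigured run fails before any compute.
#'
#' @param output_dir Run directory (created).
#' @param design Optional [cohort_design()] for a synthetic run.
#' @param events_csv,sheet_csv Optional event-level inputs.
#' @param features_t1_csv,features_t2_csv Optional precomputed feature
#'   matrices (with sidecars); `sheet_csv` required alongside.
#' @param panel A [panel_config()].
#' @param simulate_events For synthetic runs: draw event tables and extract
#'   features (slower, exercises the full assay path) instead of sampling the
#'   feature matrices directly.
#' @param n_test,n_iterations,n_folds,n_lambda,min_ratio Model settings.
#' @param network_threshold Edge p-value threshold.
#' @param per_timepoint_network Correlate within each time point separately
#'   (n per pair halves) instead of pooling T1 + T2 observations.
#' @param continuous_breakpoint Continuity-constrained piecewise fit.
#' @param bh_adjust Benjamini-Hochberg adjusted univariate p-values.
#' @param confounders Run confounder regressions (needs covariates).
#' @param seed Mandatory integer seed for the whole run.
#' @return A validated `run_config`.
#' @export
run_config <- function(output_dir, design = NULL, events_csv = NULL,
                       sheet_csv = NULL, features_t1_csv = NULL,
                       features_t2_csv = NULL, panel = panel_config(),
                       simulate_events = FALSE,
                       n_test = 3L, n_iterations = 100L, n_folds = 5L,
                       n_lambda = 100L, min_ratio = 0.01,
                       network_threshold = 1e-12,
                       per_timepoint_network = FALSE,
                       continuous_breakpoint = FALSE, bh_adjust = FALSE,
                       confounders = TRUE, seed = NULL) {
  if (is.null(seed))
    id_stop("a seed is mandatory in the run configuration", "immunodyn_config_error")
  have_design <- !is.null(design)
  have_events <- !is.null(events_csv)
  have_fm <- !is.null(features_t1_csv) || !is.null(features_t2_csv)
  if (!have_design && !have_events && !have_fm)
    id_stop("provide a cohort design, event tables, or feature matrices",
            "immunodyn_config_error")
  if (have_events || have_fm) {
    if (is.null(sheet_csv))
      id_stop("a sample sheet CSV is required with file inputs", "immunodyn_config_error")
    for (p in c(events_csv, sheet_csv, features_t1_csv, features_t2_csv))
      if (!file.exists(p))
        id_stop(sprintf("input path does not exist: %s", p), "immunodyn_config_error")
    if (have_fm && (is.null(features_t1_csv) || is.null(features_t2_csv)))
      id_stop("both T1 and T2 feature matrices are required", "immunodyn_config_error")
  }
  if (have_design) stopifnot(inherits(design, "cohort_design"))
  structure(list(output_dir = output_dir, design = design,
                 events_csv = events_csv, sheet_csv = sheet_csv,
                 features_t1_csv = features_t1_csv,
                 features_t2_csv = features_t2_csv, panel = panel,
                 simulate_events = isTRUE(simulate_events),
                 n_test = as.integer(n_test),
                 n_iterations = as.integer(n_iterations),
                 n_folds = as.integer(n_folds), n_lambda = as.integer(n_lambda),
                 min_ratio = min_ratio, network_threshold = network_threshold,
                 per_timepoint_network = isTRUE(per_timepoint_network),
                 continuous_breakpoint = isTRUE(continuous_breakpoint),
                 bh_adjust = isTRUE(bh_adjust), confounders = isTRUE(confounders),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Reads a YAML file whose keys mirror the [run_config()] arguments
#' (`design:` may hold [cohort_design()] arguments as a map).
#'
#' @param path YAML file.
#' @param output_dir Optional override of the configured output directory.
#' @return A `run_config`.
#' @export
run_config_from_yaml <- function(path, output_dir = NULL) {
  if (!requireNamespace("yaml", quietly = TRUE))
    id_stop("the 'yaml' package is required to read YAML configs", "immunodyn_config_error")
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$design)) {
    if (!is.null(cfg$design$planted_effects))
      cfg$design$planted_effects <- lapply(cfg$design$planted_effects,
                                           function(pe) do.call(planted_effect, pe))
    cfg$design <- do.call(cohort_design, cfg$design)
  }
  if (!is.null(output_dir)) cfg$output_dir <- output_dir
  do.call(run_config, cfg)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    id_stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
            "immunodyn_stage_error"))
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate/load -> extract -> rates -> correlation network ->
#' repeated-holdout model -> reduction -> univariate & confounder statistics,
#' writing every artifact plus a markdown report and a manifest (config hash,
#' seed, package versions) into the run directory. Any stage failure halts
#' the pipeline with a stage-named error; artifacts written so far are kept.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the main in-memory results and the run
#'   directory.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$output_dir, ...)

  acquire <- stage("acquire", {
    if (!is.null(config$design)) {
      if (config$simulate_events) {
        sim <- simulate_event_tables(config$design)
        fms <- extract_features(sim$events, design_panel(config$design),
                                sim$sheet)
        write_event_tables(sim$events, out("event_tables.csv"))
        list(t1 = fms$t1, t2 = fms$t2, sheet = sim$sheet, truth = sim$truth)
      } else {
        simulate_feature_matrix(config$design)
      }
    } else if (!is.null(config$events_csv)) {
      events <- read_event_tables(config$events_csv)
      sheet <- read_sample_sheet(config$sheet_csv)
      fms <- extract_features(events, config$panel, sheet)
      list(t1 = fms$t1, t2 = fms$t2, sheet = sheet, truth = NULL)
    } else {
      list(t1 = read_feature_matrix(config$features_t1_csv),
           t2 = read_feature_matrix(config$features_t2_csv),
           sheet = read_sample_sheet(config$sheet_csv), truth = NULL)
    }
  })
  stage("serialize-inputs", {
    write_feature_matrix(acquire$t1, out("features_t1.csv"))
    write_feature_matrix(acquire$t2, out("features_t2.csv"))
    write_sample_sheet(acquire$sheet, out("sample_sheet.csv"))
    if (!is.null(acquire$truth))
      write_truth_table(acquire$truth, out("truth.json"))
  })

  rates <- stage("rates", compute_rates(acquire$t1, acquire$t2, acquire$sheet))
  stage("rates-io", write_dynamics_matrix(rates, out("rates.csv")))

  net <- stage("network", {
    if (config$per_timepoint_network) {
      e1 <- spearman_edges(unclass(acquire$t1), config$network_threshold)
      e2 <- spearman_edges(unclass(acquire$t2), config$network_threshold)
      e2$from <- e2$from; edges <- rbind(e1, e2)
      edges <- edges[!duplicated(paste(edges$from, edges$to)), , drop = FALSE]
      attr(edges, "features") <- attr(e1, "features")
      build_correlation_network(edges, seed = config$seed)
    } else {
      pooled <- rbind(unclass(acquire$t1), unclass(acquire$t2))
      build_correlation_network(spearman_edges(pooled, config$network_threshold),
                                seed = config$seed)
    }
  })
  stage("network-io", write_network(net, out("network")))

  model <- stage("model", repeated_holdout(
    rates, acquire$sheet, n_test = config$n_test,
    n_iterations = config$n_iterations, seed = config$seed,
    n_folds = config$n_folds, n_lambda = config$n_lambda,
    min_ratio = config$min_ratio))
  stage("model-io", write_model_result(model, out("model")))

  profile <- stage("reduce", {
    if (all(colMeans(model$selection) == 0)) NULL else
      reduce_model(model, continuous = config$continuous_breakpoint)
  })
  if (!is.null(profile))
    stage("reduce-io", write_selection_profile(profile, out("model")))

  stats_tab <- stage("stats", univariate_table(
    rates, acquire$sheet, confounders = config$confounders,
    bh_adjust = config$bh_adjust))
  stage("stats-io", {
    write_csv17(stats_tab, out("univariate_stats.csv"))
    write_csv17(demographic_summary(acquire$sheet), out("demographics.csv"))
  })

  stage("report", {
    comm_sizes <- if (!is.null(net$communities))
      sort(table(net$communities), decreasing = TRUE) else integer(0)
    top <- if (!is.null(profile)) profile$top_features else character(0)
    lines <- c(
      "# immunodyn run report", "",
      sprintf("- seed: %d", config$seed),
      sprintf("- patients: %d (%d control / %d case)", nrow(acquire$sheet),
              sum(acquire$sheet$group == "control"),
              sum(acquire$sheet$group == "case")),
      sprintf("- features: %d", ncol(rates)),
      sprintf("- holdout iterations: %d (planned %d)", model$n_iterations,
              model$n_planned),
      sprintf("- ensemble AUC: %.3f", model$auc),
      sprintf("- group-difference Wilcoxon p: %.3g%s", model$p_value,
              if (model$p_value > 0.05) "  [NOT significant at 0.05]" else ""),
      "",
      "## Top features (breakpoint set)",
      if (length(top)) paste0("- ", top) else "- (null model; nothing to reduce)",
      "",
      "## Correlation network",
      sprintf("- nodes: %d, edges: %d", igraph::vcount(net$graph),
              igraph::ecount(net$graph)),
      if (length(comm_sizes)) {
        real <- comm_sizes[comm_sizes >= 2]
        sprintf("- communities: %d with >= 2 features (sizes: %s); %d isolated feature(s)",
                length(real), paste(as.integer(real), collapse = ", "),
                sum(comm_sizes == 1))
      } else "- communities: none (empty edge set)")
    writeLines(lines, out("report.md"))
  })

  stage("manifest", {
    cfg_for_hash <- config
    cfg_for_hash$design <- NULL
    manifest <- list(
      seed = config$seed,
      config_hash = sum(utf8ToInt(paste(deparse(unclass(cfg_for_hash)),
                                        collapse = ""))),
      package_version = as.character(packageVersion("immunodyn")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      igraph_version = as.character(packageVersion("igraph")),
      timepoints = c("T1", "T2"))
    jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                         digits = NA)
  })

  invisible(list(dir = config$output_dir, sheet = acquire$sheet,
                 truth = acquire$truth, rates = rates, network = net,
                 model = model, profile = profile, stats = stats_tab))
}
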