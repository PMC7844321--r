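#' Configure an end-to-end pipeline run
#'
#' Inputs are either fully synthetic (a [synthetic_config()], the default)
#' or file paths to expression TSVs, a sample-annotation TSV per matrix and
#' a reference edge list.
#'
#' @param synthetic A [synthetic_config()], or `NULL` when file inputs are
#'   given.
#' @param mirna_path,mirna_annotation,mrna_path,mrna_annotation,network_path
#'   Input file paths (ignored when `synthetic` is supplied).
#' @param probe_map_path Optional probe-to-gene TSV for collapsing mRNA
#'   probes.
#' @param gmt_path Optional GMT file for over-representation analysis.
#' @param known_biomarkers Optional character vector of literature-reported
#'   biomarker miRNAs for the precision index.
#' @param de_alpha Adjusted-p threshold for DE selection.
#' @param prioritize_alpha Per-feature threshold for prioritization.
#' @param wilcoxon_variant `"signed-rank"` or `"percentile"` (see
#'   [prioritize()]).
#' @param shared_mode `"intersection"` or `"union"` (see
#'   [shared_regulations()]).
#' @param outdir Output directory for artifacts, or `NULL` to skip writing.
#' @param seed Root random seed; overrides the synthetic config's seed so
#'   one number controls the whole run.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            mirna_path = NULL, mirna_annotation = NULL,
                            mrna_path = NULL, mrna_annotation = NULL,
                            network_path = NULL, probe_map_path = NULL,
                            gmt_path = NULL, known_biomarkers = NULL,
                            de_alpha = 0.05, prioritize_alpha = 0.05,
                            wilcoxon_variant = c("signed-rank", "percentile"),
                            shared_mode = c("intersection", "union"),
                            outdir = NULL, seed = NULL) {
  wilcoxon_variant <- match.arg(wilcoxon_variant)
  shared_mode <- match.arg(shared_mode)
  if (!(de_alpha > 0 && de_alpha <= 1))
    stop("de_alpha must lie in (0, 1]")
  if (!(prioritize_alpha > 0 && prioritize_alpha < 1))
    stop("prioritize_alpha must lie in (0, 1)")
  if (is.null(synthetic)) {
    need <- c(mirna_path, mirna_annotation, mrna_path, mrna_annotation,
              network_path)
    if (length(need) < 5)
      stop("file inputs require miRNA/mRNA matrices, annotations and a ",
           "reference network")
  } else {
    stopifnot(inherits(synthetic, "synthetic_config"))
    if (!is.null(seed)) {
      args <- synthetic[setdiff(names(synthetic), c("seed", ".layout"))]
      args$seed <- as.integer(seed)
      synthetic <- do.call(synthetic_config, args)
    }
  }
  structure(list(synthetic = synthetic, mirna_path = mirna_path,
                 mirna_annotation = mirna_annotation, mrna_path = mrna_path,
                 mrna_annotation = mrna_annotation,
                 network_path = network_path,
                 probe_map_path = probe_map_path, gmt_path = gmt_path,
                 known_biomarkers = known_biomarkers, de_alpha = de_alpha,
                 prioritize_alpha = prioritize_alpha,
                 wilcoxon_variant = wilcoxon_variant,
                 shared_mode = shared_mode, outdir = outdir,
                 seed = if (is.null(seed)) {
                   if (is.null(synthetic)) 1L else synthetic$seed
                 } else as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; a
#' `synthetic:` mapping is passed to [synthetic_config()].
#'
#' @param path Path to the YAML file.
#' @param ... Overrides applied on top of the file values.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path, ...) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read YAML configurations")
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$synthetic))
    vals$synthetic <- do.call(synthetic_config, vals$synthetic)
  vals <- utils::modifyList(vals, list(...))
  do.call(pipeline_config, vals)
}

#' Run the full biomarker-prioritization pipeline
#'
#' Executes every stage in order: input generation or loading,
#' differential expression of miRNAs and mRNAs for the occurrence and
#' progression contrasts, condition-specific network extraction,
#' topological feature computation and prioritization, cross-condition
#' intersection, shared-regulation extraction, ROC evaluation and sample
#' clustering of the nominated biomarkers, and (when a GMT file is
#' supplied) over-representation analysis of the shared target genes.
#'
#' When `config$outdir` is set, every intermediate artifact is written
#' there (DE tables, condition-network edge lists, feature tables, the
#' biomarker result JSON, ROC and enrichment TSVs and a `manifest.json`
#' with the per-stage counts). Re-running with the same configuration and
#' seed reproduces identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return A list of class `pipeline_result` with elements `manifest`,
#'   `de` (the four DE tables), `networks`, `features`, `prioritized`,
#'   `shared_mirnas`, `shared` (regulations), `roc`, `clustering`,
#'   `enrichment`, `truth` (synthetic runs only).
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message("[", format(Sys.time(), "%H:%M:%S"),
                                           "] ", ...)
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", what, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  truth <- NULL
  if (!is.null(config$synthetic)) {
    say("simulate: generating synthetic study (seed ", config$seed, ")")
    study <- stage("simulate", generate_synthetic_study(config$synthetic))
    mirna <- study$mirna; mrna <- study$mrna
    reference <- study$network; truth <- study$truth
  } else {
    say("load: reading input files")
    mirna <- stage("load", read_expression(config$mirna_path,
                                           config$mirna_annotation))
    mrna <- stage("load", read_expression(config$mrna_path,
                                          config$mrna_annotation))
    reference <- stage("load", read_edge_list(config$network_path))
  }

  say("de: differential expression (adj-p < ", config$de_alpha, ")")
  de <- list()
  for (cn in c("occurrence", "progression")) {
    ctr <- make_contrast(cn)
    de[[paste0("mirna_", cn)]] <- stage("de", run_de(mirna, ctr,
                                                     alpha = config$de_alpha))
    tab <- stage("de", run_de(mrna, ctr, alpha = config$de_alpha))
    if (!is.null(config$probe_map_path)) {
      pm <- utils::read.delim(config$probe_map_path,
                              stringsAsFactors = FALSE)
      tab <- stage("de", collapse_probes(tab, pm))
      tab$is_de <- tab$p_adj < config$de_alpha
    }
    de[[paste0("mrna_", cn)]] <- tab
  }
  de_sets <- lapply(de, function(t) select_de(t, config$de_alpha)$feature)

  say("network: extracting condition-specific networks")
  networks <- list(
    occurrence = stage("network", extract_condition_network(
      reference, de_sets$mirna_occurrence, de_sets$mrna_occurrence)),
    progression = stage("network", extract_condition_network(
      reference, de_sets$mirna_progression, de_sets$mrna_progression)))

  say("topology: NTG/NSR features and prioritization")
  features <- list(); prioritized <- list()
  for (cn in names(networks)) {
    ft <- stage("topology", mirna_features(networks[[cn]]))
    if (nrow(ft) >= 10) {
      ft <- stage("topology", prioritize(ft, alpha = config$prioritize_alpha,
                                         method = config$wilcoxon_variant))
      prioritized[[cn]] <- ft$mirna[ft$prioritized]
    } else {
      if (nrow(ft)) warning("condition '", cn, "' has fewer than 10 miRNAs; ",
                            "no prioritization performed")
      ft$p_ntg <- ft$p_nsr <- ft$p_ratio <- numeric(nrow(ft))
      ft$prioritized <- logical(nrow(ft))
      prioritized[[cn]] <- character(0)
    }
    ft$condition <- rep(cn, nrow(ft))
    features[[cn]] <- ft
  }

  shared_mirnas <- intersect_conditions(prioritized$occurrence,
                                        prioritized$progression)
  say("intersect: ", length(shared_mirnas), " shared miRNA(s)")
  shared <- if (length(shared_mirnas)) {
    stage("shared", shared_regulations(networks$occurrence,
                                       networks$progression, shared_mirnas,
                                       mode = config$shared_mode))
  } else {
    list(edges = data.frame(mirna = character(0), mrna = character(0)),
         n_mrna = 0L, n_regulations = 0L)
  }

  roc <- NULL; clustering <- NULL
  if (length(shared_mirnas)) {
    say("evaluate: ROC and clustering for ", length(shared_mirnas),
        " candidate(s)")
    roc <- stage("evaluate", evaluate_candidates(mirna, shared_mirnas))
    present <- intersect(shared_mirnas, rownames(mirna$values))
    if (length(present) >= 2)
      clustering <- stage("evaluate",
                          cluster_samples(subset_features(mirna, present)))
  }

  enrichment <- NULL
  if (!is.null(config$gmt_path) && shared$n_mrna > 0) {
    say("enrich: over-representation analysis")
    collection <- stage("enrich", read_gmt(config$gmt_path))
    enrichment <- stage("enrich", ora_test(unique(shared$edges$mrna),
                                           collection,
                                           universe = reference$mrna_nodes))
  }

  precision <- if (!is.null(config$known_biomarkers) && length(shared_mirnas))
    prediction_precision(shared_mirnas, config$known_biomarkers) else NULL

  manifest <- list(
    package_version = as.character(utils::packageVersion("mirnsr")),
    seed = config$seed,
    de_alpha = config$de_alpha,
    prioritize_alpha = config$prioritize_alpha,
    wilcoxon_variant = config$wilcoxon_variant,
    shared_mode = config$shared_mode,
    counts = list(
      reference_edges = n_edges(reference),
      de_mirnas_occurrence = length(de_sets$mirna_occurrence),
      de_mirnas_progression = length(de_sets$mirna_progression),
      de_mrnas_occurrence = length(de_sets$mrna_occurrence),
      de_mrnas_progression = length(de_sets$mrna_progression),
      occurrence_edges = n_edges(networks$occurrence),
      progression_edges = n_edges(networks$progression),
      prioritized_occurrence = length(prioritized$occurrence),
      prioritized_progression = length(prioritized$progression),
      shared_mirnas = length(shared_mirnas),
      shared_regulations = shared$n_regulations,
      shared_mrnas = shared$n_mrna),
    shared_mirnas = as.list(shared_mirnas),
    mean_auc = if (!is.null(roc)) {
      as.list(tapply(roc$auc_folded, roc$contrast, function(z)
        round(mean(z), 4)))
    } else NULL,
    prediction_precision = precision)

  result <- structure(list(manifest = manifest, de = de, networks = networks,
                           features = features, prioritized = prioritized,
                           shared_mirnas = shared_mirnas, shared = shared,
                           roc = roc, clustering = clustering,
                           enrichment = enrichment, truth = truth),
                      class = "pipeline_result")
  if (!is.null(config$outdir)) write_pipeline_artifacts(result, config)
  result
}

write_pipeline_artifacts <- function(result, config) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(config$outdir, f)
  for (nm in names(result$de))
    write_de_table(result$de[[nm]], p(paste0("de_", nm, ".tsv")))
  for (nm in names(result$networks))
    write_edge_list(result$networks[[nm]], p(paste0("network_", nm, ".tsv")),
                    header = TRUE)
  write_feature_table(do.call(rbind, result$features), p("features.tsv"))
  utils::write.table(result$shared$edges, p("shared_regulations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(prioritized = result$prioritized,
         shared_mirnas = result$shared_mirnas,
         n_shared_regulations = result$shared$n_regulations,
         n_shared_mrnas = result$shared$n_mrna),
    p("biomarker_result.json"), auto_unbox = FALSE, digits = NA,
    pretty = TRUE)
  if (!is.null(result$roc))
    utils::write.table(result$roc, p("roc.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(result$enrichment))
    utils::write.table(result$enrichment, p("enrichment.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(result$truth)) write_ground_truth(result$truth,
                                                 p("ground_truth.json"))
  jsonlite::write_json(result$manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(config$outdir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cts <- x$manifest$counts
  cat("pipeline_result\n")
  cat(sprintf("  DE miRNAs (occ/prog): %d / %d; DE mRNAs: %d / %d\n",
              cts$de_mirnas_occurrence, cts$de_mirnas_progression,
              cts$de_mrnas_occurrence, cts$de_mrnas_progression))
  cat(sprintf("  condition edges (occ/prog): %d / %d\n",
              cts$occurrence_edges, cts$progression_edges))
  cat(sprintf("  prioritized (occ/prog): %d / %d; shared: %d\n",
              cts$prioritized_occurrence, cts$prioritized_progression,
              cts$shared_mirnas))
  if (length(x$shared_mirnas))
    cat("  shared miRNAs:", paste(x$shared_mirnas, collapse = ", "), "\n")
  cat(sprintf("  shared regulations: %d (%d distinct mRNAs)\n",
              cts$shared_regulations, cts$shared_mrnas))
  invisible(x)
}
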