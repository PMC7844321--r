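#' Configuration for the synthetic study generator
#'
#' Describes a fully synthetic three-group study (normal, primary tumour
#' pPCa, metastatic tumour mPCa) with planted differential expression and a
#' planted reference miRNA-mRNA network, mirroring the design of the
#' microarray cohorts the model was developed on. Group sizes default to
#' those cohorts: 28/99/14 samples for the miRNA matrix and 29/131/19 for
#' the mRNA matrix.
#'
#' Two contrasts are planted. "Occurrence" features are shifted in both
#' tumour groups relative to normal; "progression" features receive an
#' additional shift in the metastatic group, so a feature can be
#' differentially expressed in both contrasts at once. Planted biomarker
#' miRNAs are DE in both contrasts and additionally receive
#' `singleline_boost` exclusive targets in the reference network (mRNAs
#' regulated by no other miRNA, themselves planted DE in both contrasts so
#' that exclusivity survives DE filtering).
#'
#' @param n_normal,n_ppca,n_mpca Sample counts per group for the miRNA
#'   matrix.
#' @param n_normal_mrna,n_ppca_mrna,n_mpca_mrna Sample counts per group for
#'   the mRNA matrix.
#' @param n_mirna,n_mrna Feature counts.
#' @param n_planted_biomarkers Number of planted biomarker miRNAs.
#' @param de_fraction Fraction of features planted DE per contrast.
#' @param effect_size Mean group shift for a planted-DE feature, log2 units.
#' @param noise_sd Within-group standard deviation, log2 units.
#' @param edge_density Background probability of a miRNA-to-mRNA edge.
#' @param singleline_boost Number of exclusive (in-degree 1) targets planted
#'   per biomarker miRNA.
#' @param seed Integer random seed; identical configurations yield
#'   byte-identical outputs.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_normal = 28, n_ppca = 99, n_mpca = 14,
                             n_normal_mrna = 29, n_ppca_mrna = 131,
                             n_mpca_mrna = 19,
                             n_mirna = 150, n_mrna = 1500,
                             n_planted_biomarkers = 5,
                             de_fraction = 0.15,
                             effect_size = 2, noise_sd = 1,
                             edge_density = 0.08,
                             singleline_boost = 15,
                             seed = 1L) {
  cfg <- list(n_normal = n_normal, n_ppca = n_ppca, n_mpca = n_mpca,
              n_normal_mrna = n_normal_mrna, n_ppca_mrna = n_ppca_mrna,
              n_mpca_mrna = n_mpca_mrna,
              n_mirna = n_mirna, n_mrna = n_mrna,
              n_planted_biomarkers = n_planted_biomarkers,
              de_fraction = de_fraction, effect_size = effect_size,
              noise_sd = noise_sd, edge_density = edge_density,
              singleline_boost = singleline_boost, seed = as.integer(seed))
  counts <- cfg[c("n_normal", "n_ppca", "n_mpca", "n_normal_mrna",
                  "n_ppca_mrna", "n_mpca_mrna", "n_mirna", "n_mrna")]
  if (any(unlist(counts) < 1)) stop("all sample/feature counts must be >= 1")
  if (cfg$n_planted_biomarkers < 0)
    stop("n_planted_biomarkers must be >= 0")
  if (!(cfg$de_fraction > 0 && cfg$de_fraction < 1))
    stop("de_fraction must lie in (0, 1)")
  if (!(cfg$edge_density >= 0 && cfg$edge_density < 1))
    stop("edge_density must lie in [0, 1)")
  if (cfg$singleline_boost < 0) stop("singleline_boost must be >= 0")
  if (cfg$effect_size < 0) stop("effect_size must be >= 0")
  if (cfg$noise_sd <= 0) stop("noise_sd must be > 0")
  layout <- planted_layout(cfg)  # validates feasibility of the planting
  cfg$.layout <- layout
  structure(cfg, class = "synthetic_config")
}

mirna_ids <- function(n) sprintf("mir-%03d", seq_len(n))
mrna_ids <- function(n) sprintf("gene-%04d", seq_len(n))

# Deterministic (seed-independent) assignment of feature ids to planted
# roles: which miRNAs/mRNAs are DE in each contrast, which miRNAs are
# biomarkers, and which mRNAs serve as their exclusive targets.
planted_layout <- function(cfg) {
  mir <- mirna_ids(cfg$n_mirna)
  gene <- mrna_ids(cfg$n_mrna)
  k <- cfg$n_planted_biomarkers
  if (k > cfg$n_mirna) stop("more planted biomarkers than miRNAs")

  n_de_mir <- max(k, round(cfg$de_fraction * cfg$n_mirna))
  if (2 * n_de_mir - k > cfg$n_mirna)
    stop("de_fraction too large for disjoint contrast-specific miRNA sets")
  biomarkers <- mir[seq_len(k)]
  occ_mir <- mir[seq_len(n_de_mir)]
  prog_mir <- c(biomarkers,
                mir[seq.int(n_de_mir + 1, length.out = n_de_mir - k)])

  n_excl <- k * cfg$singleline_boost
  n_de_gene <- round(cfg$de_fraction * cfg$n_mrna)
  both_pool <- n_excl + max(0L, round(0.1 * n_de_gene))
  if (both_pool > n_de_gene)
    stop("requested exclusive targets exceed the available mRNA pool: ",
         "increase n_mrna or de_fraction, or lower singleline_boost")
  if (2 * n_de_gene - both_pool > cfg$n_mrna)
    stop("de_fraction too large for disjoint contrast-specific mRNA sets")
  occ_gene <- gene[seq_len(n_de_gene)]
  prog_gene <- c(gene[seq_len(both_pool)],
                 gene[seq.int(n_de_gene + 1, length.out = n_de_gene - both_pool)])

  exclusive <- if (n_excl > 0) {
    split(gene[seq_len(n_excl)], rep(biomarkers, each = cfg$singleline_boost))
  } else {
    stats::setNames(rep(list(character(0)), k), biomarkers)
  }
  list(mirnas = mir, mrnas = gene,
       biomarkers = biomarkers,
       de_mirnas_occurrence = occ_mir, de_mirnas_progression = prog_mir,
       de_mrnas_occurrence = occ_gene, de_mrnas_progression = prog_gene,
       exclusive_targets = exclusive[biomarkers])
}

#' Generate the synthetic reference network and its ground truth
#'
#' Background edges are drawn independently with probability
#' `edge_density`; each planted biomarker then receives `singleline_boost`
#' exclusive targets whose only regulator it is (those mRNA columns carry no
#' background edges at all, so their in-degree in the reference map is
#' exactly 1).
#'
#' @param config A [synthetic_config()].
#' @return A list with elements `network` (a [bipartite_network()]) and
#'   `truth` (a `ground_truth` list recording planted DE sets, planted
#'   biomarkers, exclusive-target assignments and planted effect
#'   directions).
#' @export
generate_reference_network <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  lay <- config$.layout
  set.seed(config$seed)

  excl_genes <- unlist(lay$exclusive_targets, use.names = FALSE)
  open_genes <- setdiff(lay$mrnas, excl_genes)
  adj <- matrix(stats::rbinom(config$n_mirna * length(open_genes), 1L,
                              config$edge_density),
                nrow = config$n_mirna,
                dimnames = list(lay$mirnas, open_genes))
  idx <- which(adj == 1L, arr.ind = TRUE)
  edges <- data.frame(mirna = rownames(adj)[idx[, 1]],
                      mrna = colnames(adj)[idx[, 2]],
                      stringsAsFactors = FALSE)
  if (length(excl_genes)) {
    boost <- data.frame(
      mirna = rep(names(lay$exclusive_targets),
                  lengths(lay$exclusive_targets)),
      mrna = excl_genes, stringsAsFactors = FALSE)
    edges <- rbind(edges, boost)
  }
  net <- bipartite_network(edges, mirna_nodes = lay$mirnas,
                           mrna_nodes = lay$mrnas)

  # planted effect directions, one sign per feature per contrast
  dir_of <- function(ids) stats::setNames(sample(c(-1, 1), length(ids),
                                                 replace = TRUE), ids)
  truth <- structure(list(
    planted_de_mirnas_occurrence = lay$de_mirnas_occurrence,
    planted_de_mirnas_progression = lay$de_mirnas_progression,
    planted_de_mrnas_occurrence = lay$de_mrnas_occurrence,
    planted_de_mrnas_progression = lay$de_mrnas_progression,
    planted_biomarkers = lay$biomarkers,
    planted_exclusive_targets = lay$exclusive_targets,
    direction_mirnas_occurrence = dir_of(lay$de_mirnas_occurrence),
    direction_mirnas_progression = dir_of(lay$de_mirnas_progression),
    direction_mrnas_occurrence = dir_of(lay$de_mrnas_occurrence),
    direction_mrnas_progression = dir_of(lay$de_mrnas_progression)
  ), class = "ground_truth")
  list(network = net, truth = truth)
}

#' Generate synthetic miRNA and mRNA expression matrices
#'
#' Expression is simulated on an additive log2-like scale: a per-feature
#' baseline plus planted group shifts plus independent Gaussian noise.
#' Occurrence-DE features are shifted by `effect_size` (signed per the
#' ground truth) in both tumour groups; progression-DE features receive an
#' additional signed `effect_size` shift in the metastatic group only.
#' Non-planted features have identical group means.
#'
#' @param config A [synthetic_config()].
#' @param truth The `ground_truth` produced by [generate_reference_network()]
#'   under the same configuration.
#' @return A list with elements `mirna` and `mrna`, each an
#'   [expression_matrix()].
#' @export
generate_expression <- function(config, truth) {
  stopifnot(inherits(config, "synthetic_config"),
            inherits(truth, "ground_truth"))
  lay <- config$.layout
  planted <- c(truth$planted_de_mirnas_occurrence,
               truth$planted_de_mirnas_progression,
               truth$planted_de_mrnas_occurrence,
               truth$planted_de_mrnas_progression,
               unlist(truth$planted_exclusive_targets, use.names = FALSE))
  if (!all(planted %in% c(lay$mirnas, lay$mrnas)))
    stop("ground truth refers to feature ids outside this configuration")

  set.seed(config$seed + 1L)
  sim_one <- function(ids, n_norm, n_ppca, n_mpca, occ_ids, prog_ids,
                      occ_dir, prog_dir, prefix) {
    n <- length(ids)
    samples <- c(sprintf("%s_normal_%02d", prefix, seq_len(n_norm)),
                 sprintf("%s_ppca_%03d", prefix, seq_len(n_ppca)),
                 sprintf("%s_mpca_%02d", prefix, seq_len(n_mpca)))
    groups <- stats::setNames(rep(c("normal", "pPCa", "mPCa"),
                                  c(n_norm, n_ppca, n_mpca)), samples)
    baseline <- stats::rnorm(n, mean = 7, sd = 1)
    mu <- matrix(baseline, n, length(samples),
                 dimnames = list(ids, samples))
    tumour <- groups %in% c("pPCa", "mPCa")
    meta <- groups == "mPCa"
    shift_occ <- stats::setNames(numeric(n), ids)
    shift_occ[occ_ids] <- occ_dir[occ_ids] * config$effect_size
    shift_prog <- stats::setNames(numeric(n), ids)
    shift_prog[prog_ids] <- prog_dir[prog_ids] * config$effect_size
    mu[, tumour] <- mu[, tumour] + shift_occ
    mu[, meta] <- mu[, meta] + shift_prog
    values <- mu + matrix(stats::rnorm(length(mu), 0, config$noise_sd),
                          nrow(mu))
    expression_matrix(values, groups)
  }
  mirna <- sim_one(lay$mirnas, config$n_normal, config$n_ppca, config$n_mpca,
                   truth$planted_de_mirnas_occurrence,
                   truth$planted_de_mirnas_progression,
                   truth$direction_mirnas_occurrence,
                   truth$direction_mirnas_progression, "mir")
  mrna <- sim_one(lay$mrnas, config$n_normal_mrna, config$n_ppca_mrna,
                  config$n_mpca_mrna,
                  truth$planted_de_mrnas_occurrence,
                  truth$planted_de_mrnas_progression,
                  truth$direction_mrnas_occurrence,
                  truth$direction_mrnas_progression, "rna")
  list(mirna = mirna, mrna = mrna)
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper running [generate_reference_network()] and
#' [generate_expression()] under one configuration.
#'
#' @param config A [synthetic_config()].
#' @return A list with elements `mirna`, `mrna` (expression matrices),
#'   `network` (reference [bipartite_network()]) and `truth`.
#' @export
generate_synthetic_study <- function(config = synthetic_config()) {
  ref <- generate_reference_network(config)
  expr <- generate_expression(config, ref$truth)
  list(mirna = expr$mirna, mrna = expr$mrna,
       network = ref$network, truth = ref$truth)
}

#' Serialize ground truth as JSON
#'
#' @param truth A `ground_truth` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = FALSE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
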