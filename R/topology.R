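#' Number of targeted genes (NTG) of a miRNA
#'
#' The out-degree of a miRNA in a condition-specific network: how many
#' mRNAs it targets. Hub miRNAs with large NTG sit at the centre of the
#' regulatory system.
#'
#' @param network A [bipartite_network()].
#' @param mirna A miRNA id present in the network.
#' @return Integer count.
#' @export
compute_ntg <- function(network, mirna) {
  stopifnot(inherits(network, "bipartite_network"))
  if (!mirna %in% network$mirna_nodes)
    stop("unknown miRNA id: ", mirna)
  sum(network$edges$mirna == mirna)
}

#' Number of single-line regulations (NSR) of a miRNA
#'
#' Counts the miRNA's targets whose in-degree in the same network is
#' exactly 1, i.e. mRNAs regulated by this miRNA alone. Single-line
#' regulation points are vulnerable sites of the network: perturbing their
#' sole regulator has no redundant backup, so miRNAs with high NSR are
#' structurally important.
#'
#' @inheritParams compute_ntg
#' @return Integer count (`0 <= NSR <= NTG`).
#' @export
compute_nsr <- function(network, mirna) {
  stopifnot(inherits(network, "bipartite_network"))
  if (!mirna %in% network$mirna_nodes)
    stop("unknown miRNA id: ", mirna)
  targets <- network$edges$mrna[network$edges$mirna == mirna]
  if (!length(targets)) return(0L)
  indeg <- table(network$edges$mrna)
  sum(indeg[targets] == 1L)
}

#' Single-line regulation ratio NSR/NTG
#'
#' @param ntg Number of targeted genes.
#' @param nsr Number of single-line regulations; must not exceed `ntg`.
#' @return `nsr/ntg` rounded to 4 decimals; `0` when `ntg = 0`.
#' @export
compute_ratio <- function(ntg, nsr) {
  if (length(ntg) != length(nsr))
    stop("`ntg` and `nsr` must have equal length")
  if (any(ntg < 0) || any(nsr < 0)) stop("counts must be nonnegative")
  if (any(nsr > ntg)) stop("inconsistent counts: NSR exceeds NTG")
  out <- ifelse(ntg == 0, 0, nsr / ntg)
  round(out, 4)
}

#' Topological feature table for every miRNA in a network
#'
#' Vectorized computation of NTG, NSR and NSR/NTG for all miRNAs of a
#' condition-specific network.
#'
#' @param network A [bipartite_network()].
#' @return Data frame `mirna`, `ntg`, `nsr`, `ratio`, one row per miRNA
#'   node, sorted by miRNA id.
#' @export
mirna_features <- function(network) {
  stopifnot(inherits(network, "bipartite_network"))
  mirnas <- network$mirna_nodes
  if (!length(mirnas))
    return(data.frame(mirna = character(0), ntg = integer(0),
                      nsr = integer(0), ratio = numeric(0)))
  ntg <- table(factor(network$edges$mirna, levels = mirnas))
  indeg <- table(network$edges$mrna)
  single <- names(indeg)[indeg == 1L]
  se <- network$edges[network$edges$mrna %in% single, , drop = FALSE]
  nsr <- table(factor(se$mirna, levels = mirnas))
  out <- data.frame(mirna = mirnas, ntg = as.integer(ntg),
                    nsr = as.integer(nsr),
                    stringsAsFactors = FALSE)
  out$ratio <- compute_ratio(out$ntg, out$nsr)
  out
}

#' One-sample Wilcoxon signed-rank test
#'
#' Tests whether a vector of differences is symmetrically distributed
#' about zero. Zeros are dropped; absolute values are ranked with midranks
#' for ties; the statistic `W` is the sum of ranks of the positive
#' differences. The p-value is exact (full sign-pattern distribution) when
#' at most 25 nonzero differences remain and the absolute values are
#' untied, and otherwise uses the normal approximation with tie and
#' continuity corrections.
#'
#' @param d Numeric vector of differences.
#' @param alternative `"two.sided"`, `"less"` (negative median) or
#'   `"greater"`.
#' @return List with `statistic` (W), `p.value`, `n` (nonzero
#'   differences), `exact` (logical).
#' @export
wilcoxon_signed_rank <- function(d,
                                 alternative = c("two.sided", "less",
                                                 "greater")) {
  alternative <- match.arg(alternative)
  if (!is.numeric(d)) stop("differences must be numeric")
  d <- d[is.finite(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    stop("degenerate input: all differences are zero")
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  ties <- anyDuplicated(abs(d)) > 0
  exact <- !ties && n <= 25
  if (exact) {
    # exact null distribution of W by integer convolution over the 2^n
    # sign patterns; counts stay below 2^25 so all arithmetic is exact
    counts <- 1
    for (rr in seq_len(n))
      counts <- c(counts, numeric(rr)) + c(numeric(rr), counts)
    wi <- as.integer(round(w))
    p_greater <- sum(counts[(wi + 1):length(counts)]) / 2^n
    p_less <- sum(counts[seq_len(wi + 1)]) / 2^n
    p <- switch(alternative,
                greater = p_greater,
                less = p_less,
                two.sided = min(1, 2 * min(p_greater, p_less)))
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- w - mu
      cc <- switch(alternative, two.sided = sign(z) * 0.5,
                   greater = 0.5, less = -0.5)
      z <- (z - cc) / sqrt(sigma2)
      p <- switch(alternative,
                  greater = stats::pnorm(z, lower.tail = FALSE),
                  less = stats::pnorm(z),
                  two.sided = min(1, 2 * min(stats::pnorm(z),
                                             stats::pnorm(z,
                                                          lower.tail = FALSE))))
    }
  }
  list(statistic = w, p.value = p, n = n, exact = exact)
}

#' Prioritize significantly strong regulator miRNAs in one network
#'
#' For each miRNA and each topological feature (NTG, NSR, NSR/NTG) the
#' remaining miRNAs' values are compared against the focal miRNA's value
#' with a leave-one-out one-sided Wilcoxon signed-rank test (alternative:
#' the cohort's values fall below the focal value). A miRNA is prioritized
#' when all three features are significantly high (`p < alpha` for each).
#' Metric ties with the focal value yield zero differences and are dropped,
#' following the standard signed-rank convention; no multiplicity
#' correction is applied across miRNAs at this stage.
#'
#' The alternative `"percentile"` rule replaces the signed-rank p-value by
#' an empirical exceedance probability `(1 + #{others >= value}) /
#' (1 + #others)`, so `alpha = 0.05` approximates a 95th-percentile cut;
#' it is provided for sensitivity analysis.
#'
#' @param features Feature table from [mirna_features()] (one condition).
#' @param alpha Per-feature significance threshold (default 0.05).
#' @param method `"signed-rank"` (default) or `"percentile"`.
#' @return The feature table with added columns `p_ntg`, `p_nsr`,
#'   `p_ratio`, `prioritized`.
#' @export
prioritize <- function(features, alpha = 0.05,
                       method = c("signed-rank", "percentile")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(features),
            all(c("mirna", "ntg", "nsr", "ratio") %in% names(features)))
  if (nrow(features) < 10)
    stop("insufficient network: prioritization needs >= 10 miRNAs, got ",
         nrow(features))
  one_metric <- function(x) {
    vapply(seq_along(x), function(m) {
      others <- x[-m]
      if (method == "percentile")
        return((1 + sum(others >= x[m])) / (1 + length(others)))
      d <- others - x[m]
      if (all(d == 0)) return(1)
      wilcoxon_signed_rank(d, alternative = "less")$p.value
    }, numeric(1))
  }
  features$p_ntg <- one_metric(features$ntg)
  features$p_nsr <- one_metric(features$nsr)
  features$p_ratio <- one_metric(features$ratio)
  features$prioritized <- features$p_ntg < alpha & features$p_nsr < alpha &
    features$p_ratio < alpha
  features
}

#' Intersect prioritized miRNA sets across conditions
#'
#' miRNAs prioritized in both the occurrence- and progression-specific
#' networks are the biomarker nominations.
#'
#' @param occurrence_set,progression_set Character vectors of miRNA ids.
#' @return Sorted character vector of shared miRNAs.
#' @export
intersect_conditions <- function(occurrence_set, progression_set) {
  sort(intersect(unique(as.character(occurrence_set)),
                 unique(as.character(progression_set))))
}

#' Shared miRNA-mRNA regulations of the biomarker miRNAs
#'
#' Extracts the regulations incident to the shared miRNAs that appear in
#' both condition networks (`mode = "intersection"`, default) or in either
#' (`mode = "union"`).
#'
#' @param occ_net,prog_net Condition-specific [bipartite_network()]s.
#' @param shared_mirnas Nonempty character vector of shared miRNA ids.
#' @param mode `"intersection"` or `"union"`.
#' @return List with `edges` (data frame `mirna`, `mrna`), `n_mrna`
#'   (distinct target count) and `n_regulations`.
#' @export
shared_regulations <- function(occ_net, prog_net, shared_mirnas,
                               mode = c("intersection", "union")) {
  mode <- match.arg(mode)
  stopifnot(inherits(occ_net, "bipartite_network"),
            inherits(prog_net, "bipartite_network"))
  shared_mirnas <- unique(as.character(shared_mirnas))
  if (!length(shared_mirnas)) stop("`shared_mirnas` must be nonempty")
  key <- function(e) paste(e$mirna, e$mrna, sep = "\r")
  a <- occ_net$edges[occ_net$edges$mirna %in% shared_mirnas, , drop = FALSE]
  b <- prog_net$edges[prog_net$edges$mirna %in% shared_mirnas, , drop = FALSE]
  if (mode == "intersection") {
    edges <- a[key(a) %in% key(b), , drop = FALSE]
  } else {
    edges <- rbind(a, b[!key(b) %in% key(a), , drop = FALSE])
  }
  edges <- edges[order(edges$mirna, edges$mrna), , drop = FALSE]
  rownames(edges) <- NULL
  list(edges = edges, n_mrna = length(unique(edges$mrna)),
       n_regulations = nrow(edges))
}

#' Write a per-condition miRNA feature table as TSV
#'
#' @param features Output of [prioritize()] (optionally several conditions
#'   bound together with a `condition` column).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_feature_table <- function(features, path) {
  utils::write.table(features, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
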