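#' ROC curve and AUC for one marker
#'
#' The AUC is computed as the Mann-Whitney probability that a positive
#' sample's score exceeds a negative sample's score, ties counted one half.
#' Expression itself serves as the score, so a down-regulated marker
#' naturally yields a directional AUC below 0.5; the folded value
#' `max(auc, 1 - auc)` is reported alongside.
#'
#' @param scores Numeric vector of per-sample scores (e.g. expression of
#'   one miRNA).
#' @param labels Per-sample class labels with exactly two levels present.
#' @param positive The label treated as positive; default: the last level
#'   in sort order.
#' @return Object of class `roc_result`: list with `auc_directional`,
#'   `auc_folded`, `n_pos`, `n_neg`, and `curve`, a data frame of (FPR,
#'   TPR) points from (0,0) to (1,1).
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  if (!is.numeric(scores)) stop("`scores` must be numeric")
  labels <- as.character(labels)
  if (length(scores) != length(labels))
    stop("`scores` and `labels` must have equal length")
  lev <- sort(unique(labels))
  if (length(lev) != 2)
    stop("`labels` must contain exactly two classes, got ", length(lev))
  if (is.null(positive)) positive <- lev[2]
  if (!positive %in% lev) stop("positive class not present in labels")
  pos <- labels == positive
  n_pos <- sum(pos); n_neg <- sum(!pos)
  r <- rank(scores)
  # 2*concordance is integer-valued: exact rational arithmetic before the
  # single final division keeps AUC(s) + AUC(-s) = 1 an exact identity
  conc2 <- 2 * sum(r[pos]) - n_pos * (n_pos + 1)
  auc <- conc2 / (2 * n_pos * n_neg)

  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  last <- c(s[-1] != s[-length(s)], TRUE)  # threshold after each tie block
  tpr <- cumsum(p)[last] / n_pos
  fpr <- cumsum(!p)[last] / n_neg
  curve <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
  structure(list(auc_directional = auc, auc_folded = max(auc, 1 - auc),
                 n_pos = n_pos, n_neg = n_neg, curve = curve),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUC %.4f (folded %.4f), %d pos / %d neg\n",
              x$auc_directional, x$auc_folded, x$n_pos, x$n_neg))
  invisible(x)
}

#' Hierarchical clustering of samples on candidate-marker expression
#'
#' Samples are clustered by average-linkage agglomeration on the
#' correlation distance `1 - Pearson r` computed across the candidate
#' features (each feature standardized first). Columns are processed in
#' lexicographic sample order, which makes the result invariant to the
#' input column order; constant features are dropped with a warning.
#'
#' @param x An [expression_matrix()] or plain numeric matrix (features in
#'   rows), typically restricted to the candidate miRNAs.
#' @param k Number of flat clusters to cut (default 3, matching the
#'   normal / primary / metastatic design).
#' @return Object of class `sample_clustering`: list with `hclust`, `order`
#'   (leaf sample ids), `clusters` (named integer vector), `dist` (the
#'   correlation-distance matrix), `dropped` (constant features removed).
#' @export
cluster_samples <- function(x, k = 3) {
  values <- if (inherits(x, "expression_matrix")) x$values else x
  if (!is.matrix(values) || !is.numeric(values))
    stop("`x` must be an expression_matrix or numeric matrix")
  if (ncol(values) < 3) stop("clustering needs >= 3 samples")
  values <- values[, order(colnames(values)), drop = FALSE]
  sds <- apply(values, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant feature(s) dropped before clustering")
    values <- values[sds > 0, , drop = FALSE]
  }
  if (nrow(values) < 2) stop("clustering needs >= 2 non-constant features")
  z <- t(scale(t(values)))
  d <- stats::as.dist(1 - stats::cor(z))
  h <- stats::hclust(d, method = "average")
  clusters <- stats::cutree(h, k = min(k, ncol(values)))
  structure(list(hclust = h, order = h$labels[h$order],
                 clusters = clusters, dist = d,
                 dropped = names(sds)[sds == 0]),
            class = "sample_clustering")
}

#' Literature-precision index of a predicted biomarker set
#'
#' The percentage of predicted miRNAs that are already reported biomarkers
#' for the disease, used as an external validation index of the model.
#'
#' @param predicted Nonempty character vector of predicted miRNA ids.
#' @param known Character vector of literature-reported biomarker ids.
#' @return Percentage, rounded to one decimal.
#' @export
prediction_precision <- function(predicted, known) {
  predicted <- unique(as.character(predicted))
  if (!length(predicted)) stop("`predicted` must be nonempty")
  known <- unique(as.character(known))
  round(100 * length(intersect(predicted, known)) / length(predicted), 1)
}

#' Evaluate candidate miRNAs by ROC on both contrasts
#'
#' For every candidate, computes the occurrence AUC (normal vs tumour) and
#' the progression AUC (primary vs metastatic) from its expression.
#'
#' @param x The miRNA [expression_matrix()].
#' @param candidates Character vector of miRNA ids.
#' @return Data frame `mirna`, `contrast`, `auc_directional`, `auc_folded`,
#'   `n_pos`, `n_neg`.
#' @export
evaluate_candidates <- function(x, candidates) {
  stopifnot(inherits(x, "expression_matrix"))
  candidates <- intersect(candidates, rownames(x$values))
  if (!length(candidates)) stop("no candidate is present in the matrix")
  rows <- list()
  for (cn in c("occurrence", "progression")) {
    ctr <- make_contrast(cn)
    keep <- x$groups %in% c(ctr$group_a, ctr$group_b)
    lab <- ifelse(x$groups[keep] %in% ctr$group_b, "case", "control")
    for (m in candidates) {
      r <- roc_auc(x$values[m, keep], lab, positive = "case")
      rows[[length(rows) + 1L]] <- data.frame(
        mirna = m, contrast = cn, auc_directional = r$auc_directional,
        auc_folded = r$auc_folded, n_pos = r$n_pos, n_neg = r$n_neg,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
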