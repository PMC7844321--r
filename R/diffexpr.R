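#' Define a two-group contrast
#'
#' The model uses two contrasts: `"occurrence"` compares normal samples
#' against all tumour samples (primary and metastatic pooled), and
#' `"progression"` compares primary against metastatic tumours. The
#' occurrence contrast can optionally be restricted to primary tumours
#' only.
#'
#' @param name `"occurrence"` or `"progression"`.
#' @param ppca_only For `"occurrence"`: use only the primary-tumour group
#'   as the tumour class instead of pooling primary and metastatic.
#' @return A list of class `de_contrast` with `name`, `group_a`, `group_b`.
#'   Log fold changes are `mean(group_b) - mean(group_a)`.
#' @export
make_contrast <- function(name = c("occurrence", "progression"),
                          ppca_only = FALSE) {
  name <- match.arg(name)
  if (name == "occurrence") {
    group_a <- "normal"
    group_b <- if (ppca_only) "pPCa" else c("pPCa", "mPCa")
  } else {
    group_a <- "pPCa"
    group_b <- "mPCa"
  }
  structure(list(name = name, group_a = group_a, group_b = group_b),
            class = "de_contrast")
}

#' Per-feature two-group statistics
#'
#' Computes, for every feature, the difference of group means (log2 fold
#' change), the pooled within-group variance, the residual degrees of
#' freedom and the standard-error scale of the mean difference.
#'
#' @param x An [expression_matrix()].
#' @param contrast A [make_contrast()] object.
#' @return Data frame with columns `feature`, `log_fc`, `s2`, `df_resid`,
#'   `v` (`= 1/n_a + 1/n_b`), plus attributes `n_a`, `n_b`.
#' @export
fit_two_group <- function(x, contrast) {
  stopifnot(inherits(x, "expression_matrix"),
            inherits(contrast, "de_contrast"))
  a <- x$values[, x$groups %in% contrast$group_a, drop = FALSE]
  b <- x$values[, x$groups %in% contrast$group_b, drop = FALSE]
  n_a <- ncol(a); n_b <- ncol(b)
  if (n_a < 2 || n_b < 2)
    stop("insufficient replication: each contrast side needs >= 2 samples (",
         contrast$name, " has ", n_a, " vs ", n_b, ")")
  mean_a <- rowMeans(a)
  mean_b <- rowMeans(b)
  ss_a <- rowSums((a - mean_a)^2)
  ss_b <- rowSums((b - mean_b)^2)
  df_resid <- n_a + n_b - 2
  out <- data.frame(feature = rownames(x$values),
                    log_fc = mean_b - mean_a,
                    s2 = (ss_a + ss_b) / df_resid,
                    df_resid = df_resid,
                    v = 1 / n_a + 1 / n_b,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_a") <- n_a
  attr(out, "n_b") <- n_b
  out
}

# Newton inversion of the trigamma function (solve trigamma(x) = y).
trigamma_inverse <- function(y, tol = 1e-8, maxit = 50L) {
  if (y <= 0) stop("trigamma_inverse needs y > 0")
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in seq_len(maxit)) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif) < tol * x) break
  }
  x
}

# Method-of-moments fit of the scaled-F model for sample variances:
# s2_g ~ s0^2 * F(d_g, d0). Works on log s2 via digamma/trigamma moments.
fit_variance_prior <- function(s2, df_resid) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 10)
    stop("prior estimation needs at least 10 features with positive ",
         "residual variance; got ", sum(ok))
  z <- log(s2[ok])
  d <- df_resid[ok]
  e <- z - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  evar <- stats::var(e) - mean(trigamma(d / 2))
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- exp(emean)
  }
  list(d0 = d0, s0_sq = s0_sq)
}

#' Empirical-Bayes moderation of per-feature variances
#'
#' Shrinks each feature's residual variance toward a prior variance
#' `s0_sq` estimated, together with its prior degrees of freedom `d0`, by a
#' method-of-moments fit of a scaled-F model to the log residual variances
#' (digamma/trigamma moment equations, trigamma inverted by Newton
#' iteration). The moderated t statistic is the log fold change divided by
#' the shrunken standard error and is referred to a t distribution with
#' `d0 + df_resid` degrees of freedom (standard normal in the unbounded-
#' `d0` limit).
#'
#' @param fit Output of [fit_two_group()].
#' @param d0 Optional override of the prior degrees of freedom: `0` gives
#'   the ordinary pooled two-sample t, `Inf` full shrinkage to `s0_sq`.
#' @return List with `prior` (list `d0`, `s0_sq`) and `table`: data frame
#'   `feature`, `log_fc`, `s2`, `t_mod`, `df_total`, `p_raw`.
#' @export
ebayes_moderate <- function(fit, d0 = NULL) {
  stopifnot(is.data.frame(fit),
            all(c("feature", "log_fc", "s2", "df_resid", "v") %in% names(fit)))
  prior <- fit_variance_prior(fit$s2, fit$df_resid)
  if (!is.null(d0)) {
    if (d0 < 0) stop("d0 must be >= 0")
    prior$d0 <- d0
  }
  if (is.finite(prior$d0)) {
    s2_post <- (prior$d0 * prior$s0_sq + fit$df_resid * fit$s2) /
      (prior$d0 + fit$df_resid)
  } else {
    s2_post <- rep(prior$s0_sq, nrow(fit))
  }
  df_total <- prior$d0 + fit$df_resid
  se <- sqrt(s2_post * fit$v)
  t_mod <- fit$log_fc / se
  if (prior$d0 == 0 && any(fit$s2 == 0)) {
    warning(sum(fit$s2 == 0), " zero-variance feature(s) with d0 = 0: ",
            "p set to 0 when log_fc != 0, else 1")
    zero <- fit$s2 == 0
    t_mod[zero] <- ifelse(fit$log_fc[zero] != 0, Inf * sign(fit$log_fc[zero]),
                          0)
  }
  p_raw <- if (is.finite(prior$d0)) {
    2 * stats::pt(-abs(t_mod), df = df_total)
  } else {
    2 * stats::pnorm(-abs(t_mod))
  }
  p_raw[is.nan(t_mod)] <- 1  # 0/0: no change, no evidence
  t_mod[is.nan(t_mod)] <- 0
  table <- data.frame(feature = fit$feature, log_fc = fit$log_fc,
                      s2 = fit$s2, t_mod = t_mod, df_total = df_total,
                      p_raw = p_raw, row.names = NULL,
                      stringsAsFactors = FALSE)
  list(prior = prior, table = table)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment, returned in input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values (same length and order).
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop("p-values must be numeric")
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Full differential-expression analysis for one contrast
#'
#' Runs [fit_two_group()], [ebayes_moderate()] and [bh_adjust()], and
#' labels each feature's direction and DE status.
#'
#' @param x An [expression_matrix()].
#' @param contrast A [make_contrast()] object.
#' @param alpha Adjusted-p threshold defining `is_de` (default 0.05).
#' @param d0 Optional prior-df override, see [ebayes_moderate()].
#' @return A DE table: data frame with columns `feature`, `log_fc`, `s2`,
#'   `t_mod`, `df_total`, `p_raw`, `p_adj`, `direction` (`Up`/`Down`),
#'   `is_de`; the estimated prior is attached as attribute `prior`.
#' @export
run_de <- function(x, contrast, alpha = 0.05, d0 = NULL) {
  fit <- fit_two_group(x, contrast)
  mod <- ebayes_moderate(fit, d0 = d0)
  tab <- mod$table
  tab$p_adj <- bh_adjust(tab$p_raw)
  tab$direction <- ifelse(tab$log_fc > 0, "Up", "Down")
  tab$is_de <- tab$p_adj < alpha
  attr(tab, "prior") <- mod$prior
  attr(tab, "contrast") <- contrast$name
  tab
}

#' Collapse probe-level results to gene level
#'
#' When a gene is measured by several probes, the probe with the most
#' significant variation (smallest raw p in the contrast fit) represents
#' the gene; ties are broken by larger absolute log fold change, then by
#' lexicographic probe id. Probes absent from the map are dropped with a
#' message reporting the count.
#'
#' @param table A DE table keyed by probe (from [run_de()]).
#' @param probe_map Data frame with two columns: probe id, gene id.
#' @return The DE table re-keyed by gene (`feature` = gene id; the winning
#'   probe retained in column `probe`).
#' @export
collapse_probes <- function(table, probe_map) {
  stopifnot(is.data.frame(table), "feature" %in% names(table),
            "p_raw" %in% names(table))
  if (!is.data.frame(probe_map) || ncol(probe_map) < 2 || !nrow(probe_map))
    stop("`probe_map` must be a nonempty data frame (probe id, gene id)")
  map <- stats::setNames(as.character(probe_map[[2]]),
                         as.character(probe_map[[1]]))
  unmapped <- !table$feature %in% names(map)
  if (any(unmapped))
    message(sum(unmapped), " unmapped probe(s) dropped")
  tab <- table[!unmapped, , drop = FALSE]
  if (!nrow(tab)) stop("no probes left after mapping")
  tab$gene <- unname(map[tab$feature])
  ord <- order(tab$gene, tab$p_raw, -abs(tab$log_fc), tab$feature)
  tab <- tab[ord, , drop = FALSE]
  tab <- tab[!duplicated(tab$gene), , drop = FALSE]
  tab$probe <- tab$feature
  tab$feature <- tab$gene
  tab$gene <- NULL
  rownames(tab) <- NULL
  tab
}

#' Select differentially expressed features
#'
#' @param table A DE table with a populated `p_adj` column.
#' @param alpha Strict adjusted-p threshold (default 0.05; features at
#'   exactly `alpha` are excluded).
#' @return Data frame `feature`, `direction` of the selected features.
#' @export
select_de <- function(table, alpha = 0.05) {
  stopifnot(is.data.frame(table), all(c("feature", "p_adj") %in% names(table)))
  keep <- table$p_adj < alpha
  dirs <- if ("direction" %in% names(table)) table$direction
          else rep(NA_character_, nrow(table))
  out <- data.frame(feature = table$feature[keep],
                    direction = dirs[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write a DE table as TSV
#'
#' @param table A DE table from [run_de()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_de_table <- function(table, path) {
  cols <- intersect(c("feature", "log_fc", "t_mod", "p_raw", "p_adj",
                      "direction", "is_de"), names(table))
  utils::write.table(table[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
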