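#' Read a gene-set collection from a GMT file
#'
#' Standard GMT semantics: one set per line, tab-separated fields `name`,
#' `description`, then member gene ids.
#'
#' @param path Path to the GMT file.
#' @return Object of class `gene_set_collection`: named list of character
#'   vectors with a `description` attribute per set.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad))
    stop(sprintf("malformed GMT line %d: need name, description, >= 1 member",
                 bad[1]))
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[`, "", 1)
  gene_set_collection(sets,
                      descriptions = vapply(fields, `[`, "", 2))
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors (nonempty, unique names).
#' @param descriptions Optional character vector of per-set descriptions.
#' @return A `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (!is.list(sets) || is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("`sets` must be a named list")
  if (anyDuplicated(names(sets))) stop("set names must be unique")
  if (any(lengths(sets) == 0)) stop("every set must have >= 1 member")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (!is.null(descriptions)) attr(sets, "descriptions") <-
    stats::setNames(descriptions, names(sets))
  structure(sets, class = "gene_set_collection")
}

#' Over-representation analysis of a target gene list
#'
#' One-sided hypergeometric (Fisher) upper-tail test per gene set: with a
#' universe of `N` genes of which `K` belong to the set, and `n` targets of
#' which `k` overlap the set, the p-value is `P(X >= k)` for
#' hypergeometric `X`. `mode = "ease"` applies the DAVID EASE convention,
#' substituting `max(k - 1, 0)` for `k`, which penalizes single-gene
#' overlaps. Targets outside the universe are dropped with a message.
#'
#' @param targets Character vector of target gene ids.
#' @param collection A [gene_set_collection()].
#' @param universe Character vector: the background gene universe (e.g.
#'   all mRNAs of the reference network).
#' @param mode `"fisher"` (default) or `"ease"`.
#' @param alpha Significance threshold for the top-term report.
#' @return Data frame sorted by raw p: `set`, `size` (set size within the
#'   universe), `overlap`, `p_raw`, `p_adj` (BH), `members_in_overlap`
#'   (comma-joined). The top ten sets with `p_raw < alpha` are attached as
#'   attribute `top_terms`.
#' @export
ora_test <- function(targets, collection, universe,
                     mode = c("fisher", "ease"), alpha = 0.05) {
  mode <- match.arg(mode)
  if (!inherits(collection, "gene_set_collection"))
    collection <- gene_set_collection(collection)
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("`universe` must be nonempty")
  if (!length(collection)) stop("`collection` must be nonempty")
  targets <- unique(as.character(targets))
  outside <- setdiff(targets, universe)
  if (length(outside))
    message(length(outside), " target(s) outside the universe dropped")
  targets <- intersect(targets, universe)
  N <- length(universe)
  n <- length(targets)
  rows <- lapply(names(collection), function(nm) {
    members <- intersect(collection[[nm]], universe)
    K <- length(members)
    hit <- intersect(targets, members)
    k <- length(hit)
    k_test <- if (mode == "ease") max(k - 1L, 0L) else k
    p <- stats::phyper(k_test - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, size = K, overlap = k, p_raw = p,
               members_in_overlap = paste(sort(hit), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p_raw)
  out <- out[order(out$p_raw, out$set),
             c("set", "size", "overlap", "p_raw", "p_adj",
               "members_in_overlap")]
  rownames(out) <- NULL
  attr(out, "top_terms") <- utils::head(out[out$p_raw < alpha, ], 10)
  out
}
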