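#' Construct an expression matrix with sample group labels
#'
#' The basic substrate of all differential-expression computation: a numeric
#' feature-by-sample matrix (log2-scale normalized intensities) together
#' with a group label for every sample.
#'
#' @param values Numeric matrix, features in rows (unique rownames), samples
#'   in columns (unique colnames).
#' @param groups Character or factor vector of group labels, one per sample.
#'   Either named by sample id or in column order. Typical labels are
#'   `"normal"`, `"pPCa"` (primary tumour) and `"mPCa"` (metastatic tumour).
#' @return An object of class `expression_matrix`: a list with elements
#'   `values` (the matrix) and `groups` (named character vector).
#' @export
expression_matrix <- function(values, groups) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("`values` must have unique rownames (feature ids)")
  if (is.null(colnames(values)) || anyDuplicated(colnames(values)))
    stop("`values` must have unique colnames (sample ids)")
  groups <- as.character(stats::setNames(groups, names(groups)))
  if (is.null(names(groups))) {
    if (length(groups) != ncol(values))
      stop("`groups` must have one label per sample")
    names(groups) <- colnames(values)
  }
  missing <- setdiff(colnames(values), names(groups))
  if (length(missing))
    stop("samples without a group label: ", paste(missing, collapse = ", "))
  groups <- groups[colnames(values)]
  structure(list(values = values, groups = groups),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d features x %d samples\n",
              nrow(x$values), ncol(x$values)))
  tab <- table(x$groups)
  cat("groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Read an expression matrix and its sample annotation from TSV
#'
#' The matrix file has a header row of sample ids and a first column of
#' feature ids; the annotation file has two columns, sample id and group.
#'
#' @param path Path to the expression TSV.
#' @param annotation_path Path to the two-column sample-annotation TSV.
#' @param header Logical; whether the annotation file has a header row.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, annotation_path, header = TRUE) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  values <- as.matrix(tab[, -1, drop = FALSE])
  rownames(values) <- as.character(tab[[1]])
  ann <- utils::read.delim(annotation_path, header = header,
                           stringsAsFactors = FALSE)
  groups <- stats::setNames(as.character(ann[[2]]), as.character(ann[[1]]))
  expression_matrix(values, groups)
}

#' Write an expression matrix and its sample annotation as TSV
#'
#' @param x An [expression_matrix()].
#' @param path Output path for the expression TSV.
#' @param annotation_path Output path for the sample-annotation TSV.
#' @return Invisibly, `x`.
#' @export
write_expression <- function(x, path, annotation_path) {
  stopifnot(inherits(x, "expression_matrix"))
  out <- data.frame(feature = rownames(x$values), x$values,
                    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  ann <- data.frame(sample = names(x$groups), group = unname(x$groups))
  utils::write.table(ann, annotation_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(x)
}

#' Subset an expression matrix to a set of features
#'
#' @param x An [expression_matrix()].
#' @param features Character vector of feature ids to keep (order preserved).
#' @return An [expression_matrix()] restricted to `features`.
#' @export
subset_features <- function(x, features) {
  stopifnot(inherits(x, "expression_matrix"))
  missing <- setdiff(features, rownames(x$values))
  if (length(missing))
    stop("features not in matrix: ", paste(missing, collapse = ", "))
  expression_matrix(x$values[features, , drop = FALSE], x$groups)
}
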