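#' Construct a directed bipartite miRNA-mRNA network
#'
#' Edges run from a miRNA regulator to an mRNA target. Duplicate edges are
#' removed (with a message when any are dropped) and bipartiteness is
#' enforced: no id may appear both as a miRNA and as an mRNA.
#'
#' @param edges Data frame with two character columns (miRNA id, mRNA id);
#'   extra columns are ignored.
#' @param mirna_nodes,mrna_nodes Optional full node sets, allowing isolated
#'   nodes (as in a reference map). Default: inferred from the edges.
#' @return An object of class `bipartite_network`: list with `edges`
#'   (data.frame `mirna`, `mrna`), `mirna_nodes`, `mrna_nodes`.
#' @export
bipartite_network <- function(edges, mirna_nodes = NULL, mrna_nodes = NULL) {
  if (!is.data.frame(edges) || ncol(edges) < 2) {
    if (is.data.frame(edges) && ncol(edges) == 0 && nrow(edges) == 0) {
      edges <- data.frame(mirna = character(0), mrna = character(0))
    } else {
      stop("`edges` must be a data frame with at least two columns")
    }
  }
  edges <- data.frame(mirna = as.character(edges[[1]]),
                      mrna = as.character(edges[[2]]),
                      stringsAsFactors = FALSE)
  dup <- duplicated(paste(edges$mirna, edges$mrna, sep = "\r"))
  if (any(dup)) {
    message(sum(dup), " duplicate edge(s) removed")
    edges <- edges[!dup, , drop = FALSE]
    rownames(edges) <- NULL
  }
  mirna_nodes <- sort(unique(c(edges$mirna, mirna_nodes)))
  mrna_nodes <- sort(unique(c(edges$mrna, mrna_nodes)))
  both <- intersect(mirna_nodes, mrna_nodes)
  if (length(both))
    stop("not bipartite: id(s) on both sides: ",
         paste(utils::head(both, 5), collapse = ", "))
  structure(list(edges = edges, mirna_nodes = mirna_nodes,
                 mrna_nodes = mrna_nodes),
            class = "bipartite_network")
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat(sprintf("bipartite_network: %d miRNAs, %d mRNAs, %d edges\n",
              length(x$mirna_nodes), length(x$mrna_nodes), nrow(x$edges)))
  invisible(x)
}

#' Number of edges in a network
#' @param network A [bipartite_network()].
#' @return Integer edge count.
#' @export
n_edges <- function(network) {
  stopifnot(inherits(network, "bipartite_network"))
  nrow(network$edges)
}

#' Read a miRNA-mRNA edge list from a two-column TSV
#'
#' @param path Path to the file, one `miRNA<TAB>mRNA` pair per line.
#' @param header `TRUE`, `FALSE`, or `"auto"` (default): with `"auto"` the
#'   first line is treated as a header when its fields look like column
#'   names (e.g. `mirna`/`mrna`, `source`/`target`).
#' @return A [bipartite_network()]. Duplicate lines are dropped with a
#'   message; a line without exactly two fields is an error naming the
#'   line number.
#' @export
read_edge_list <- function(path, header = "auto") {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(bipartite_network(data.frame(mirna = character(0),
                                        mrna = character(0))))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 2)
  if (length(bad))
    stop(sprintf("malformed line %d: expected 2 tab-separated fields, got %d",
                 bad[1], lengths(fields)[bad[1]]))
  mat <- matrix(unlist(fields), ncol = 2, byrow = TRUE)
  if (identical(header, "auto")) {
    first <- tolower(mat[1, ])
    header <- all(first %in% c("mirna", "mirna_id", "mir", "source",
                               "regulator", "mrna", "mrna_id", "gene",
                               "gene_id", "target"))
  }
  if (isTRUE(header)) mat <- mat[-1, , drop = FALSE]
  bipartite_network(data.frame(mirna = mat[, 1], mrna = mat[, 2],
                               stringsAsFactors = FALSE))
}

#' Write a network as a two-column TSV edge list
#'
#' @param network A [bipartite_network()].
#' @param path Output path.
#' @param header Logical; write a `mirna<TAB>mrna` header line.
#' @return Invisibly, `path`.
#' @export
write_edge_list <- function(network, path, header = FALSE) {
  stopifnot(inherits(network, "bipartite_network"))
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = isTRUE(header))
  invisible(path)
}

#' Extract a condition-specific subnetwork from the reference map
#'
#' Keeps exactly the reference edges whose miRNA is differentially
#' expressed and whose mRNA target is differentially expressed in the same
#' contrast; nodes left without any incident edge are dropped. DE ids
#' absent from the reference map are ignored (a message reports how many).
#'
#' @param reference A [bipartite_network()] reference map.
#' @param de_mirnas Character vector of DE miRNA ids.
#' @param de_mrnas Character vector of DE mRNA ids.
#' @return A [bipartite_network()] with no isolated nodes.
#' @export
extract_condition_network <- function(reference, de_mirnas, de_mrnas) {
  stopifnot(inherits(reference, "bipartite_network"))
  de_mirnas <- unique(as.character(de_mirnas))
  de_mrnas <- unique(as.character(de_mrnas))
  n_unknown <- sum(!de_mirnas %in% reference$mirna_nodes) +
    sum(!de_mrnas %in% reference$mrna_nodes)
  if (n_unknown)
    message(n_unknown, " DE id(s) absent from the reference map ignored")
  keep <- reference$edges$mirna %in% de_mirnas &
    reference$edges$mrna %in% de_mrnas
  edges <- reference$edges[keep, , drop = FALSE]
  rownames(edges) <- NULL
  bipartite_network(edges)
}

#' Convert a network to an igraph object
#'
#' Optional bridge for visualization or GraphML export via
#' `igraph::write_graph()`.
#'
#' @param network A [bipartite_network()].
#' @return An `igraph` directed graph with a logical `type` vertex
#'   attribute (`FALSE` = miRNA, `TRUE` = mRNA).
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "bipartite_network"))
  if (!requireNamespace("igraph", quietly = TRUE))
    stop("the igraph package is required for as_igraph()")
  g <- igraph::graph_from_data_frame(
    network$edges, directed = TRUE,
    vertices = data.frame(
      name = c(network$mirna_nodes, network$mrna_nodes),
      type = rep(c(FALSE, TRUE),
                 c(length(network$mirna_nodes), length(network$mrna_nodes)))))
  g
}
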