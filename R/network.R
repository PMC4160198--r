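#' Build an undirected protein-protein interaction network
#'
#' Constructs the interaction network used to define gene neighborhoods.
#' Self-loops are dropped and duplicate edges collapsed, so the resulting
#' graph is simple and undirected.  An optional per-edge confidence score
#' (STRING-style) is kept as the `score` edge attribute but is not used to
#' weight neighborhoods; an optional `min_score` cutoff discards
#' low-confidence edges before the graph is built.
#'
#' @param edges data frame whose first two columns are gene IDs of the edge
#'   endpoints; an optional third column `score` carries a confidence value.
#' @param nodes character vector of gene IDs to include as vertices even
#'   when isolated (typically the full gene universe).  Endpoints of
#'   `edges` are always included.
#' @param min_score minimum confidence score an edge must reach to be kept;
#'   `NULL` (default) keeps all edges.
#' @return an [igraph::graph] object with vertex name attributes.
#' @examples
#' net <- interaction_network(data.frame(a = c("g1", "g2"), b = c("g2", "g3")))
#' neighbor_set(net, "g2")
#' @export
interaction_network <- function(edges, nodes = NULL, min_score = NULL) {
  if (!is.data.frame(edges) || ncol(edges) < 2) {
    stop_fmt("`edges` must be a data frame with at least two columns")
  }
  a <- as.character(edges[[1]])
  b <- as.character(edges[[2]])
  score <- if (ncol(edges) >= 3) as.numeric(edges[[3]]) else rep(999, length(a))
  if (!is.null(min_score)) {
    keep <- score >= min_score
    a <- a[keep]; b <- b[keep]; score <- score[keep]
  }
  verts <- sort(unique(c(a, b, as.character(nodes %||% character()))))
  g <- igraph::graph_from_data_frame(
    data.frame(from = a, to = b, score = score, stringsAsFactors = FALSE),
    directed = FALSE, vertices = verts
  )
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                   edge.attr.comb = list(score = "max"))
}

#' Direct interaction neighbors of a gene
#'
#' Returns the set of genes sharing an edge with `gene`, excluding `gene`
#' itself.  A gene absent from the network yields an empty set with a
#' warning rather than an error: in real data this signals an ID-mapping
#' gap, not a malformed input.
#'
#' @param network an igraph network from [interaction_network()].
#' @param gene a single gene ID.
#' @return character vector of neighbor gene IDs (sorted).
#' @export
neighbor_set <- function(network, gene) {
  stopifnot(length(gene) == 1)
  if (!gene %in% igraph::V(network)$name) {
    warning(sprintf("gene '%s' is not a network node; returning empty neighbor set",
                    gene), call. = FALSE)
    return(character())
  }
  sort(igraph::neighbors(network, gene)$name)
}

# Sparse 0/1 adjacency over `universe` (rows/cols in that order); network
# nodes outside the universe are dropped from rows but still counted in
# degrees via the full adjacency, handled in encode_genes().
network_adjacency <- function(network, nodes) {
  el <- igraph::as_edgelist(network, names = TRUE)
  i <- match(el[, 1], nodes)
  j <- match(el[, 2], nodes)
  keep <- !is.na(i) & !is.na(j)
  Matrix::sparseMatrix(
    i = c(i[keep], j[keep]), j = c(j[keep], i[keep]), x = 1,
    dims = c(length(nodes), length(nodes)), dimnames = list(nodes, nodes)
  )
}
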