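#' Is-a term DAG
#'
#' Directed acyclic graph of `child -> parent` is-a relations over
#' annotation terms, as used for mapping selected GO terms onto the direct
#' children of each namespace root.
#'
#' @param edges data frame whose first two columns are `child` and
#'   `parent` term IDs (an optional third column names the relation and is
#'   ignored beyond bookkeeping).
#' @return object of class `term_dag`.
#' @export
term_dag <- function(edges) {
  if (!is.data.frame(edges) || ncol(edges) < 2) {
    stop_fmt("`edges` must be a data frame with child and parent columns")
  }
  df <- data.frame(child = as.character(edges[[1]]),
                   parent = as.character(edges[[2]]),
                   stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(df, directed = TRUE)
  if (!igraph::is_dag(g)) stop_fmt("term relations contain a cycle; not a DAG")
  structure(list(edges = df, graph = g), class = "term_dag")
}

#' @export
print.term_dag <- function(x, ...) {
  cat(sprintf("<term_dag> %d terms, %d is-a edges\n",
              igraph::vcount(x$graph), nrow(x$edges)))
  invisible(x)
}

dag_terms <- function(dag) igraph::V(dag$graph)$name

# All terms below `term` (terms from which `term` is reachable via
# child->parent edges), excluding `term` itself.
dag_descendants <- function(dag, term) {
  if (!term %in% dag_terms(dag)) return(character())
  setdiff(names(igraph::subcomponent(dag$graph, term, mode = "in")), term)
}

# All terms above `term`, excluding itself.
dag_ancestors <- function(dag, term) {
  if (!term %in% dag_terms(dag)) return(character())
  setdiff(names(igraph::subcomponent(dag$graph, term, mode = "out")), term)
}
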