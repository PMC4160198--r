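#' Neighborhood enrichment score (-log10 hypergeometric tail)
#'
#' The enrichment score of a gene for an annotation term is the -log10 of
#' the upper-tail hypergeometric probability of observing at least `m`
#' term members among the gene's `n` direct network neighbors, when `M` of
#' the `N` universe genes carry the term:
#' \deqn{P = \sum_{k \ge m} \frac{\binom{M}{k}\binom{N-M}{n-k}}{\binom{N}{n}}}
#' The tail is evaluated in log space (via [stats::phyper()] with
#' `log.p = TRUE`), so extreme overlaps do not underflow to `P = 0`;
#' scores are capped at `cap` (-log10 units) to keep every feature finite
#' while preserving ordering.  All arguments are vectorized and recycled.
#'
#' @param N universe size ("overall proteins").
#' @param M number of universe genes annotated to the term.
#' @param n neighbor-set size of the query gene.
#' @param m overlap between the neighbor set and the term set.
#' @param cap maximum reportable score (default 300).
#' @return numeric vector of non-negative, finite scores; `m = 0` always
#'   scores 0 because the tail probability is 1.
#' @examples
#' enrichment_score(N = 10, M = 4, n = 3, m = 2)   # -log10(1/3)
#' @export
enrichment_score <- function(N, M, n, m, cap = 300) {
  len <- max(length(N), length(M), length(n), length(m))
  N <- rep_len(as.numeric(N), len); M <- rep_len(as.numeric(M), len)
  n <- rep_len(as.numeric(n), len); m <- rep_len(as.numeric(m), len)
  if (any(N < 0)) stop_fmt("invalid EnrichmentContext: N must be >= 0")
  if (any(M > N)) stop_fmt("invalid EnrichmentContext: M exceeds N")
  if (any(n > N)) stop_fmt("invalid EnrichmentContext: n exceeds N")
  if (any(m < 0)) stop_fmt("invalid EnrichmentContext: m is negative")
  if (any(m > pmin(n, M))) stop_fmt("invalid EnrichmentContext: m exceeds min(n, M)")
  logp <- phyper(m - 1, M, N - M, n, lower.tail = FALSE, log.p = TRUE)
  score <- -logp / log(10)
  # phyper returns exactly 0 log-probability when the tail is the whole
  # support (m = 0, or the support forces X >= m); no special-casing needed
  # beyond clamping tiny negative zeros.
  pmin(pmax(score, 0), cap)
}

#' Encode genes as neighborhood-enrichment feature vectors
#'
#' Builds the feature matrix at the heart of the analysis: one row per
#' universe gene, one column per annotation term (GO namespaces first,
#' pathway columns last), each entry the [enrichment_score()] of the
#' gene's direct-neighbor set against the term's member set.  Genes with
#' no neighbors get all-zero rows.  The query gene itself is never part of
#' its own neighborhood.
#'
#' @param network igraph network from [interaction_network()].
#' @param catalogs one [annotation_catalog()] or a list of them.
#' @param universe ordered gene IDs defining rows (default: all network
#'   nodes, sorted); annotated genes must all be contained in it.
#' @param N universe size used in the hypergeometric test; defaults to
#'   `length(universe)`.  Exposed because "overall proteins" is a
#'   convention choice in real data.
#' @param score_cap cap passed to [enrichment_score()].
#' @param propagate if `TRUE`, annotations are propagated up the is-a DAG
#'   (a gene annotated to a term is also counted for every catalog
#'   ancestor of that term) before scoring.  Default `FALSE`: terms are
#'   used exactly as annotated.
#' @param dag a [term_dag()]; required when `propagate = TRUE`.
#' @return numeric matrix (genes x terms) with attributes
#'   `term_namespace` (named character, per column) and `universe_size`.
#' @export
encode_genes <- function(network, catalogs, universe = NULL, N = NULL,
                         score_cap = 300, propagate = FALSE, dag = NULL) {
  catalogs <- canonical_catalogs(catalogs)
  if (propagate) {
    if (is.null(dag)) stop_fmt("`propagate = TRUE` requires a term DAG")
    catalogs <- lapply(catalogs, propagate_annotations, dag = dag)
  }
  net_nodes <- igraph::V(network)$name
  universe <- as.character(universe %||% sort(net_nodes))
  if (anyDuplicated(universe)) stop_fmt("`universe` contains duplicated gene IDs")

  annotated <- unique(unlist(lapply(catalogs, function(cat)
    unlist(cat$term_sets, use.names = FALSE)), use.names = FALSE))
  missing <- setdiff(annotated, universe)
  if (length(missing) > 0) {
    stop_fmt("annotated gene(s) outside the universe: %s%s",
             paste(head(missing, 5), collapse = ", "),
             if (length(missing) > 5) sprintf(" (+%d more)", length(missing) - 5) else "")
  }

  # Work over the union of universe and network nodes so neighbors outside
  # the declared universe still count toward n.
  all_nodes <- union(universe, net_nodes)
  adj <- network_adjacency(network, all_nodes)

  term_ids <- unlist(lapply(catalogs, function(cat) names(cat$term_sets)),
                     use.names = FALSE)
  if (anyDuplicated(term_ids)) stop_fmt("term IDs duplicated across catalogs")
  term_ns <- unlist(lapply(catalogs, function(cat)
    rep(cat$namespace, length(cat$term_sets))), use.names = FALSE)
  names(term_ns) <- term_ids

  memb_i <- integer(0); memb_j <- integer(0); col <- 0L
  for (cat in catalogs) {
    for (genes in cat$term_sets) {
      col <- col + 1L
      memb_i <- c(memb_i, match(genes, all_nodes))
      memb_j <- c(memb_j, rep.int(col, length(genes)))
    }
  }
  memb <- Matrix::sparseMatrix(i = memb_i, j = memb_j, x = 1,
                               dims = c(length(all_nodes), length(term_ids)))

  rows <- match(universe, all_nodes)
  overlap <- as.matrix((adj %*% memb)[rows, , drop = FALSE])
  deg <- Matrix::rowSums(adj)[rows]
  M <- Matrix::colSums(memb)
  Nuniv <- N %||% length(universe)

  nr <- length(universe); nc <- length(term_ids)
  scores <- enrichment_score(
    N = Nuniv,
    M = rep(M, each = nr),
    n = rep.int(deg, nc),
    m = as.vector(overlap),
    cap = score_cap
  )
  out <- matrix(scores, nrow = nr, ncol = nc,
                dimnames = list(universe, term_ids))
  attr(out, "term_namespace") <- term_ns
  attr(out, "universe_size") <- Nuniv
  out
}

# Propagate gene annotations up the is-a DAG: each catalog term's member
# set becomes the union over itself and its catalog descendants.
propagate_annotations <- function(catalog, dag) {
  sets <- catalog$term_sets
  for (id in names(sets)) {
    desc <- intersect(dag_descendants(dag, id), names(catalog$term_sets))
    if (length(desc) > 0) {
      sets[[id]] <- sort(unique(c(sets[[id]],
        unlist(catalog$term_sets[desc], use.names = FALSE))))
    }
  }
  annotation_catalog(catalog$namespace, sets)
}
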