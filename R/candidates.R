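#' Score candidate genes by key-function counts
#'
#' For every negative gene not in the exclusion list, counts how many
#' terms of the total optimal feature set score strictly above
#' `threshold` (default `-log10(0.05)`) in that gene's enrichment
#' vector: genes sharing many "key functions" with the known positives
#' are candidate tumor suppressors.  Oncogene-like genes are excluded
#' before ranking.
#'
#' @param fm feature matrix from [encode_genes()].
#' @param os_terms term IDs of the total optimal feature set; must all be
#'   feature-matrix columns.
#' @param negatives character vector of negative gene IDs to score.
#' @param exclude gene IDs to drop before ranking (e.g. curated
#'   oncogenes); default none.
#' @param threshold key-function score threshold (strict inequality).
#' @return data frame (`rank`, `gene_id`, `key_function_count`) sorted by
#'   decreasing count, ties sharing a dense rank and ordered by gene ID.
#' @export
score_candidates <- function(fm, os_terms, negatives, exclude = character(),
                             threshold = -log10(0.05)) {
  os_terms <- as.character(os_terms)
  if (threshold < 0) stop_fmt("`threshold` must be >= 0")
  unknown <- setdiff(os_terms, colnames(fm))
  if (length(unknown) > 0) {
    stop_fmt("optimal-set term(s) missing from the feature matrix: %s",
             paste(head(unknown, 5), collapse = ", "))
  }
  genes <- setdiff(as.character(negatives), as.character(exclude))
  genes <- genes[genes %in% rownames(fm)]
  if (length(genes) == 0) {
    return(data.frame(rank = integer(0), gene_id = character(0),
                      key_function_count = integer(0)))
  }
  counts <- if (length(os_terms) == 0) {
    stats::setNames(rep(0L, length(genes)), genes)
  } else {
    rowSums(fm[genes, os_terms, drop = FALSE] > threshold)
  }
  ord <- order(-counts, genes)
  counts <- as.integer(counts[ord])
  data.frame(rank = match(counts, unique(counts)),  # dense ranks, ties shared
             gene_id = genes[ord],
             key_function_count = counts,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Summarize selected GO terms by namespace root children
#'
#' Maps each selected term, by ancestor traversal in the is-a DAG, onto
#' every direct child of its namespace root it descends from, and reports
#' per root child the frequency (number of selected descendants) and the
#' ratio frequency / total descendant terms of that child, as a
#' percentage rounded half-up to 2 decimals.  A term under several root
#' children counts once under each.
#'
#' @param selected character vector of selected term IDs.
#' @param dag a [term_dag()].
#' @param namespace_roots term IDs of the namespace roots whose direct
#'   children anchor the summary.
#' @return list with `summary` (data frame `root`, `root_child`,
#'   `frequency`, `total_descendants`, `ratio_percent`) and `unmapped`
#'   (selected terms absent from the DAG or not under any root child).
#' @export
summarize_root_children <- function(selected, dag, namespace_roots) {
  stopifnot(inherits(dag, "term_dag"))
  selected <- unique(as.character(selected))
  known <- dag_terms(dag)
  rows <- list()
  mapped <- character(0)
  for (root in namespace_roots) {
    kids <- sort(dag$edges$child[dag$edges$parent == root])
    for (ch in kids) {
      desc <- dag_descendants(dag, ch)
      hits <- intersect(selected, desc)
      mapped <- union(mapped, hits)
      rows[[length(rows) + 1L]] <- data.frame(
        root = root, root_child = ch,
        frequency = length(hits),
        total_descendants = length(desc),
        ratio_percent = if (length(desc) > 0) {
          round_half_up(100 * length(hits) / length(desc), 2)
        } else 0,
        stringsAsFactors = FALSE
      )
    }
  }
  summary <- if (length(rows) > 0) do.call(rbind, rows) else {
    data.frame(root = character(0), root_child = character(0),
               frequency = integer(0), total_descendants = integer(0),
               ratio_percent = numeric(0))
  }
  list(summary = summary, unmapped = setdiff(selected, mapped))
}
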