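#' Annotation catalog: term -> gene-set map within one namespace
#'
#' A catalog groups the gene sets of one annotation namespace: the three
#' Gene Ontology domains (`"BP"`, `"CC"`, `"MF"`) or `"pathway"` for
#' KEGG-style pathway sets.  Term IDs must be unique and every set
#' non-empty; members are stored sorted so identical catalogs compare (and
#' serialize) identically.
#'
#' @param namespace one of `"BP"`, `"CC"`, `"MF"`, `"pathway"`.
#' @param term_sets named list of character vectors; names are term IDs.
#' @return an object of class `annotation_catalog`.
#' @export
annotation_catalog <- function(namespace, term_sets) {
  namespace <- match.arg(namespace, c("BP", "CC", "MF", "pathway"))
  if (length(term_sets) == 0) stop_fmt("catalog '%s' has no terms", namespace)
  if (is.null(names(term_sets)) || anyDuplicated(names(term_sets))) {
    stop_fmt("term IDs must be unique and named in catalog '%s'", namespace)
  }
  sizes <- lengths(term_sets)
  if (any(sizes == 0)) {
    stop_fmt("empty term set(s) in catalog '%s': %s", namespace,
             paste(names(term_sets)[sizes == 0], collapse = ", "))
  }
  term_sets <- lapply(term_sets, function(g) sort(unique(as.character(g))))
  structure(list(namespace = namespace, term_sets = term_sets),
            class = "annotation_catalog")
}

#' @export
print.annotation_catalog <- function(x, ...) {
  cat(sprintf("<annotation_catalog> namespace=%s terms=%d genes=%d\n",
              x$namespace, length(x$term_sets),
              length(unique(unlist(x$term_sets, use.names = FALSE)))))
  invisible(x)
}

# Restrict a catalog to a gene universe, dropping members outside it and
# any term left empty (real-mode annotations routinely cover genes the
# network does not).
restrict_catalog <- function(catalog, genes) {
  sets <- lapply(catalog$term_sets, intersect, genes)
  sets <- sets[lengths(sets) > 0]
  if (length(sets) == 0) {
    stop_fmt("no term of catalog '%s' overlaps the gene universe",
             catalog$namespace)
  }
  annotation_catalog(catalog$namespace, sets)
}

# Normalize a single catalog or list of catalogs to the canonical column
# order: GO namespaces (BP, CC, MF) first, pathways last.
canonical_catalogs <- function(catalogs) {
  if (inherits(catalogs, "annotation_catalog")) catalogs <- list(catalogs)
  if (length(catalogs) == 0) stop_fmt("at least one annotation catalog is required")
  ok <- vapply(catalogs, inherits, logical(1), "annotation_catalog")
  if (!all(ok)) stop_fmt("`catalogs` must be annotation_catalog objects")
  ns <- vapply(catalogs, function(x) x$namespace, character(1))
  catalogs[order(match(ns, c("BP", "CC", "MF", "pathway")))]
}
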