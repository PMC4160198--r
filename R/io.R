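# Readers and writers for the plain-text interchange formats:
#   edge list TSV  gene_a<TAB>gene_b<TAB>score   (score optional, default 999)
#   GMT            term_id<TAB>description<TAB>gene1<TAB>...
#   DAG TSV        child_term<TAB>parent_term<TAB>is_a
#   gene lists     one ID per line, '#' comments ignored
# All writers emit sorted, canonical output so identical objects produce
# byte-identical files.

#' Read a STRING-dialect edge list
#'
#' @param path TSV file with columns `gene_a`, `gene_b` and optionally
#'   `score`; a header line is detected and skipped if present.
#' @return data frame with columns `gene_a`, `gene_b`, `score`.
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop_fmt("edge list not found: %s", path)
  dt <- data.table::fread(path, header = "auto", sep = "\t",
                          colClasses = list(character = 1:2))
  if (ncol(dt) < 2) stop_fmt("malformed edge list (need >= 2 columns): %s", path)
  out <- data.frame(gene_a = as.character(dt[[1]]),
                    gene_b = as.character(dt[[2]]),
                    score = if (ncol(dt) >= 3) as.numeric(dt[[3]]) else 999,
                    stringsAsFactors = FALSE)
  out
}

write_edge_list <- function(edges, path) {
  ord <- order(edges$gene_a, edges$gene_b)
  write_tsv(edges[ord, c("gene_a", "gene_b", "score"), drop = FALSE], path)
}

#' Read a GMT gene-set file into an annotation catalog
#'
#' Parsing is delegated to [fgsea::gmtPathways()]; the description column
#' is dropped.
#'
#' @param path GMT file.
#' @param namespace catalog namespace, see [annotation_catalog()].
#' @return an `annotation_catalog`.
#' @export
read_gmt <- function(path, namespace) {
  if (!file.exists(path)) stop_fmt("GMT file not found: %s", path)
  sets <- fgsea::gmtPathways(path)
  annotation_catalog(namespace, sets)
}

write_gmt <- function(catalog, path) {
  ids <- sort(names(catalog$term_sets))
  lines <- vapply(ids, function(id) {
    paste(c(id, catalog$namespace, catalog$term_sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
}

#' Read an is-a DAG edge table
#'
#' @param path TSV with columns `child`, `parent`, `relation`.
#' @return a [term_dag()].
#' @export
read_term_dag <- function(path) {
  if (!file.exists(path)) stop_fmt("DAG file not found: %s", path)
  dt <- data.table::fread(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  term_dag(as.data.frame(dt))
}

write_term_dag <- function(dag, path) {
  df <- dag$edges
  df$relation <- "is_a"
  write_tsv(df[order(df$child, df$parent), , drop = FALSE], path)
}

#' Read a gene list (one ID per line)
#'
#' Blank lines and `#` comments are ignored.
#'
#' @param path text file.
#' @return character vector of gene IDs.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop_fmt("gene list not found: %s", path)
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}

write_gene_list <- function(genes, path) {
  writeLines(sort(unique(as.character(genes))), path)
}

#' Write a feature matrix as gzipped TSV plus JSON sidecar
#'
#' The TSV carries a header row of term IDs and a leading `gene_id`
#' column; the sidecar records the universe size used as `N` and the
#' column order with namespaces, so a matrix can be reconstructed
#' faithfully.
#'
#' @param fm matrix from [encode_genes()].
#' @param path output path; `.gz` is appended if absent and the sidecar is
#'   written next to it as `<path>.json`.
#' @return invisibly, the paths written.
#' @export
write_feature_matrix <- function(fm, path) {
  if (!grepl("\\.gz$", path)) path <- paste0(path, ".gz")
  con <- gzfile(path, "wb")
  on.exit(close(con), add = TRUE)
  df <- data.frame(gene_id = rownames(fm), fm, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- sub("\\.gz$", ".json", path)
  jsonlite::write_json(list(
    universe_size = attr(fm, "universe_size"),
    columns = colnames(fm),
    term_namespace = as.list(attr(fm, "term_namespace"))
  ), sidecar, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(path, sidecar))
}

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' @param path the `.gz` TSV path.
#' @return numeric matrix with `term_namespace` and `universe_size`
#'   attributes restored from the sidecar.
#' @export
read_feature_matrix <- function(path) {
  if (!file.exists(path)) stop_fmt("feature matrix not found: %s", path)
  df <- utils::read.delim(gzfile(path), header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  fm <- as.matrix(df[, -1, drop = FALSE])
  rownames(fm) <- as.character(df[[1]])
  sidecar <- sub("\\.gz$", ".json", path)
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    fm <- fm[, meta$columns, drop = FALSE]
    attr(fm, "universe_size") <- meta$universe_size
    attr(fm, "term_namespace") <- unlist(meta$term_namespace)
  }
  fm
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
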