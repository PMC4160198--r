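#' Pipeline run configuration
#'
#' One config drives the whole analysis: simulate (or load) the inputs,
#' encode genes, partition negatives, filter and rank features, run IFS
#' per dataset, take the union, and rank candidates.  Exactly one of
#' `generator` (synthetic mode) or `input_dir`/file paths (real mode)
#' must be supplied.
#'
#' @param out_dir run directory; all artifacts are written under it.
#' @param generator a [generator_config()] for synthetic mode.
#' @param network_file,positives_file real-mode input paths (edge-list
#'   TSV and positive gene list).
#' @param gmt_files named character vector of GMT paths, names in
#'   `BP`/`CC`/`MF`/`pathway`.
#' @param dag_file optional is-a DAG TSV.
#' @param exclusions_file optional exclusion gene list.
#' @param k_datasets number of near-equal negative subsets (default 6);
#'   ignored when `partition_sizes` is given.
#' @param partition_sizes explicit negative-subset sizes.
#' @param cramer_threshold Stage-I Cramer's V cutoff, default 0.1.
#' @param binarize_threshold score binarization threshold for the
#'   Cramer filter, default `-log10(0.05)`.
#' @param cap maximum ranked-list length, default 500.
#' @param cv_folds cross-validation folds, default 10.
#' @param dagging_k dagging base-model count, default 10.
#' @param key_function_threshold candidate-scoring threshold, default
#'   `-log10(0.05)`.
#' @param min_edge_score optional edge-confidence cutoff (real mode).
#' @param propagate_annotations propagate annotations up the DAG before
#'   encoding, default `FALSE`.
#' @param seed global seed, fanned out to per-stage sub-seeds.
#' @return validated `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            generator = NULL,
                            network_file = NULL, gmt_files = NULL,
                            dag_file = NULL, positives_file = NULL,
                            exclusions_file = NULL,
                            k_datasets = 6, partition_sizes = NULL,
                            cramer_threshold = 0.1,
                            binarize_threshold = -log10(0.05),
                            cap = 500, cv_folds = 10, dagging_k = 10,
                            key_function_threshold = -log10(0.05),
                            min_edge_score = NULL,
                            propagate_annotations = FALSE,
                            seed = 1) {
  synthetic <- !is.null(generator)
  real <- !is.null(network_file) || !is.null(positives_file)
  if (synthetic == real) {
    stop_fmt("exactly one of `generator` (synthetic mode) and real-mode input files must be given")
  }
  if (synthetic) stopifnot(inherits(generator, "generator_config"))
  if (cramer_threshold < 0 || cramer_threshold > 1) {
    stop_fmt("cramer_threshold must be in [0, 1]")
  }
  if (cap < 1) stop_fmt("cap must be >= 1")
  if (cv_folds < 2) stop_fmt("cv_folds must be >= 2")
  if (dagging_k < 1) stop_fmt("dagging_k must be >= 1")
  structure(list(out_dir = out_dir, mode = if (synthetic) "synthetic" else "real",
                 generator = generator, network_file = network_file,
                 gmt_files = gmt_files, dag_file = dag_file,
                 positives_file = positives_file,
                 exclusions_file = exclusions_file,
                 k_datasets = as.integer(k_datasets),
                 partition_sizes = partition_sizes,
                 cramer_threshold = cramer_threshold,
                 binarize_threshold = binarize_threshold,
                 cap = as.integer(cap), cv_folds = as.integer(cv_folds),
                 dagging_k = as.integer(dagging_k),
                 key_function_threshold = key_function_threshold,
                 min_edge_score = min_edge_score,
                 propagate_annotations = isTRUE(propagate_annotations),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline config from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; a `generator`
#' mapping is passed to [generator_config()].
#'
#' @param path YAML file.
#' @param out_dir overrides the YAML `out_dir` when given.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$generator)) {
    gen <- y$generator
    if (!is.null(gen$n_terms_per_namespace)) {
      gen$n_terms_per_namespace <- unlist(gen$n_terms_per_namespace)
    }
    if (!is.null(gen$term_size_range)) {
      gen$term_size_range <- unlist(gen$term_size_range)
    }
    y$generator <- do.call(generator_config, gen)
  }
  if (!is.null(y$gmt_files)) y$gmt_files <- unlist(y$gmt_files)
  if (!is.null(out_dir)) y$out_dir <- out_dir
  do.call(pipeline_config, y)
}

#' Run the full analysis pipeline
#'
#' Executes simulate/load -> encode -> partition -> Cramer filter ->
#' MaxRel/mRMR ranking -> IFS -> total optimal set -> candidate ranking,
#' writing every stage artifact plus a machine-readable JSON manifest
#' under `config$out_dir`.  All randomness derives from `config$seed`,
#' so a rerun with the same config reproduces byte-identical outputs.
#' Any stage failure aborts with the stage name; the manifest then
#' records the failed stage and flags the partial outputs as stale.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  manifest <- list(tool = "tsgrank",
                   version = as.character(utils::packageVersion("tsgrank")),
                   mode = config$mode, seed = config$seed,
                   parameters = config[c("k_datasets", "cramer_threshold",
                                         "binarize_threshold", "cap",
                                         "cv_folds", "dagging_k",
                                         "key_function_threshold")],
                   stages = list(), status = "running")
  stage <- "init"
  log_msg <- function(...) message(sprintf("[tsgrank] %s", sprintf(...)))

  result <- tryCatch({
    # ---- inputs -----------------------------------------------------------
    stage <- "inputs"
    if (config$mode == "synthetic") {
      log_msg("generating synthetic world (seed %d)", config$generator$seed)
      world <- generate_world(config$generator)
      write_world(world, file.path(out, "world"))
      network <- world$network
      catalogs <- world$catalogs
      dag <- world$dag
      universe <- world$universe
      positives <- world$positives
      exclusions <- world$exclusions
    } else {
      for (f in c(config$network_file, config$positives_file)) {
        if (!file.exists(f)) stop_fmt("input file not found: %s", f)
      }
      edges <- read_edge_list(config$network_file)
      positives <- read_gene_list(config$positives_file)
      catalogs <- lapply(names(config$gmt_files), function(ns)
        read_gmt(config$gmt_files[[ns]], ns))
      dag <- if (!is.null(config$dag_file)) read_term_dag(config$dag_file) else NULL
      exclusions <- if (!is.null(config$exclusions_file)) {
        read_gene_list(config$exclusions_file)
      } else character(0)
      network <- interaction_network(edges, min_score = config$min_edge_score)
      universe <- sort(igraph::V(network)$name)
      catalogs <- lapply(catalogs, restrict_catalog, genes = universe)
      positives <- intersect(positives, universe)
      world <- NULL
    }
    negatives <- setdiff(universe, positives)
    manifest$stages$inputs <- list(
      n_genes = length(universe), n_positives = length(positives),
      n_negatives = length(negatives), n_edges = igraph::ecount(network),
      n_terms = sum(vapply(catalogs, function(cat) length(cat$term_sets), 1L)),
      n_exclusions = length(exclusions))
    log_msg("universe: %d genes (%d positive), %d edges",
            length(universe), length(positives), igraph::ecount(network))

    # ---- encoding ---------------------------------------------------------
    stage <- "encode"
    fm <- encode_genes(network, catalogs, universe = universe,
                       propagate = config$propagate_annotations,
                       dag = if (config$propagate_annotations) dag else NULL)
    write_feature_matrix(fm, file.path(out, "feature_matrix.tsv"))
    manifest$stages$encode <- list(rows = nrow(fm), columns = ncol(fm))
    log_msg("feature matrix: %d x %d", nrow(fm), ncol(fm))

    # ---- partition --------------------------------------------------------
    stage <- "partition"
    subsets <- partition_negatives(negatives, sizes = config$partition_sizes,
                                   k = if (is.null(config$partition_sizes))
                                     config$k_datasets else NULL,
                                   seed = derive_seed(config$seed, 1))
    datasets <- assemble_datasets(fm, positives, subsets)
    for (d in datasets) {
      write_tsv(data.frame(gene_id = rownames(d$x), label = d$y),
                file.path(out, sprintf("dataset_%s.tsv", d$name)))
    }
    manifest$stages$partition <- list(
      n_datasets = length(datasets),
      subset_sizes = lengths(subsets))

    # ---- selection + IFS per dataset --------------------------------------
    stage <- "feature_selection"
    per_dataset <- list()
    ifs_results <- list()
    for (di in seq_along(datasets)) {
      d <- datasets[[di]]
      retained <- cramer_filter(d, threshold = config$cramer_threshold,
                                binarize_threshold = config$binarize_threshold)
      log_msg("%s: %d/%d features pass the Cramer filter",
              d$name, length(retained), ncol(d$x))
      rec <- list(dataset = d$name, n_samples = nrow(d$x),
                  n_retained = length(retained))
      if (length(retained) == 0) {
        rec$n_optimal <- 0L
        rec$max_mcc <- 0
        per_dataset[[d$name]] <- rec
        next
      }
      maxrel <- maxrel_rank(d, retained, cap = config$cap)
      mrmr <- mrmr_rank(d, retained, cap = config$cap)
      write_tsv(maxrel, file.path(out, sprintf("maxrel_%s.tsv", d$name)))
      write_tsv(mrmr, file.path(out, sprintf("mrmr_%s.tsv", d$name)))
      fit <- ifs(d, mrmr, folds = config$cv_folds,
                 seed = derive_seed(config$seed, 100 + di),
                 dagging_k = config$dagging_k)
      write_tsv(fit$curve[, c("n_features", "SN", "SP", "ACC", "MCC")],
                file.path(out, sprintf("ifs_curve_%s.tsv", d$name)))
      ifs_results[[d$name]] <- fit
      rec$n_ranked <- nrow(mrmr)
      rec$n_optimal <- fit$optimal$n_features
      rec$max_mcc <- fit$optimal$mcc
      log_msg("%s: optimal %d features, MCC %.4f", d$name,
              rec$n_optimal, rec$max_mcc)
      per_dataset[[d$name]] <- rec
    }
    manifest$stages$datasets <- per_dataset
    manifest$stages$mean_max_mcc <- if (length(per_dataset) > 0) {
      mean(vapply(per_dataset, `[[`, numeric(1), "max_mcc"))
    } else 0

    # ---- union ------------------------------------------------------------
    stage <- "total_optimal_set"
    if (length(ifs_results) > 0) {
      os <- total_optimal_set(ifs_results)
      os_terms <- os$term
      write_tsv(os, file.path(out, "total_optimal_set.tsv"))
    } else {
      os_terms <- character(0)
      write_tsv(data.frame(term = character(0), n_datasets = integer(0),
                           datasets = character(0)),
                file.path(out, "total_optimal_set.tsv"))
    }
    ns_attr <- attr(fm, "term_namespace")
    manifest$stages$total_optimal_set <- list(
      n_terms = length(os_terms),
      n_go = sum(ns_attr[os_terms] != "pathway"),
      n_pathway = sum(ns_attr[os_terms] == "pathway"))
    log_msg("total optimal set: %d terms", length(os_terms))

    # ---- candidates -------------------------------------------------------
    stage <- "candidates"
    cand <- score_candidates(fm, os_terms, negatives, exclude = exclusions,
                             threshold = config$key_function_threshold)
    write_tsv(cand, file.path(out, "candidates.tsv"))
    manifest$stages$candidates <- list(
      n_scored = nrow(cand),
      top_gene = if (nrow(cand) > 0) cand$gene_id[1] else NA,
      top_count = if (nrow(cand) > 0) cand$key_function_count[1] else 0)

    # ---- DAG summary ------------------------------------------------------
    stage <- "root_children"
    if (!is.null(dag)) {
      roots <- intersect(sprintf("%s:ROOT", c("BP", "CC", "MF")), dag_terms(dag))
      if (length(roots) > 0) {
        rc <- summarize_root_children(os_terms, dag, roots)
        write_tsv(rc$summary, file.path(out, "root_children_summary.tsv"))
        manifest$stages$root_children <- list(
          n_children = nrow(rc$summary), n_unmapped = length(rc$unmapped))
      }
    }

    manifest$status <- "ok"
    manifest$truth <- if (!is.null(world)) world$truth else NULL
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
    log_msg("done: %s", out)
    invisible(manifest)
  }, error = function(e) {
    manifest$status <- "failed"
    manifest$failed_stage <- stage
    manifest$error <- conditionMessage(e)
    manifest$stale_outputs <- list.files(out, recursive = TRUE)
    try(jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                             auto_unbox = TRUE, pretty = TRUE, digits = NA,
                             null = "null"), silent = TRUE)
    stop_fmt("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  })
  result
}
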