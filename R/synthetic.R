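#' Configuration for the synthetic-world generator
#'
#' The generator emulates the statistical structure the analysis assumes:
#' a sparse undirected gene network, term-to-gene annotations in four
#' namespaces, a shallow is-a DAG, a minority positive class, and a
#' planted subset of "causal" terms whose member genes are preferentially
#' wired to positives so that their neighborhood enrichment separates the
#' classes.  Defaults are sized so the full pipeline runs in minutes on
#' one CPU (1,000 genes, 150 positives, 340 terms).
#'
#' @param n_genes number of genes in the universe.
#' @param n_positives number of positive (tumor-suppressor-like) genes;
#'   must be `< n_genes`.
#' @param n_terms_per_namespace named counts for the `BP`, `CC`, `MF` and
#'   `pathway` namespaces.
#' @param n_causal_terms number of planted causal terms (sampled across
#'   namespaces).
#' @param causal_terms_per_gene number of causal terms assigned to each
#'   positive gene (capped at `n_causal_terms`); heterogeneous assignment
#'   mimics pathway diversity among true positives.
#' @param term_size_range integer interval of term-set sizes.
#' @param background_edge_prob Erdos-Renyi background edge probability.
#' @param causal_wiring_prob probability that a positive gene gains an
#'   edge to each member of each of its assigned causal terms, on top of
#'   the background graph.  `0` produces a signal-free null world.
#' @param n_exclusions number of negative genes flagged as
#'   oncogene-like exclusions (exercises the candidate-ranking exclusion
#'   step; may be 0).
#' @param seed integer seed; all randomness flows from it.
#' @return a validated `generator_config` list.
#' @export
generator_config <- function(n_genes = 1000,
                             n_positives = 150,
                             n_terms_per_namespace = c(BP = 150, CC = 60,
                                                       MF = 80, pathway = 50),
                             n_causal_terms = 12,
                             causal_terms_per_gene = 4,
                             term_size_range = c(10, 40),
                             background_edge_prob = 0.01,
                             causal_wiring_prob = 0.5,
                             n_exclusions = 20,
                             seed = 1) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_positives = as.integer(n_positives),
              n_terms_per_namespace = n_terms_per_namespace,
              n_causal_terms = as.integer(n_causal_terms),
              causal_terms_per_gene = as.integer(causal_terms_per_gene),
              term_size_range = as.integer(term_size_range),
              background_edge_prob = background_edge_prob,
              causal_wiring_prob = causal_wiring_prob,
              n_exclusions = as.integer(n_exclusions),
              seed = as.integer(seed))
  ns <- c("BP", "CC", "MF", "pathway")
  if (!all(ns %in% names(cfg$n_terms_per_namespace))) {
    stop_fmt("n_terms_per_namespace must name all of: %s", paste(ns, collapse = ", "))
  }
  cfg$n_terms_per_namespace <- cfg$n_terms_per_namespace[ns]
  if (cfg$n_positives >= cfg$n_genes) stop_fmt("n_positives must be < n_genes")
  if (cfg$n_causal_terms > sum(cfg$n_terms_per_namespace)) {
    stop_fmt("n_causal_terms exceeds the total number of terms")
  }
  for (p in c("background_edge_prob", "causal_wiring_prob")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop_fmt("%s must be in [0, 1]", p)
  }
  if (length(cfg$term_size_range) != 2 || any(cfg$term_size_range < 1) ||
      cfg$term_size_range[1] > cfg$term_size_range[2]) {
    stop_fmt("term_size_range must be an increasing interval of sizes >= 1")
  }
  if (cfg$term_size_range[2] > cfg$n_genes) {
    stop_fmt("term_size_range exceeds n_genes (%d > %d)",
             cfg$term_size_range[2], cfg$n_genes)
  }
  if (cfg$causal_terms_per_gene < 1) stop_fmt("causal_terms_per_gene must be >= 1")
  structure(cfg, class = "generator_config")
}

#' Generate a synthetic world
#'
#' Draws an Erdos-Renyi background graph over the gene universe, samples
#' term memberships uniformly, plants `n_causal_terms` causal terms, and
#' wires each positive gene to each member of each of its assigned causal
#' terms with probability `causal_wiring_prob` (self-loops never
#' generated, duplicate edges collapsed).  With positive wiring
#' probability, positive genes' neighborhoods are therefore enriched for
#' causal-term members in expectation.  Fully reproducible from the
#' config seed.
#'
#' @param config a [generator_config()].
#' @return object of class `synthetic_world` with elements `universe`,
#'   `network`, `catalogs`, `dag`, `positives`, `exclusions`, `truth`
#'   (planted causal term IDs) and `config`.
#' @export
generate_world <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_local_seed(config$seed, {
    n <- config$n_genes
    universe <- sprintf("g%05d", seq_len(n))

    # Background Erdos-Renyi edges over unordered pairs (i < j).
    pairs <- which(upper.tri(matrix(FALSE, n, n)), arr.ind = TRUE)
    sel <- runif(nrow(pairs)) < config$background_edge_prob
    bg <- pairs[sel, , drop = FALSE]

    # Annotation catalogs: uniform member sampling per term.
    catalogs <- list()
    for (ns in names(config$n_terms_per_namespace)) {
      k <- config$n_terms_per_namespace[[ns]]
      if (k == 0) next
      lo <- config$term_size_range[1]; hi <- config$term_size_range[2]
      sets <- lapply(seq_len(k), function(j) {
        size <- lo + sample.int(hi - lo + 1L, 1L) - 1L
        sample(universe, size)
      })
      names(sets) <- sprintf("%s:T%04d", ns, seq_len(k))
      catalogs[[ns]] <- annotation_catalog(ns, sets)
    }

    all_terms <- unlist(lapply(catalogs, function(cat) names(cat$term_sets)),
                        use.names = FALSE)
    positives <- sort(sample(universe, config$n_positives))
    truth <- sort(sample(all_terms, config$n_causal_terms))

    term_members <- unlist(lapply(catalogs, function(cat) cat$term_sets),
                           recursive = FALSE, use.names = TRUE)
    names(term_members) <- sub("^[^.]*\\.", "", names(term_members))

    # Preferential wiring of positives into their assigned causal terms.
    extra_a <- character(0); extra_b <- character(0)
    k_assign <- min(config$causal_terms_per_gene, config$n_causal_terms)
    if (config$n_causal_terms > 0 && config$causal_wiring_prob > 0) {
      for (p in positives) {
        assigned <- sample(truth, k_assign)
        for (t in assigned) {
          members <- setdiff(term_members[[t]], p)
          hit <- members[runif(length(members)) < config$causal_wiring_prob]
          extra_a <- c(extra_a, rep.int(p, length(hit)))
          extra_b <- c(extra_b, hit)
        }
      }
    } else if (config$n_causal_terms > 0) {
      # Keep the RNG stream aligned between null and signal worlds so that
      # the background graph and labels are directly comparable.
      for (p in positives) {
        assigned <- sample(truth, k_assign)
        for (t in assigned) {
          members <- setdiff(term_members[[t]], p)
          invisible(runif(length(members)))
        }
      }
    }

    edges <- data.frame(
      gene_a = c(universe[bg[, 1]], extra_a),
      gene_b = c(universe[bg[, 2]], extra_b),
      score = 999,
      stringsAsFactors = FALSE
    )
    network <- interaction_network(edges, nodes = universe)

    dag <- build_synthetic_dag(catalogs)

    negatives <- setdiff(universe, positives)
    exclusions <- if (config$n_exclusions > 0) {
      sort(sample(negatives, min(config$n_exclusions, length(negatives))))
    } else character(0)

    structure(list(universe = universe, network = network,
                   catalogs = catalogs, dag = dag,
                   positives = positives, exclusions = exclusions,
                   truth = truth, config = config),
              class = "synthetic_world")
  })
}

# Shallow three-level is-a DAG per GO namespace: catalog terms -> root
# children -> namespace root.  A term attaches to one child, or to two
# with probability 0.2 (GO terms may descend from several root children).
# Pathway sets are flat in KEGG and get no DAG.
build_synthetic_dag <- function(catalogs, n_children = 6) {
  child <- character(0); parent <- character(0)
  for (ns in intersect(c("BP", "CC", "MF"), names(catalogs))) {
    root <- sprintf("%s:ROOT", ns)
    kids <- sprintf("%s:C%02d", ns, seq_len(n_children))
    child <- c(child, kids); parent <- c(parent, rep(root, n_children))
    for (id in names(catalogs[[ns]]$term_sets)) {
      k <- if (runif(1) < 0.2) 2 else 1
      for (ch in sample(kids, k)) {
        child <- c(child, id); parent <- c(parent, ch)
      }
    }
  }
  term_dag(data.frame(child = child, parent = parent,
                      stringsAsFactors = FALSE))
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_world> %d genes (%d positives), %d edges, ",
                     "%d terms, %d planted causal terms\n"),
              length(x$universe), length(x$positives),
              igraph::ecount(x$network),
              sum(vapply(x$catalogs, function(cat) length(cat$term_sets), 1L)),
              length(x$truth)))
  invisible(x)
}

#' Write a synthetic world to a directory of plain-text files
#'
#' Emits `network.tsv` (edge list), one GMT per namespace (`bp.gmt`,
#' `cc.gmt`, `mf.gmt`, `pathway.gmt`), `dag.tsv`, `universe.txt`,
#' `positives.txt`, `exclusions.txt` (written even when empty) and
#' `causal_terms.txt`.  Output is canonical: identical worlds produce
#' byte-identical files.
#'
#' @param world a `synthetic_world`.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of paths written.
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "synthetic_world"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (file.access(dir, 2) != 0) stop_fmt("directory not writable: %s", dir)
  paths <- c(network = file.path(dir, "network.tsv"),
             dag = file.path(dir, "dag.tsv"),
             universe = file.path(dir, "universe.txt"),
             positives = file.path(dir, "positives.txt"),
             exclusions = file.path(dir, "exclusions.txt"),
             truth = file.path(dir, "causal_terms.txt"))
  el <- igraph::as_data_frame(world$network, what = "edges")
  swap <- el$from > el$to
  edges <- data.frame(gene_a = ifelse(swap, el$to, el$from),
                      gene_b = ifelse(swap, el$from, el$to),
                      score = el$score, stringsAsFactors = FALSE)
  write_edge_list(edges, paths[["network"]])
  write_term_dag(world$dag, paths[["dag"]])
  write_gene_list(world$universe, paths[["universe"]])
  write_gene_list(world$positives, paths[["positives"]])
  write_gene_list(world$exclusions, paths[["exclusions"]])
  writeLines(sort(world$truth), paths[["truth"]])
  for (ns in names(world$catalogs)) {
    p <- file.path(dir, paste0(tolower(ns), ".gmt"))
    write_gmt(world$catalogs[[ns]], p)
    paths[[paste0("gmt_", ns)]] <- p
  }
  invisible(paths)
}

#' Read a world previously written by [write_world()]
#'
#' @param dir directory holding the world files.
#' @return a `synthetic_world` (without the generating config).
#' @export
read_world <- function(dir) {
  universe <- read_gene_list(file.path(dir, "universe.txt"))
  edges <- read_edge_list(file.path(dir, "network.tsv"))
  catalogs <- list()
  for (ns in c("BP", "CC", "MF", "pathway")) {
    p <- file.path(dir, paste0(tolower(ns), ".gmt"))
    if (file.exists(p)) catalogs[[ns]] <- read_gmt(p, ns)
  }
  truth_path <- file.path(dir, "causal_terms.txt")
  excl_path <- file.path(dir, "exclusions.txt")
  structure(list(
    universe = universe,
    network = interaction_network(edges, nodes = universe),
    catalogs = catalogs,
    dag = read_term_dag(file.path(dir, "dag.tsv")),
    positives = read_gene_list(file.path(dir, "positives.txt")),
    exclusions = if (file.exists(excl_path)) read_gene_list(excl_path) else character(0),
    truth = if (file.exists(truth_path)) sort(readLines(truth_path)) else character(0),
    config = NULL
  ), class = "synthetic_world")
}
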