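#' Partition the negative genes into disjoint subsets
#'
#' Implements the imbalance-handling scheme: the (large) negative class is
#' split into disjoint subsets by a seeded uniform shuffle, and each
#' subset is later paired with the full positive set.  Either explicit
#' subset `sizes` or a near-equal `k`-way split may be requested; with
#' `k`, remainders go to the earlier subsets (larger first).
#'
#' @param negatives character vector of negative gene IDs.
#' @param sizes explicit subset sizes; must sum to `length(negatives)`.
#' @param k number of near-equal subsets (used when `sizes` is `NULL`).
#' @param seed shuffle seed; changes membership but never sizes.
#' @return list of character vectors (each sorted), pairwise disjoint and
#'   jointly covering `negatives`.
#' @export
partition_negatives <- function(negatives, sizes = NULL, k = NULL, seed = 1) {
  negatives <- as.character(negatives)
  n <- length(negatives)
  if (is.null(sizes) == is.null(k)) {
    stop_fmt("exactly one of `sizes` and `k` must be given")
  }
  if (is.null(sizes)) {
    k <- as.integer(k)
    if (k < 1 || k > n) stop_fmt("`k` must be between 1 and the negative count")
    base <- n %/% k
    sizes <- base + as.integer(seq_len(k) <= n %% k)
  }
  sizes <- as.integer(sizes)
  if (any(sizes < 1)) stop_fmt("subset sizes must be >= 1")
  if (sum(sizes) != n) {
    stop_fmt("subset sizes sum to %d but there are %d negatives", sum(sizes), n)
  }
  shuffled <- with_local_seed(seed, sample(negatives))
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1) + 1L)
  lapply(seq_along(sizes), function(i) sort(shuffled[starts[i]:ends[i]]))
}

#' Subset sizes mirroring a fixed negative:positive ratio
#'
#' Produces as many subsets of `ratio * n_positives` negatives as fit,
#' plus one remainder subset, e.g. 17,985 negatives against 615 positives
#' give five subsets of 3,075 and one of 2,610.
#'
#' @param n_negatives,n_positives class counts.
#' @param ratio negatives per positive within each full subset.
#' @return integer vector of subset sizes.
#' @export
ratio_partition_sizes <- function(n_negatives, n_positives, ratio = 5) {
  full <- ratio * n_positives
  if (full < 1 || full > n_negatives) {
    stop_fmt("ratio*n_positives (%d) must be in [1, n_negatives]", full)
  }
  n_full <- n_negatives %/% full
  rem <- n_negatives - n_full * full
  c(rep(full, n_full), if (rem > 0) rem)
}

#' Assemble labeled datasets from negative subsets
#'
#' Pairs every negative subset with the full positive set: dataset `i`
#' holds all positives (label 1) followed by subset `i` (label 0), each
#' block in universe (feature-matrix row) order.
#'
#' @param fm feature matrix from [encode_genes()].
#' @param positives character vector of positive gene IDs (non-empty).
#' @param negative_subsets list from [partition_negatives()]; subsets must
#'   not overlap the positives.
#' @param names dataset tags, default `S1`, `S2`, ...
#' @return list of `labeled_dataset` objects.
#' @export
assemble_datasets <- function(fm, positives, negative_subsets,
                              names = paste0("S", seq_along(negative_subsets))) {
  positives <- as.character(positives)
  if (length(positives) == 0) stop_fmt("the positive set must be non-empty")
  universe <- rownames(fm)
  missing <- setdiff(positives, universe)
  if (length(missing) > 0) {
    stop_fmt("positive gene(s) not in the feature matrix: %s",
             paste(head(missing, 5), collapse = ", "))
  }
  pos_ord <- universe[universe %in% positives]
  lapply(seq_along(negative_subsets), function(i) {
    neg <- as.character(negative_subsets[[i]])
    overlap <- intersect(neg, positives)
    if (length(overlap) > 0) {
      stop_fmt("subset %d overlaps the positives: %s", i,
               paste(head(overlap, 5), collapse = ", "))
    }
    neg_ord <- universe[universe %in% neg]
    rows <- c(pos_ord, neg_ord)
    labeled_dataset(fm[rows, , drop = FALSE],
                    c(rep(1L, length(pos_ord)), rep(0L, length(neg_ord))),
                    names[i])
  })
}

#' Labeled dataset container
#'
#' @param x numeric feature matrix (rows = genes, columns = terms).
#' @param y integer 0/1 label vector (1 = positive), one per row.
#' @param name dataset tag (e.g. `"S1"`).
#' @return object of class `labeled_dataset`.
#' @export
labeled_dataset <- function(x, y, name = "S1") {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (length(y) != nrow(x)) stop_fmt("label length != row count")
  if (!all(y %in% c(0L, 1L))) stop_fmt("labels must be 0/1")
  if (length(unique(y)) < 2) stop_fmt("both classes must be non-empty")
  structure(list(x = x, y = y, name = name), class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %s: %d samples (%d positive), %d features\n",
              x$name, nrow(x$x), sum(x$y), ncol(x$x)))
  invisible(x)
}
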