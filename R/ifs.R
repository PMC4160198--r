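#' Classification metrics from confusion counts
#'
#' \deqn{ACC = (TP+TN)/n,\; SN = TP/(TP+FN),\; SP = TN/(TN+FP)}
#' \deqn{MCC = \frac{TP \cdot TN - FP \cdot FN}
#'   {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}}
#' Any zero denominator yields 0 for the affected metric (the MCC
#' convention for degenerate confusion tables).
#'
#' @param counts named numeric vector or list with `TP`, `TN`, `FP`, `FN`.
#' @return named numeric vector `c(SN, SP, ACC, MCC)`.
#' @examples
#' metrics_from_counts(c(TP = 40, TN = 30, FP = 10, FN = 20))
#' @export
metrics_from_counts <- function(counts) {
  counts <- as.list(counts)
  tp <- as.numeric(counts$TP); tn <- as.numeric(counts$TN)
  fp <- as.numeric(counts$FP); fn <- as.numeric(counts$FN)
  if (anyNA(c(tp, tn, fp, fn)) || any(c(tp, tn, fp, fn) < 0)) {
    stop_fmt("counts must be non-negative TP/TN/FP/FN")
  }
  total <- tp + tn + fp + fn
  if (total <= 0) stop_fmt("confusion counts sum to zero")
  safe_div <- function(num, den) if (den > 0) num / den else 0
  denom <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  c(SN = safe_div(tp, tp + fn),
    SP = safe_div(tn, tn + fp),
    ACC = (tp + tn) / total,
    MCC = safe_div(tp * tn - fp * fn, denom))
}

confusion_counts <- function(truth, pred) {
  c(TP = sum(truth == 1 & pred == 1),
    TN = sum(truth == 0 & pred == 0),
    FP = sum(truth == 0 & pred == 1),
    FN = sum(truth == 1 & pred == 0))
}

# Stratified fold assignment: within each class, a seeded shuffle is
# dealt round-robin, so every fold keeps both classes.
stratified_folds <- function(y, folds, seed) {
  folds <- as.integer(folds)
  if (folds < 2) stop_fmt("`folds` must be >= 2")
  tab <- table(y)
  if (any(tab < folds)) {
    stop_fmt("class with %d members is rarer than the fold count %d",
             min(tab), folds)
  }
  assign <- integer(length(y))
  with_local_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      assign[idx[sample.int(length(idx))]] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assign
}

#' Cross-validated dagging metrics
#'
#' Stratified `folds`-fold cross-validation: for each fold a dagging
#' ensemble is trained on the remaining samples and predicts the held-out
#' fold; the held-out predictions are pooled into a single confusion
#' table from which one [metrics_from_counts()] set is computed.
#'
#' @param dataset a [labeled_dataset()].
#' @param features term IDs (columns) to use; default all.
#' @param folds number of CV folds, default 10.
#' @param seed seed for fold assignment and subsample shuffles.
#' @param dagging_k base-model count of each ensemble.
#' @return list with `metrics`, `counts` and the `fold_assignment`.
#' @export
cross_validate <- function(dataset, features = NULL, folds = 10, seed = 1,
                           dagging_k = 10) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  x <- if (is.null(features)) dataset$x else dataset$x[, features, drop = FALSE]
  assign <- stratified_folds(dataset$y, folds, seed)
  counts <- cv_core(x, dataset$y, assign, dagging_k, seed)
  list(metrics = metrics_from_counts(counts), counts = counts,
       fold_assignment = assign)
}

cv_core <- function(x, y, fold_assignment, dagging_k, seed) {
  counts <- c(TP = 0, TN = 0, FP = 0, FN = 0)
  for (f in sort(unique(fold_assignment))) {
    test <- fold_assignment == f
    ens <- train_dagging(x[!test, , drop = FALSE], y[!test],
                         k = dagging_k, seed = derive_seed(seed, f))
    pred <- predict(ens, x[test, , drop = FALSE])
    counts <- counts + confusion_counts(y[test], pred)
  }
  counts
}

#' Incremental feature selection along a ranked list
#'
#' Evaluates every nested prefix of the ranked feature list by
#' cross-validated dagging: prefix `i` uses the first `i` features.  The
#' optimal feature set is the smallest prefix achieving the maximum MCC.
#' Fold assignment is fixed once per dataset/seed, so successive prefix
#' evaluations are paired.
#'
#' @param dataset a [labeled_dataset()].
#' @param ranked a `ranked_feature_list` (or character vector of term IDs)
#'   in rank order; non-empty.
#' @param folds,seed,dagging_k see [cross_validate()].
#' @return object of class `ifs_result`: `curve` is a data frame
#'   (`n_features`, `SN`, `SP`, `ACC`, `MCC`) and `optimal` holds the
#'   dataset tag, the optimal prefix length `n_features`, its `terms` and
#'   the achieved `mcc`.
#' @export
ifs <- function(dataset, ranked, folds = 10, seed = 1, dagging_k = 10) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  terms <- if (is.data.frame(ranked)) as.character(ranked$term) else as.character(ranked)
  if (length(terms) == 0) stop_fmt("the ranked feature list is empty")
  missing <- setdiff(terms, colnames(dataset$x))
  if (length(missing) > 0) {
    stop_fmt("ranked feature(s) not in the dataset: %s",
             paste(head(missing, 5), collapse = ", "))
  }
  x <- dataset$x[, terms, drop = FALSE]
  assign <- stratified_folds(dataset$y, folds, seed)
  curve <- matrix(NA_real_, nrow = length(terms), ncol = 4,
                  dimnames = list(NULL, c("SN", "SP", "ACC", "MCC")))
  for (i in seq_along(terms)) {
    counts <- cv_core(x[, seq_len(i), drop = FALSE], dataset$y, assign,
                      dagging_k, seed)
    curve[i, ] <- metrics_from_counts(counts)
  }
  curve <- data.frame(n_features = seq_along(terms), curve)
  class(curve) <- c("ifs_curve", "data.frame")
  i_star <- which.max(curve$MCC)  # first maximum = smallest optimal prefix
  structure(list(
    curve = curve,
    optimal = list(dataset = dataset$name, n_features = i_star,
                   terms = terms[seq_len(i_star)], mcc = curve$MCC[i_star])
  ), class = "ifs_result")
}

#' @export
print.ifs_result <- function(x, ...) {
  cat(sprintf("<ifs_result> %s: optimal %d features, MCC = %.4f\n",
              x$optimal$dataset, x$optimal$n_features, x$optimal$mcc))
  invisible(x)
}

#' Plot an IFS curve
#'
#' MCC against the number of features in the classifier, with the optimal
#' prefix marked.
#'
#' @param x an `ifs_curve` (or the `curve` element of an [ifs()] result).
#' @param ... passed to [graphics::plot()].
#' @export
plot.ifs_curve <- function(x, ...) {
  graphics::plot(x$n_features, x$MCC, type = "l", xlab = "Number of features",
                 ylab = "MCC", ...)
  i_star <- which.max(x$MCC)
  graphics::points(x$n_features[i_star], x$MCC[i_star], pch = 19, col = "red")
}

#' Union of per-dataset optimal feature sets
#'
#' The total optimal feature set is the deduplicated union of the
#' per-dataset optimal sets, with provenance recording which datasets
#' selected each term.
#'
#' @param sets list of [ifs()] results (or of their `optimal` elements).
#' @return data frame of class `total_optimal_set` with columns `term`,
#'   `n_datasets` and `datasets` (comma-separated tags), ordered by first
#'   appearance.
#' @export
total_optimal_set <- function(sets) {
  if (length(sets) == 0) stop_fmt("at least one optimal set is required")
  opts <- lapply(sets, function(s) if (inherits(s, "ifs_result")) s$optimal else s)
  terms <- unique(unlist(lapply(opts, `[[`, "terms"), use.names = FALSE))
  prov <- lapply(terms, function(t) {
    vapply(opts[vapply(opts, function(o) t %in% o$terms, logical(1))],
           `[[`, character(1), "dataset")
  })
  structure(data.frame(
    term = terms,
    n_datasets = lengths(prov),
    datasets = vapply(prov, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE, row.names = NULL
  ), class = c("total_optimal_set", "data.frame"))
}
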