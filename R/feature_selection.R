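#' Binarize enrichment scores at a significance threshold
#'
#' Bridges the continuous -log10 enrichment scores to the categorical
#' Cramer's V test: a feature is "on" for a gene when its score strictly
#' exceeds `threshold` (default `-log10(0.05)`, the same cutoff used to
#' call key functions in candidate ranking).
#'
#' @param scores numeric vector or matrix of enrichment scores.
#' @param threshold non-negative score threshold; strict inequality.
#' @return integer 0/1 object of the same shape.
#' @export
binarize_features <- function(scores, threshold = -log10(0.05)) {
  if (threshold < 0) stop_fmt("`threshold` must be >= 0")
  out <- (scores > threshold) + 0L
  storage.mode(out) <- "integer"
  out
}

#' Cramer's V association of a contingency table
#'
#' \eqn{V = \sqrt{\chi^2 / (n \cdot (\min(r, c) - 1))}} from the Pearson
#' chi-square statistic of the table; for a 2x2 table this equals the
#' absolute phi coefficient.  Degenerate tables (any all-zero row or
#' column margin, or a single row/column) return 0.
#'
#' @param table matrix of non-negative counts with positive total.
#' @return value in `[0, 1]`.
#' @examples
#' cramers_v(matrix(c(30, 10, 10, 30), 2))  # 0.5
#' @export
cramers_v <- function(table) {
  tab <- as.matrix(table)
  if (any(tab < 0)) stop_fmt("counts must be non-negative")
  n <- sum(tab)
  if (n <= 0) stop_fmt("empty contingency table")
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0)) return(0)
  if (min(dim(tab)) < 2) return(0)
  expected <- outer(rs, cs) / n
  chi2 <- sum((tab - expected)^2 / expected)
  v <- sqrt(chi2 / (n * (min(dim(tab)) - 1)))
  min(v, 1)
}

#' Per-feature Cramer's V against the class label
#'
#' Each feature column is binarized with [binarize_features()] and its
#' 2x2 table against the labels summarized by the absolute phi
#' coefficient (identical to [cramers_v()] but vectorized over columns).
#'
#' @param dataset a [labeled_dataset()].
#' @param binarize_threshold threshold for [binarize_features()].
#' @return named numeric vector of V values, one per feature column.
#' @export
feature_cramers_v <- function(dataset, binarize_threshold = -log10(0.05)) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  xb <- dataset$x > binarize_threshold
  pos <- dataset$y == 1L
  n <- length(pos)
  a <- colSums(xb[pos, , drop = FALSE])    # x=1, y=1
  b <- colSums(xb[!pos, , drop = FALSE])   # x=1, y=0
  r1 <- sum(pos); r0 <- n - r1
  cc <- r1 - a                             # x=0, y=1
  d <- r0 - b                              # x=0, y=0
  denom <- sqrt((a + b) * (cc + d) * (a + cc) * (b + d))
  v <- abs(a * d - b * cc) / denom
  v[!is.finite(v)] <- 0
  names(v) <- colnames(dataset$x)
  v
}

#' Stage-I prefilter: drop features weakly associated with the label
#'
#' Features with Cramer's V strictly below `threshold` are excluded
#' (`V = threshold` is retained); survivors keep their original column
#' order.
#'
#' @param dataset a [labeled_dataset()].
#' @param threshold Cramer's V cutoff in `[0, 1]`, default 0.1.
#' @param binarize_threshold threshold for [binarize_features()].
#' @return character vector of retained term IDs.
#' @export
cramer_filter <- function(dataset, threshold = 0.1,
                          binarize_threshold = -log10(0.05)) {
  if (threshold < 0 || threshold > 1) stop_fmt("`threshold` must be in [0, 1]")
  v <- feature_cramers_v(dataset, binarize_threshold)
  names(v)[v >= threshold]
}

#' Discretize scores into three states for mutual information
#'
#' z-style discretization at mean +/- one (population) standard
#' deviation: values `<= mu - sigma` map to -1, values `>= mu + sigma` to
#' +1, everything else (including constant vectors, where `sigma = 0`) to
#' 0.
#'
#' @param scores numeric vector.
#' @return integer vector over `{-1, 0, 1}`.
#' @export
discretize_for_mi <- function(scores) {
  stopifnot(length(scores) >= 1)
  mu <- mean(scores)
  sigma <- sqrt(mean((scores - mu)^2))
  if (sigma == 0) return(rep(0L, length(scores)))
  out <- integer(length(scores))
  out[scores <= mu - sigma] <- -1L
  out[scores >= mu + sigma] <- 1L
  out
}

# Column-wise discretization of a matrix (population sd per column).
discretize_matrix <- function(x) {
  mu <- colMeans(x)
  sigma <- sqrt(pmax(colMeans(x^2) - mu^2, 0))
  lo <- sweep(x, 2, mu - sigma, "<=")
  hi <- sweep(x, 2, mu + sigma, ">=")
  out <- matrix(0L, nrow(x), ncol(x), dimnames = dimnames(x))
  out[lo] <- -1L
  out[hi] <- 1L
  out[, sigma == 0] <- 0L
  out
}

#' Plug-in mutual information of two discrete vectors (bits)
#'
#' Empirical joint-frequency mutual information, log base 2, with
#' `0 log 0 = 0`.
#'
#' @param a,b equal-length discrete vectors (any atomic type).
#' @return non-negative number of bits.
#' @export
mutual_information <- function(a, b) {
  if (length(a) != length(b) || length(a) < 1) {
    stop_fmt("`a` and `b` must be equal-length, non-empty vectors")
  }
  joint <- table(a, b)
  p <- joint / sum(joint)
  pa <- rowSums(p); pb <- colSums(p)
  idx <- which(p > 0, arr.ind = TRUE)
  sum(p[idx] * log2(p[idx] / (pa[idx[, 1]] * pb[idx[, 2]])))
}

# MI (bits) between one discrete vector v (integer states) and every
# column of integer matrix X, vectorized via indicator cross-products.
mi_vs_matrix <- function(v, X) {
  n <- length(v)
  vs <- sort(unique(v))
  xs <- sort(unique(as.vector(X)))
  Iv <- vapply(vs, function(s) as.numeric(v == s), numeric(n))
  rs <- colSums(Iv)                     # counts per v-state
  p <- ncol(X)
  mi <- numeric(p)
  ct <- matrix(0, length(xs), p)        # column-state counts per feature
  joint <- vector("list", length(xs))
  for (ti in seq_along(xs)) {
    Jt <- crossprod(Iv, X == xs[ti])    # |vs| x p counts of (v=s, x=t)
    joint[[ti]] <- Jt
    ct[ti, ] <- colSums(Jt)
  }
  for (ti in seq_along(xs)) {
    Jt <- joint[[ti]]
    for (si in seq_along(vs)) {
      cnt <- Jt[si, ]
      nz <- cnt > 0
      if (any(nz)) {
        mi[nz] <- mi[nz] + cnt[nz] / n *
          (log2(cnt[nz]) + log2(n) - log2(rs[si]) - log2(ct[ti, nz]))
      }
    }
  }
  mi
}

#' Rank features by relevance alone (MaxRel)
#'
#' Features (discretized with [discretize_for_mi()]) are sorted by
#' decreasing mutual information with the class label; ties are broken by
#' original column index and the list truncated to `cap`.
#'
#' @param dataset a [labeled_dataset()].
#' @param retained term IDs to rank (typically the [cramer_filter()]
#'   survivors); non-empty.
#' @param cap maximum list length, default 500.
#' @return data frame (`rank`, `term`, `score`) of class
#'   `ranked_feature_list` with attribute `criterion = "MaxRel"`.
#' @export
maxrel_rank <- function(dataset, retained = colnames(dataset$x), cap = 500) {
  rk <- rank_setup(dataset, retained, cap)
  ord <- order(-rk$rel, seq_along(rk$rel))[seq_len(min(cap, length(rk$rel)))]
  ranked_feature_list(retained[ord], rk$rel[ord], "MaxRel")
}

#' Rank features by max-relevance, min-redundancy (mRMR)
#'
#' Greedy mRMR under the difference (MID) scheme: the first pick
#' maximizes MI with the label; each later pick maximizes
#' \eqn{I(f; y) - \frac{1}{|S|}\sum_{s \in S} I(f; s)} over already
#' selected features \eqn{S}.  Exact criterion ties are broken by lower
#' mean redundancy, then by original column index.
#'
#' @inheritParams maxrel_rank
#' @return data frame (`rank`, `term`, `score`) of class
#'   `ranked_feature_list` with attribute `criterion = "mRMR"`; `score`
#'   is the criterion value at the step the feature was selected.
#' @export
mrmr_rank <- function(dataset, retained = colnames(dataset$x), cap = 500) {
  rk <- rank_setup(dataset, retained, cap)
  p <- length(retained)
  n_out <- min(cap, p)
  selected <- integer(n_out)
  sel_score <- numeric(n_out)
  red_sum <- numeric(p)
  eps <- 1e-12

  pick <- which.max(rk$rel)  # first max wins: column-index tie-break
  selected[1] <- pick; sel_score[1] <- rk$rel[pick]
  for (step in seq_len(n_out - 1L) + 1L) {
    red_sum <- red_sum + mi_vs_matrix(rk$disc[, selected[step - 1L]], rk$disc)
    score <- rk$rel - red_sum / (step - 1L)
    score[selected[seq_len(step - 1L)]] <- -Inf
    mx <- max(score)
    cand <- which(score >= mx - eps)
    if (length(cand) > 1) {
      red <- red_sum[cand]
      cand <- cand[red <= min(red) + eps]
    }
    selected[step] <- cand[1]
    sel_score[step] <- score[cand[1]]
  }
  ranked_feature_list(retained[selected], sel_score, "mRMR")
}

rank_setup <- function(dataset, retained, cap) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  if (length(retained) == 0) stop_fmt("`retained` must be non-empty")
  if (cap < 1) stop_fmt("`cap` must be >= 1")
  missing <- setdiff(retained, colnames(dataset$x))
  if (length(missing) > 0) {
    stop_fmt("unknown feature(s): %s", paste(head(missing, 5), collapse = ", "))
  }
  disc <- discretize_matrix(dataset$x[, retained, drop = FALSE])
  list(disc = disc, rel = mi_vs_matrix(dataset$y, disc))
}

ranked_feature_list <- function(terms, scores, criterion) {
  structure(data.frame(rank = seq_along(terms), term = terms, score = scores,
                       stringsAsFactors = FALSE, row.names = NULL),
            criterion = criterion,
            class = c("ranked_feature_list", "data.frame"))
}
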