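#' Train a dagging ensemble of linear SVMs
#'
#' Dagging trains one base classifier per disjoint subsample: the samples
#' are shuffled once (seeded) and split into `k` near-equal folds that
#' jointly cover the training set; each fold trains a linear-kernel
#' soft-margin SVM (`C = 1`, via [e1071::svm()]) on features rescaled to
#' `[0, 1]` by that fold's own minima/maxima.  Predictions are combined
#' by majority vote.
#'
#' @param x numeric feature matrix.
#' @param y integer 0/1 labels.
#' @param k number of disjoint subsamples (base models); `k = 1` reduces
#'   to a single SVM on the full data.
#' @param seed shuffle seed.
#' @return object of class `dagging_ensemble`.
#' @export
train_dagging <- function(x, y, k = 10, seed = 1) {
  x <- as.matrix(x)
  y <- as.integer(y)
  n <- nrow(x)
  k <- as.integer(k)
  if (k < 1) stop_fmt("`k` must be >= 1")
  if (k > n) stop_fmt("`k` (%d) exceeds the sample count (%d)", k, n)
  if (length(unique(y)) < 2) stop_fmt("both classes must be present overall")

  shuffled <- with_local_seed(seed, sample.int(n))
  base <- n %/% k; extra <- n %% k
  sizes <- base + as.integer(seq_len(k) <= extra)
  ends <- cumsum(sizes); starts <- c(1L, head(ends, -1) + 1L)

  models <- vector("list", k)
  for (i in seq_len(k)) {
    idx <- shuffled[starts[i]:ends[i]]
    yi <- y[idx]
    if (length(unique(yi)) < 2) {
      # Single-class subsample: the base model votes its constant class.
      models[[i]] <- list(type = "constant", label = yi[1])
      next
    }
    xi <- x[idx, , drop = FALSE]
    mins <- apply(xi, 2, min)
    rng <- apply(xi, 2, max) - mins
    rng[rng == 0] <- 1
    xs <- sweep(sweep(xi, 2, mins, "-"), 2, rng, "/")
    fit <- e1071::svm(xs, factor(yi, levels = c(0, 1)),
                      kernel = "linear", cost = 1, scale = FALSE)
    models[[i]] <- list(type = "svm", fit = fit, mins = mins, rng = rng)
  }
  structure(list(models = models, k = k, features = colnames(x),
                 fold_sizes = sizes, seed = seed),
            class = "dagging_ensemble")
}

#' Predict labels by majority vote of the dagging base models
#'
#' A strict majority of positive votes predicts the positive class; an
#' exact tie (possible at even `k`) resolves to the negative class, the
#' conservative choice for a rare positive class.
#'
#' @param object a `dagging_ensemble`.
#' @param newdata numeric matrix with the training feature columns.
#' @param ... unused.
#' @return integer vector of 0/1 predictions.
#' @export
predict.dagging_ensemble <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(object$features) && !is.null(colnames(newdata))) {
    newdata <- newdata[, object$features, drop = FALSE]
  }
  votes <- rep(0L, nrow(newdata))
  for (m in object$models) {
    if (m$type == "constant") {
      votes <- votes + m$label
    } else {
      xs <- sweep(sweep(newdata, 2, m$mins, "-"), 2, m$rng, "/")
      votes <- votes + (predict(m$fit, xs) == "1")
    }
  }
  as.integer(votes > object$k / 2)
}

#' @export
print.dagging_ensemble <- function(x, ...) {
  cat(sprintf("<dagging_ensemble> k=%d base SVMs over %d features\n",
              x$k, length(x$features)))
  invisible(x)
}
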