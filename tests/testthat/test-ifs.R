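test_that("metrics follow the confusion-matrix formulas", {
  perfect <- metrics_from_counts(c(TP = 60, TN = 40, FP = 0, FN = 0))
  expect_equal(unname(perfect), c(1, 1, 1, 1))
  m <- metrics_from_counts(c(TP = 40, TN = 30, FP = 10, FN = 20))
  expect_equal(m[["SN"]], 2 / 3)
  expect_equal(m[["SP"]], 0.75)
  expect_equal(m[["ACC"]], 0.7)
  expect_equal(m[["MCC"]], 1000 / sqrt(6e6))
  # all-negative prediction with both classes present: zero-denominator rule
  degen <- metrics_from_counts(c(TP = 0, TN = 50, FP = 0, FN = 10))
  expect_equal(degen[["MCC"]], 0)
  expect_equal(degen[["SN"]], 0)
  expect_error(metrics_from_counts(c(TP = -1, TN = 1, FP = 0, FN = 0)),
               "non-negative")
})

test_that("MCC equals the Pearson correlation of truth and prediction", {
  set.seed(19)
  for (i in 1:100) {
    counts <- c(TP = rpois(1, 20), TN = rpois(1, 30),
                FP = rpois(1, 10), FN = rpois(1, 5))
    if (sum(counts) == 0) next
    truth <- rep(c(1, 1, 0, 0), counts[c("TP", "FN", "FP", "TN")])
    pred <- rep(c(1, 0, 1, 0), counts[c("TP", "FN", "FP", "TN")])
    mcc <- metrics_from_counts(counts)[["MCC"]]
    r <- suppressWarnings(stats::cor(truth, pred))
    if (is.na(r)) expect_equal(mcc, 0) else expect_equal(mcc, r, tolerance = 1e-12)
  }
})

test_that("dagging folds partition the training samples near-equally", {
  d <- separable_dataset(n = 200)
  ens <- train_dagging(d$x[51:150, ], d$y[51:150], k = 10, seed = 1)
  expect_identical(ens$fold_sizes, rep(10L, 10))
  ens2 <- train_dagging(d$x[49:151, ], d$y[49:151], k = 10, seed = 1)
  expect_identical(sort(ens2$fold_sizes, decreasing = TRUE),
                   c(11L, 11L, 11L, rep(10L, 7)))
  expect_equal(sum(ens2$fold_sizes), 103)
  expect_error(train_dagging(d$x[1:5, ], d$y[1:5], k = 10), "exceeds")
})

test_that("k = 1 dagging reduces to a single SVM on the full data", {
  d <- separable_dataset(n = 60)
  ens <- train_dagging(d$x, d$y, k = 1, seed = 1)
  expect_length(ens$models, 1)
  expect_identical(ens$models[[1]]$type, "svm")
  expect_identical(predict(ens, d$x), d$y)
})

test_that("majority voting breaks exact ties toward the negative class", {
  const_model <- function(label) list(type = "constant", label = label)
  tied <- structure(list(models = c(replicate(5, const_model(1L), simplify = FALSE),
                                    replicate(5, const_model(0L), simplify = FALSE)),
                         k = 10L, features = NULL),
                    class = "dagging_ensemble")
  expect_identical(predict(tied, matrix(0, 3, 2)), rep(0L, 3))
  all_pos <- structure(list(models = replicate(3, const_model(1L), simplify = FALSE),
                            k = 3L, features = NULL),
                       class = "dagging_ensemble")
  expect_identical(predict(all_pos, matrix(0, 2, 2)), rep(1L, 2))
})

test_that("single-class subsamples fall back to constant voters", {
  x <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  y <- c(rep(1L, 2), rep(0L, 18))  # k=10 folds of 2: most are all-negative
  ens <- train_dagging(x, y, k = 10, seed = 2)
  types <- vapply(ens$models, `[[`, character(1), "type")
  expect_true("constant" %in% types)
  expect_length(predict(ens, x), 20)
})

test_that("cross-validation holds each sample out exactly once", {
  d <- separable_dataset(n = 80)
  cv <- cross_validate(d, folds = 10, seed = 1, dagging_k = 5)
  expect_equal(sum(cv$counts), nrow(d$x))
  expect_identical(sort(unique(cv$fold_assignment)), 1:10)
  expect_equal(length(cv$fold_assignment), nrow(d$x))
  # stratification keeps both classes in each fold
  for (f in 1:10) {
    expect_identical(sort(unique(d$y[cv$fold_assignment == f])), c(0L, 1L))
  }
  expect_error(cross_validate(d, folds = 60), "rarer than")
})

test_that("well-separated Gaussian clusters cross-validate to MCC 1", {
  d <- separable_dataset(n = 200)
  cv <- cross_validate(d, folds = 10, seed = 3, dagging_k = 10)
  expect_equal(cv$metrics[["MCC"]], 1)
})

test_that("label-shuffled data cross-validates near MCC 0", {
  set.seed(23)
  x <- matrix(rnorm(400 * 4), 400, 4, dimnames = list(NULL, paste0("f", 1:4)))
  for (s in 1:2) {
    y <- sample(rep(c(1L, 0L), each = 200))
    d <- labeled_dataset(x, y, "null")
    cv <- cross_validate(d, folds = 10, seed = s, dagging_k = 10)
    expect_lte(abs(cv$metrics[["MCC"]]), 0.15)
  }
})

test_that("IFS evaluates nested prefixes and picks the smallest max-MCC set", {
  d <- separable_dataset(n = 80, p = 4)
  fit <- ifs(d, colnames(d$x), folds = 5, seed = 2, dagging_k = 5)
  expect_equal(fit$curve$n_features, 1:4)
  expect_equal(fit$optimal$mcc, max(fit$curve$MCC))
  expect_equal(fit$optimal$n_features, min(which(fit$curve$MCC == max(fit$curve$MCC))))
  expect_identical(fit$optimal$terms, colnames(d$x)[seq_len(fit$optimal$n_features)])
  # determinism: same seed, bit-identical curve
  fit2 <- ifs(d, colnames(d$x), folds = 5, seed = 2, dagging_k = 5)
  expect_identical(fit$curve, fit2$curve)
  expect_error(ifs(d, character(0)), "empty")
})

test_that("the total optimal set is a provenance-tracked union", {
  s1 <- list(dataset = "S1", terms = c("a", "b"), mcc = 0.5)
  s2 <- list(dataset = "S2", terms = c("b", "c"), mcc = 0.6)
  os <- total_optimal_set(list(s1, s2))
  expect_setequal(os$term, c("a", "b", "c"))
  expect_equal(os$n_datasets[os$term == "b"], 2)
  expect_identical(os$datasets[os$term == "b"], "S1,S2")
  # idempotence
  os2 <- total_optimal_set(list(s1, s1))
  expect_identical(os2$term, s1$terms)
})
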