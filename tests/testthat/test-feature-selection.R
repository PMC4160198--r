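test_that("binarization is strict at the threshold", {
  thr <- -log10(0.05)
  expect_identical(binarize_features(c(2.0, 0.0, thr), thr), c(1L, 0L, 0L))
  expect_identical(binarize_features(rep(0, 4), thr), rep(0L, 4))
  expect_identical(binarize_features(c(0.1, 5), 0), c(1L, 1L))
  expect_error(binarize_features(1, -0.5), ">= 0")
})

test_that("Cramer's V matches closed forms and is swap-invariant", {
  expect_equal(cramers_v(matrix(c(50, 0, 0, 50), 2)), 1)
  expect_equal(cramers_v(matrix(c(25, 25, 25, 25), 2)), 0)
  # 2x2 closed form |ad - bc| / sqrt(margins) = 800/1600
  expect_equal(cramers_v(matrix(c(30, 10, 10, 30), 2)), 0.5)
  set.seed(4)
  for (i in 1:25) {
    tab <- matrix(rpois(6, 20), 2, 3)
    v <- cramers_v(tab)
    expect_true(v >= 0 && v <= 1)
    expect_equal(cramers_v(t(tab)), v)
  }
  # degenerate margins and empty tables
  expect_equal(cramers_v(matrix(c(10, 20, 0, 0), 2)), 0)
  expect_error(cramers_v(matrix(0, 2, 2)), "empty")
})

test_that("the Cramer filter keeps V >= threshold in column order", {
  set.seed(8)
  y <- rep(c(1L, 0L), each = 40)
  thr <- -log10(0.05)
  x <- cbind(
    perfect = ifelse(y == 1, 3, 0),            # V = 1
    constant = rep(0.2, 80),                   # degenerate, V = 0
    strong = ifelse(y == 1, c(rep(3, 30), rep(0, 10)),
                    c(rep(3, 10), rep(0, 30))),# [[30,10],[10,30]] -> V = 0.5
    noise = runif(80)                          # weak
  )
  d <- labeled_dataset(x, y, "toy")
  v <- feature_cramers_v(d, binarize_threshold = thr)
  expect_equal(unname(v[["strong"]]), 0.5)
  kept <- cramer_filter(d, threshold = 0.1, binarize_threshold = thr)
  expect_true(all(c("perfect", "strong") %in% kept))
  expect_false("constant" %in% kept)
  expect_identical(kept, colnames(x)[colnames(x) %in% kept])  # original order
  # boundary is inclusive and raising the threshold never grows the set
  expect_true("perfect" %in% cramer_filter(d, threshold = 1))
  thresholds <- seq(0, 1, by = 0.1)
  sizes <- vapply(thresholds, function(t) length(cramer_filter(d, t)), 1L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("three-state discretization follows the mean +/- sigma rule", {
  expect_identical(discretize_for_mi(rep(2.5, 6)), rep(0L, 6))
  expect_identical(discretize_for_mi(c(0, 0, 0, 0, 10)), c(0L, 0L, 0L, 0L, 1L))
  x <- c(-3, 0, 3)
  expect_identical(discretize_for_mi(x)[2], 0L)  # value exactly at the mean
  set.seed(11)
  for (i in 1:20) {
    v <- rnorm(50)
    expect_identical(discretize_for_mi(v), disc_oracle(v))
  }
})

test_that("mutual information matches plug-in values and its identities", {
  a <- rep(c(0, 1), 20)
  expect_equal(mutual_information(a, a), 1)  # H of a fair bit
  expect_equal(mutual_information(rep(1, 40), a), 0)
  # joint frequencies [[0.4, 0.1], [0.1, 0.4]]
  x <- rep(c(0, 0, 1, 1), c(8, 2, 2, 8))
  yv <- rep(c(0, 1, 0, 1), c(8, 2, 2, 8))
  expect_equal(mutual_information(x, yv), 0.2780719, tolerance = 1e-6)
  set.seed(12)
  for (i in 1:20) {
    u <- sample(0:2, 60, replace = TRUE)
    w <- sample(0:1, 60, replace = TRUE)
    expect_equal(mutual_information(u, w), mutual_information(w, u))
    expect_equal(mutual_information(u, w), mi_oracle(u, w), tolerance = 1e-12)
    # merging states never increases information about the other variable
    merged <- pmin(u, 1)
    expect_lte(mutual_information(merged, w), mutual_information(u, w) + 1e-12)
  }
})

test_that("MaxRel sorts by relevance with column-index ties", {
  y <- rep(c(1L, 0L), each = 20)
  set.seed(3)
  x <- cbind(a = runif(40), dup1 = as.numeric(y), b = runif(40),
             dup2 = as.numeric(y))
  d <- labeled_dataset(x, y, "toy")
  rk <- maxrel_rank(d, colnames(x), cap = 4)
  # both label copies occupy ranks 1-2 in column order
  expect_identical(rk$term[1:2], c("dup1", "dup2"))
  expect_identical(attr(rk, "criterion"), "MaxRel")
  expect_equal(nrow(maxrel_rank(d, "a", cap = 10)), 1)
  # cap truncates
  expect_equal(nrow(maxrel_rank(d, colnames(x), cap = 2)), 2)
})

test_that("mRMR demotes redundant duplicates below fresh features", {
  y <- c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L)
  f1 <- as.numeric(y); f3 <- f1; f3[1] <- 0
  d <- labeled_dataset(cbind(f1 = f1, f2 = f1, f3 = f3), y, "demo")
  rk <- mrmr_rank(d, c("f1", "f2", "f3"), cap = 3)
  expect_identical(rk$term, c("f1", "f3", "f2"))
  # first pick always equals MaxRel's first pick
  expect_identical(rk$term[1], maxrel_rank(d, c("f1", "f2", "f3"))$term[1])
  expect_equal(nrow(mrmr_rank(d, "f1")), 1)
  expect_error(mrmr_rank(d, c("f1", "f2"), cap = 0), "cap")
})

test_that("greedy mRMR equals the exhaustive step-wise oracle", {
  set.seed(17)
  for (rep in 1:10) {
    n <- 30
    p <- sample(4:8, 1)
    y <- sample(c(0L, 1L), n, replace = TRUE, prob = c(0.6, 0.4))
    if (length(unique(y)) < 2) next
    x <- matrix(rnorm(n * p), n, p)
    x[, 1] <- x[, 1] + y            # informative
    if (p >= 5) x[, 5] <- x[, 1]    # redundant copy
    colnames(x) <- paste0("f", seq_len(p))
    d <- labeled_dataset(x, y, "rand")
    expect_identical(mrmr_rank(d, colnames(x), cap = p)$term,
                     mrmr_oracle(x, y),
                     label = sprintf("rep %d (p=%d)", rep, p))
  }
})
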