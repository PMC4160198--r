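test_that("enrichment score matches hand-enumerated hypergeometric tails", {
  # P = (C(4,2)C(6,1) + C(4,3)C(6,0)) / C(10,3) = 40/120
  expect_equal(enrichment_score(N = 10, M = 4, n = 3, m = 2), log10(3),
               tolerance = 1e-12)
  # fully overlapping draw: P = 1/C(20,5)
  expect_equal(enrichment_score(N = 20, M = 5, n = 5, m = 5),
               log10(choose(20, 5)), tolerance = 1e-12)
  # m = 0 means the tail is the whole support
  expect_identical(enrichment_score(N = 50, M = 10, n = 7, m = 0), 0)
  # support can force X >= m: N=10, M=8, n=5 implies X >= 3
  expect_identical(enrichment_score(N = 10, M = 8, n = 5, m = 3), 0)
})

test_that("enrichment score agrees with tail enumeration on random contexts", {
  set.seed(1)
  for (rep in 1:200) {
    N <- sample(2:30, 1)
    M <- sample(0:N, 1)
    n <- sample(0:N, 1)
    m <- sample(0:min(n, M), 1)
    p_impl <- 10^(-enrichment_score(N, M, n, m))
    expect_equal(p_impl, hyper_tail_oracle(N, M, n, m), tolerance = 1e-9,
                 label = sprintf("N=%d M=%d n=%d m=%d", N, M, n, m))
  }
})

test_that("score is monotone in the overlap and bounded by the cap", {
  sc <- enrichment_score(N = 40, M = 12, n = 10, m = 0:10)
  expect_true(all(diff(sc) >= 0))
  expect_true(all(sc >= 0 & is.finite(sc)))
  # extreme contexts hit the cap instead of overflowing to Inf
  big <- enrichment_score(N = 20000, M = 30, n = 5000, m = 30, cap = 300)
  expect_true(is.finite(big) && big <= 300)
})

test_that("invariant violations are rejected naming the offending field", {
  expect_error(enrichment_score(10, 12, 3, 1), "M exceeds N")
  expect_error(enrichment_score(10, 4, 12, 1), "n exceeds N")
  expect_error(enrichment_score(10, 4, 3, 4), "min\\(n, M\\)")
  expect_error(enrichment_score(10, 4, 3, -1), "negative")
})

test_that("neighbor sets are direct neighbors excluding the gene itself", {
  net <- interaction_network(
    data.frame(a = c("a", "b", "a"), b = c("b", "c", "c")),
    nodes = c("a", "b", "c", "lonely")
  )
  expect_identical(neighbor_set(net, "b"), c("a", "c"))
  expect_identical(neighbor_set(net, "lonely"), character(0))
  expect_warning(out <- neighbor_set(net, "ghost"), "not a network node")
  expect_identical(out, character(0))
})

test_that("self-loops and duplicate edges are dropped from the network", {
  net <- interaction_network(
    data.frame(a = c("a", "a", "a", "b"), b = c("b", "b", "a", "a"))
  )
  expect_equal(igraph::ecount(net), 1)
  expect_identical(neighbor_set(net, "a"), "b")
})

test_that("feature matrix has one row per gene, GO columns before pathways", {
  net <- interaction_network(
    data.frame(a = c("g1", "g1", "g2", "g3"), b = c("g2", "g3", "g3", "g4")),
    nodes = paste0("g", 1:5)
  )
  catalogs <- list(
    annotation_catalog("pathway", list(`pw:1` = c("g1", "g2"), `pw:2` = "g4")),
    annotation_catalog("BP", list(`bp:1` = c("g2", "g3"), `bp:2` = "g1",
                                  `bp:3` = c("g1", "g4")))
  )
  fm <- encode_genes(net, catalogs, universe = paste0("g", 1:5))
  expect_equal(dim(fm), c(5, 5))
  expect_identical(colnames(fm), c("bp:1", "bp:2", "bp:3", "pw:1", "pw:2"))
  expect_identical(unname(attr(fm, "term_namespace")),
                   c("BP", "BP", "BP", "pathway", "pathway"))
  # isolated gene: empty neighborhood, all-zero row
  expect_true(all(fm["g5", ] == 0))
  # hand-check one entry: g1's neighbors {g2,g3}, term bp:1 = {g2,g3},
  # N=5, M=2, n=2, m=2 -> P = 1/C(5,2)
  expect_equal(fm["g1", "bp:1"], log10(choose(5, 2)), tolerance = 1e-12)
})

test_that("permuting the universe permutes rows and nothing else", {
  w <- generate_world(tiny_config())
  fm1 <- encode_genes(w$network, w$catalogs, universe = w$universe)
  perm <- rev(w$universe)
  fm2 <- encode_genes(w$network, w$catalogs, universe = perm)
  expect_identical(colnames(fm1), colnames(fm2))
  expect_equal(fm2[w$universe, ], fm1[w$universe, ], ignore_attr = TRUE)
})

test_that("annotated genes outside the universe are rejected", {
  net <- interaction_network(data.frame(a = "g1", b = "g2"))
  cat1 <- annotation_catalog("BP", list(`bp:1` = c("g1", "gX")))
  expect_error(encode_genes(net, cat1, universe = c("g1", "g2")), "gX")
})

test_that("empty catalog lists are rejected", {
  net <- interaction_network(data.frame(a = "g1", b = "g2"))
  expect_error(encode_genes(net, list(), universe = c("g1", "g2")),
               "at least one annotation catalog")
})

test_that("feature matrix round-trips through gzipped TSV plus sidecar", {
  w <- generate_world(tiny_config())
  fm <- encode_genes(w$network, w$catalogs, universe = w$universe)
  path <- file.path(withr::local_tempdir(), "fm.tsv")
  write_feature_matrix(fm, path)
  back <- read_feature_matrix(paste0(path, ".gz"))
  expect_equal(unclass(back), unclass(fm), ignore_attr = TRUE)
  expect_identical(colnames(back), colnames(fm))
  expect_equal(attr(back, "universe_size"), attr(fm, "universe_size"))
})
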