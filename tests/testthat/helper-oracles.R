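# Independent oracles and small fixtures used across the suite.  Each
# oracle deliberately re-derives its quantity from first principles
# (enumeration, closed forms, naive loops) so it never shares code with
# the implementation path it checks.

# Upper-tail hypergeometric probability P(X >= m) by direct
# binomial-coefficient enumeration of the tail.
hyper_tail_oracle <- function(N, M, n, m) {
  ks <- seq(m, min(n, M))
  if (length(ks) == 0 || m > min(n, M)) return(0)
  sum(choose(M, ks) * choose(N - M, n - ks)) / choose(N, n)
}

# Plug-in mutual information (bits) via entropies H(a) + H(b) - H(a,b).
mi_oracle <- function(a, b) {
  ent <- function(x) {
    p <- table(x) / length(x)
    -sum(p * log2(p))
  }
  ent(a) + ent(b) - ent(paste(a, b))
}

# Mean +/- population-sd three-state discretizer (independent of the
# package's vectorized version).
disc_oracle <- function(x) {
  mu <- sum(x) / length(x)
  sig <- sqrt(sum((x - mu)^2) / length(x))
  if (sig == 0) return(rep(0L, length(x)))
  ifelse(x <= mu - sig, -1L, ifelse(x >= mu + sig, 1L, 0L))
}

# Exhaustive step-wise mRMR (difference scheme) over discretized
# features: at each step every remaining feature's criterion is
# recomputed from scratch with mi_oracle; ties on the criterion break by
# lower mean redundancy, then column index.
mrmr_oracle <- function(x, y, cap = ncol(x)) {
  disc <- apply(x, 2, disc_oracle)
  p <- ncol(disc)
  rel <- vapply(seq_len(p), function(j) mi_oracle(disc[, j], y), numeric(1))
  eps <- 1e-12
  selected <- integer(0)
  while (length(selected) < min(cap, p)) {
    remaining <- setdiff(seq_len(p), selected)
    red <- vapply(remaining, function(j) {
      if (length(selected) == 0) 0 else {
        mean(vapply(selected, function(s) mi_oracle(disc[, j], disc[, s]),
                    numeric(1)))
      }
    }, numeric(1))
    crit <- rel[remaining] - red
    best <- max(crit)
    cand <- which(crit >= best - eps)
    if (length(cand) > 1) cand <- cand[red[cand] <= min(red[cand]) + eps]
    selected <- c(selected, remaining[cand[1]])
  }
  colnames(x)[selected]
}

# Naive double-loop key-function counting for candidate scoring.
candidate_count_oracle <- function(fm, genes, terms, threshold) {
  counts <- integer(length(genes))
  for (gi in seq_along(genes)) {
    for (t in terms) {
      if (fm[genes[gi], t] > threshold) counts[gi] <- counts[gi] + 1L
    }
  }
  names(counts) <- genes
  counts
}

# Two well-separated Gaussian feature clusters: linearly separable by a
# wide margin, so any sane classifier reaches MCC = 1.
separable_dataset <- function(n = 200, p = 5, shift = 8, seed = 42) {
  stopifnot(n %% 2 == 0)
  set.seed(seed)
  y <- rep(c(1L, 0L), each = n / 2)
  x <- matrix(rnorm(n * p), n, p) + shift * y
  colnames(x) <- paste0("f", seq_len(p))
  rownames(x) <- sprintf("s%03d", seq_len(n))
  labeled_dataset(x, y, "separable")
}

# Small synthetic-world config for fast unit tests.
tiny_config <- function(seed = 5, ...) {
  generator_config(
    n_genes = 200, n_positives = 40,
    n_terms_per_namespace = c(BP = 20, CC = 8, MF = 10, pathway = 6),
    n_causal_terms = 6, term_size_range = c(8, 20),
    background_edge_prob = 0.02, seed = seed, ...
  )
}
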