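---
title: "Network-neighborhood enrichment and feature selection for tumor suppressor gene prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tsgrank methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Tumor suppressor genes (TSGs) restrain tumorigenesis; losing them — by
deletion, loss of heterozygosity, silencing — is a recurrent route to
cancer. Curated TSG catalogs are small (hundreds of genes) against a
background of ~18,000 protein-coding genes, so recognizing what makes a
TSG *look like* a TSG, and ranking the remaining genes by that
resemblance, is a useful prioritization exercise. `tsgrank` implements
such an analysis as a seeded, testable pipeline: genes are described by
the functional profile of their interaction-network neighborhood, the
informative parts of that profile are selected against a known TSG set,
and unlabeled genes are ranked by how many of the selected functions
they carry.

## Encoding: neighborhood enrichment scores

For gene $g$ with direct-neighbor set $G$ ($n = |G|$) in a
protein–protein interaction network of $N$ genes, and an annotation
term $t$ with $M$ member genes of which $m$ fall in $G$, the feature
value is

$$s(g, t) \;=\; -\log_{10} \sum_{k \ge m}
  \frac{\binom{M}{k}\binom{N-M}{n-k}}{\binom{N}{n}},$$

the upper-tail hypergeometric surprise of the overlap. One column per
term — Gene Ontology namespaces (BP, CC, MF) first, pathway sets last —
gives each gene a non-negative feature vector. Choices worth knowing:

* **$N$ is the declared universe size** (all network genes in real
  mode), not a fixed human-proteome constant; the "overall proteins"
  count is database-version-dependent, so it is a parameter
  (`encode_genes(..., N = )`), defaulting to the universe length.
* **$g$ is excluded from its own neighborhood**; an isolated gene has
  $n = 0$, hence an all-zero row.
* **Tails are computed in log space** (`phyper(log.p = TRUE)`), so
  extreme overlaps never underflow to $P = 0$; scores are capped at 300
  (in $-\log_{10}$ units), which preserves ordering while keeping every
  feature finite.
* **Annotations are used as given.** Propagating memberships up the
  is-a DAG is available (`propagate = TRUE`) but off by default: the
  default is the literal reading of "annotated to the term".
* Edge confidence scores are carried but not used; a `min_score` cutoff
  is available since interaction databases ship low-confidence edges.

## Class imbalance: disjoint negative subsets

With positives outnumbered ~29:1 in the motivating real-data setting,
the analysis splits the negatives into disjoint subsets and pairs each
subset with the *full* positive set, yielding $k$ datasets
$S_1 \dots S_k$. `ratio_partition_sizes()` implements the
fixed-ratio rule (as many subsets of $5\times$ the positive count as
fit, plus a remainder — for 17,985 negatives and 615 positives:
five of 3,075 and one of 2,610); the pipeline default is a near-equal
six-way split (`k_datasets = 6`), which is well defined at any scale.
At the synthetic default scale (850 negatives, 150 positives) the two
rules genuinely diverge — the ratio rule would produce a remainder
subset with *fewer* negatives than positives — which is why the
near-equal split is the default and the ratio rule an option for
real-scale data. Assignment is a seeded uniform shuffle; re-seeding
changes membership, never sizes.

## Feature selection

**Stage I — Cramér's V prefilter.** Each feature is binarized at
$-\log_{10}(0.05) \approx 1.301$ (strictly greater than), cross-tabulated
against the class label, and summarized by Cramér's
$V = \sqrt{\chi^2 / (n \cdot (\min(r,c) - 1))}$ (for 2×2 tables,
$|\phi|$). Features with $V < 0.1$ are dropped; $V = 0.1$ is kept. The
binarization threshold is the same significance cutoff the candidate
stage uses for "key functions" — the one threshold the analysis already
owns — since a $\chi^2$-based statistic needs categorical input.
Degenerate tables (a zero margin) score 0 and are dropped.

**Stage II — mRMR ranking.** Surviving features are discretized into
three states at mean ± one population standard deviation (constant
columns map to all-zero) and ranked by mutual information (bits,
plug-in estimate). Two lists are produced per dataset: *MaxRel*
(relevance $I(f; y)$ only) and *mRMR* under the difference scheme —
greedy selection maximizing
$I(f;y) - \tfrac{1}{|S|}\sum_{s \in S} I(f;s)$. Both lists are capped
at 500. Tie-breaking is deterministic: MaxRel ties break by column
index; mRMR criterion ties break by **lower mean redundancy first**,
then column index. The redundancy tie-break matters: after an exact
duplicate of an already-selected feature and a slightly perturbed copy
of the label both reach criterion 0, the duplicate should lose — index
order alone cannot express that.

**Stage III — incremental feature selection (IFS).** For every prefix
of the mRMR list, the dataset restricted to those features is evaluated
by stratified 10-fold cross-validation of a *dagging* ensemble: the
training samples are shuffled once and split into `dagging_k = 10`
disjoint near-equal subsamples, each training one linear-kernel
soft-margin SVM ($C = 1$, features min–max scaled to $[0,1]$ by the
subsample's own ranges), combined by majority vote with exact ties
going to the negative class (conservative for the rare positive
class). Held-out predictions are pooled into one confusion table per
prefix, giving

$$ACC, \quad SN = \frac{TP}{TP+FN}, \quad SP = \frac{TN}{TN+FP}, \quad
MCC = \frac{TP \cdot TN - FP \cdot FN}
  {\sqrt{(TP{+}FP)(TP{+}FN)(TN{+}FP)(TN{+}FN)}},$$

with any zero denominator yielding 0. MCC, robust to class imbalance,
is the selection criterion: the optimal feature set of a dataset is the
*smallest* prefix achieving the curve's maximum MCC. CV folds are fixed
per dataset and seed, so prefix evaluations are paired; a single-class
dagging subsample degrades gracefully to a constant voter. The union of
the per-dataset optimal sets — with provenance — is the **total optimal
feature set**.

## Candidate ranking

Every negative gene not on the exclusion list (curated oncogenes, in
the real setting — oncogene and suppressor functions are hard to tell
apart) is scored by its number of *key functions*: total-optimal-set
terms whose enrichment score strictly exceeds $-\log_{10}(0.05)$.
Candidates are ranked by that count (dense ranks, ties sharing a rank
and ordered by gene ID). Selected GO terms are additionally mapped up
the is-a DAG onto each direct child of their namespace root they
descend from — a term under several children counts under each — and
summarized per child as a frequency and a ratio
(frequency / descendant-term count, half-up to two decimals).

## The synthetic world

`generate_world()` builds a self-contained test bed with the
statistical structure the analysis assumes, so every stage is testable
without any database download:

| parameter | default | meaning |
|---|---|---|
| `n_genes` | 1000 | universe size |
| `n_positives` | 150 | minority positive class |
| `n_terms_per_namespace` | BP 150, CC 60, MF 80, pathway 50 | 340 terms total |
| `term_size_range` | [10, 40] | uniform term sizes |
| `background_edge_prob` | 0.01 | Erdős–Rényi density (mean degree ≈ 10) |
| `n_causal_terms` | 12 | planted "TSG function" terms |
| `causal_terms_per_gene` | 4 | causal terms assigned per positive |
| `causal_wiring_prob` | 0.5 | edge probability positive → causal-term member |
| `n_exclusions` | 20 | oncogene-like negatives |

The background graph is Erdős–Rényi — the simplest null with
controllable density — and each positive gene receives a fixed random
subset of the causal terms, gaining an edge to each member of each
assigned term with `causal_wiring_prob`, on top of the background; this
wires positive neighborhoods to be enriched for causal-term members in
expectation while negatives stay pure background. Defaults were sized
so a full six-dataset study runs in a few minutes on one CPU: 1,000
genes with mean degree ~10 keep encoding instant, 150 positives keep
every CV fold populated, and term sizes of 10–40 give hypergeometric
tails that are informative but not saturated. The is-a DAG is
deliberately shallow (terms → six root children → namespace root, with
20% of terms under two children): enough to exercise root-child
mapping, with no pretense of realistic GO depth. What the generator
does **not** emulate: scale-free/modular network topology, correlated
term memberships, annotation bias toward well-studied genes, or any
mechanistic model of gene silencing — so passing tests demonstrate
correctness and calibration of the *procedure*, not performance claims
about real interactomes.

With wiring probability 0 the world is signal-free by construction; the
planted-term labels in `world$truth` make parameter-recovery tests
possible (at `causal_wiring_prob = 0.5` the pipeline recovers the
planted terms essentially completely — see the package tests and
`scripts/acceptance.R`, which compute exactly these quantities).

## Known limitations

* **In-sample selection bias at small sample sizes.** The Cramér
  filter, the mRMR ranking and the IFS maximum are all computed on the
  same dataset the cross-validation evaluates, as in the original
  analysis design. The $V \ge 0.1$ cutoff scales as
  $\chi^2 = nV^2$: at $n \approx 3{,}700$ samples it demands
  $\chi^2 \ge 37$ (vanishingly rare under the null), but at the
  synthetic default scale ($n \approx 290$ per dataset) it only demands
  $\chi^2 \ge 2.9$, so roughly 5–15% of pure-noise features survive,
  and maximizing CV-MCC over prefixes of cherry-picked noise features
  is optimistically biased. The signal-free studies run by the test
  suite and acceptance script quantify this: per-dataset optimal MCC
  around 0.2–0.35 at the default scale, where a selection-free
  procedure would sit near 0. This is a property of the method at small
  $n$, worth keeping in mind when reading small-sample IFS curves; the
  planted-signal MCC of 1.0 at the same scale is far outside that band.
* The negative class is everything not curated as positive; in real
  data it surely contains unrecognized positives, which depresses
  measured specificity.
* The SVM contract is the decision function (linear kernel, $C = 1$,
  per-subsample min–max scaling); any convergent solver is acceptable,
  and `e1071::svm` is used here.
* Scores are raw $-\log_{10} P$ values used as features; no
  multiple-testing correction is applied or appropriate.

## Reproducibility

Every source of randomness flows from explicit integer seeds; the
pipeline fans one global seed out to per-stage sub-seeds by a fixed
derivation, restores the caller's RNG state, and re-running an
identical config reproduces byte-identical artifacts (asserted in the
test suite). The JSON manifest records parameters, stage dimensions,
per-dataset optima and status; a failed stage is named and its partial
outputs flagged stale.
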