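---
title: "Marker-gene discovery for multi-class single-cell data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker-gene discovery for multi-class single-cell data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Given a cells × genes expression matrix and a cell-type label per cell,
`cellmark` asks: *which small set of genes suffices to tell the cell types
apart, and by what expression thresholds?* The answer is useful twice over —
the genes are candidate cell-type markers, and the thresholds, read off a
decision tree as IF–THEN rules, describe each type's expression pattern in a
form a biologist can inspect.

Real atlas-scale datasets of this kind have properties that shape the whole
design: very many classes, severe class imbalance (the largest type can
outnumber the smallest by a factor of hundreds), tens of thousands of mostly
uninformative genes, and sparse count-like values. The pipeline is a chain of
progressively more expensive feature-selection stages, each narrowing the
candidate set for the next:

1. **Relevance filter** — mutual information of each (discretized) gene with
   the label; genes scoring ≤ 0.001 bits are dropped. A cheap pass that
   removes only clearly label-independent genes.
2. **Shadow-feature confirmation** — a Boruta-style all-relevant test of each
   survivor against permuted copies of the candidate genes, using
   random-forest impurity importance.
3. **Monte Carlo feature selection (MCFS)** — thousands of small decision
   trees on random feature projections; each split node credits its feature
   with a relative-importance (RI) score, yielding a full ranking.
4. **Incremental feature selection (IFS)** — sweep nested top-*k* prefixes of
   the ranking, score each with cross-validated multiclass MCC, and pick the
   *optimal* (max-MCC) and *efficient* (near-max, far smaller) feature
   counts.
5. **Rule extraction** — a final decision tree on the DT-optimal prefix,
   flattened into support/confidence-ranked IF–THEN rules.

# Models and estimators

## Mutual information and discretization

Expression values are continuous, so each gene is first discretized into
three states by distance from its mean: `low` below *mean − ασ*, `high`
above *mean + ασ*, `mid` otherwise (α = 1 by default, σ with denominator
*n*). This is the classic preprocessing of mutual-information filters on
expression data; a constant gene is all-`mid` and scores MI = 0. MI is the
plug-in estimate from the empirical joint table,

$$I(x, y) = \sum_{x,y} \hat p(x,y)\,
  \log_2 \frac{\hat p(x,y)}{\hat p(x)\hat p(y)},$$

reported in **bits** (base 2). The retention threshold (default 0.001) is a
dimensionless convention and is exposed as a parameter precisely because its
scale — bits vs nats — is a convention, not a derivation. Retention is
strict (`MI > threshold`): the filter drops the ≤-threshold mass. Note that
plug-in MI is positively biased at finite *n* (roughly
$(|X|-1)(|Y|-1)/(2n\ln 2)$ bits), so on a few thousand cells many genuinely
uninformative genes clear 0.001; the filter is intentionally permissive and
the confirmation stage does the real work.

## Shadow-feature confirmation

Each iteration appends a freshly permuted copy (*shadow*) of every
still-undecided gene, fits a random forest (100 trees, impurity importance),
and records a *hit* for genes whose importance exceeds the best shadow.
Hit counts are tested against Binomial(iterations, ½). The default
*two-step* multiplicity handling corrects each iteration's tests two ways at
once — Benjamini–Hochberg across the undecided genes, and Bonferroni across
the iterations a gene has been tested (significance requires
`p ≤ α/iter`) — mirroring the widely used Python implementation of the
method; a plain Bonferroni-across-features mode is available. We chose the
in-loop corrected test over a literal "uncorrected during the loop,
Bonferroni once at the end" scheme because the latter is self-defeating: the
loop terminates as soon as every gene is provisionally decided (typically
after ~5 iterations), at which point no gene has enough trials to clear a
final Bonferroni bar and every confirmation would be reverted. Genes still
undecided at `max_iter` are *tentative* and, by default, forwarded to the
ranking stage (`keep_tentative = TRUE`): for a ranking stage, inclusion is
the conservative choice, and MCFS will place uninformative stragglers at the
bottom anyway.

## MCFS relative importance

For feature *f*, summing over all *s·t* trees τ and the nodes *n_f(τ)* that
split on *f*:

$$\mathrm{RI}_f = \sum_{\tau} (\mathrm{wAcc}_\tau)^u \,
  \mathrm{IG}(n_f(\tau)) \,
  \left(\frac{\mathrm{no.in}\; n_f(\tau)}{\mathrm{no.in}\;\tau}\right)^{v},$$

with *u = v =* 1 by default. `wAcc` is the tree's *weighted accuracy* — the
unweighted mean of per-class recall on the tree's held-out split (balanced
accuracy), so trees that only get the majority classes right are discounted.
`IG` is the literal information gain of the split in bits, and the node
fraction downweights deep nodes that touch few samples. Projection defaults:
*m* = ⌈0.05 *d*⌉ features per projection (min 1) and
*s* = ⌈300 *d*/*m*⌉ projections (capped at 20 000) with *t* = 5
train/test resplits each, so every feature is expected in ≈ 300 projections
(≈ 1500 trees) — enough for stable RI estimates at desk scale while staying
minutes-cheap. Ties in RI (e.g. never-selected features at 0) keep the input
gene order, making ranked lists reproducible byte for byte.

The trees behind MCFS, the IFS decision-tree classifier, and rule extraction
are one implementation: a deterministic, unpruned entropy CART (Rcpp) that
exposes per-node gain and sample counts. Split thresholds are midpoints
between consecutive distinct values; `value ≤ threshold` goes left; gain
ties resolve to the lowest feature index and smallest threshold; leaf ties
to the first class level. Determinism here is load-bearing: identical
configurations must reproduce identical artifacts.

## Class balancing (SMOTE)

Minority classes are oversampled to the majority count: a random minority
sample *x*, one of its *k* = 5 nearest same-class neighbours *y* (Euclidean
distance on the current feature subset, not all genes), and
*z = x + λ(y − x)*, λ ~ U(0, 1). Balancing is applied **only inside
cross-validation training folds** — held-out folds are never touched, and
all reported metrics are computed on original cells only. The alternative
reading (balance once, before splitting) leaks interpolated copies of
training cells into test folds and inflates every score; it is retained as
`smote_in_fold = FALSE` for comparison, with evaluation still restricted to
original cells. Classes of size 1 cannot be oversampled (no neighbour) and
are an error; *k* is clamped to class size − 1 with a warning.

## Multiclass MCC

The model-selection metric is the K-class Matthews correlation coefficient:
with N × K one-hot indicator matrices X (true) and Y (predicted),

$$\mathrm{MCC} = \frac{\mathrm{cov}(X, Y)}
  {\sqrt{\mathrm{cov}(X, X)\,\mathrm{cov}(Y, Y)}},$$

where cov(·,·) sums per-column covariances. This equals Gorodkin's $R_K$
computed from the confusion matrix (the test suite checks the equivalence on
random matrices to 1e−10). A zero denominator — e.g. a constant
prediction — is defined as MCC = 0, the standard convention. MCC is
preferred over accuracy because with hundreds-fold imbalance a
majority-class predictor scores high accuracy but ≈ 0 MCC. Overall accuracy
and per-class recall (*individual accuracy*) are reported alongside.

## IFS and the optimal/efficient distinction

Prefixes of size step, 2·step, … (default step 5, capped at the top 1000
features; a non-multiple bound is appended as a final partial prefix) are
each scored by stratified 10-fold cross-validation with in-fold SMOTE,
pooling out-of-fold predictions before computing metrics once (pooling,
rather than averaging per-fold metrics, is the implemented reading; with
very small classes per-fold MCCs are unstable). Stratification is required
at atlas-style imbalance — plain random folds can lose a small class from
training entirely; classes smaller than the fold count are dealt round-robin
so each sample is still tested exactly once. `optimal_k` is the smallest
prefix achieving the maximum MCC; `efficient_k` is the smallest prefix
within `delta` (default 0.02) of it. The delta formalizes the practical
observation that the MCC curve saturates: nearly all the discriminative
power concentrates in a small head of the ranking, and a classifier using a
quarter of the genes at a percent or two of MCC is the better tool.

## Rules

The final tree is fit on the full dataset restricted to the decision-tree
optimal prefix, SMOTE-balanced by default so minority types get leaves of
their own (the unbalanced mode is exposed; its leaves skew to the majority
class). Each leaf becomes one rule — the conjunction of its root-to-leaf
edge conditions, predicting the leaf majority class. Support and confidence
are computed on the **original** cells, never synthetic ones, so reported
patterns describe real cells; a leaf carved out purely by synthetic points
can therefore report support 0. Rules are ranked by support, then
confidence, then extraction order (the ranking criterion is a package
convention), and capped at the top 1000. The full rule set of one tree is
mutually exclusive and exhaustive, so rule application reproduces the tree's
predictions exactly — the boundary convention `gene ≤ threshold` matches the
tree's split semantics, including values exactly at a threshold.

# The synthetic generator

There is no desk-scale public dataset with known ground truth, so the
package ships a generator that emulates the data regime the pipeline
targets: `n_classes = 6` cell types with sizes drawn log-uniformly between
50 and 1000 cells (imbalance up to 20×, the scaled-down analogue of
atlas-scale imbalance), 500 genes of which 5 per class are planted
class-exclusive markers, zero-inflated negative-binomial counts (baseline
mean 1, dispersion 0.5, dropout 0.3 — typical droplet-data sparsity), and
marker means shifted up by a factor `exp(2)` within their class. Markers are
class-exclusive so recovery metrics are unambiguous. One global seed drives
one named random stream per operation, so each stage is reproducible
independently of how many draws other stages consume.

What the generator does **not** emulate: hierarchical class structure
(subtypes of subtypes), batch effects, gene–gene correlation beyond the
marker shifts, library-size variation, or marker sharing between related
types. Passing recovery tests on this generator therefore demonstrates that
the machinery works as specified — not that it would rank genes well on any
real atlas; on real data the stages' thresholds (MI cutoff, Boruta α, IFS
delta) are the knobs to revisit.

# Numerical choices and degenerate inputs

- MI: zero-probability cells contribute 0; symmetry is exact (the estimator
  only touches the joint table).
- Discretization of a constant gene yields all-`mid`, MI exactly 0, dropped
  by any positive threshold and by the strict inequality even at 0.
- Entropy-tree growth stops at purity, fewer than 2 samples, or best gain
  ≤ 1e−12 (guards float noise); trees are otherwise unpruned, as both MCFS
  and the reference decision-tree implementations default to.
- MCFS train/test splits are stratified at fraction 0.66; a split that
  leaves fewer than 2 classes in training is redrawn up to 10 times, then
  the projection is skipped with a warning.
- Seeds are derived as `(seed mod 524287)·4096 + hash(stream)`, staying
  below 2^31; forests run single-threaded with fixed seeds.
- All TSV artifacts print doubles with `%.17g` and JSON with full precision,
  so write→read round-trips are exact and identical runs are byte-identical.

# Problem sizes used in the shipped validation

The test suite and the acceptance script run the generator defaults
(6 classes, ~2000–3000 cells, 500 genes, seed-determined) end to end —
about 4–5 minutes of compute — and verify: full marker retention through the
MI filter, ≥ 90% marker confirmation with ≤ 5% noise confirmation in the
shadow stage, all 30 markers in the top 60 of the MCFS ranking, IFS(RF)
max MCC ≥ 0.9 with an efficient prefix ≤ 60 genes, and exact rule/tree
agreement. Oracle equivalences (MI, MCC, RI) are checked on thousands of
small random instances at 1e−10…1e−12 tolerances. The byte-identity
(determinism) check runs a compact configuration — 4 classes, 60 genes,
reduced projection counts — twice; determinism is scale-free, so the
compact run checks the same property at a fraction of the cost.

# Known limitations

- The MI stage is univariate: interacting genes invisible marginally are
  only caught later, by the forest-based stages.
- Boruta's importance is Gini-impurity based and inherits its bias towards
  high-cardinality features; with discretization-free continuous inputs
  this is acceptable, but a permutation-importance mode would be the
  natural extension.
- SMOTE interpolates linearly in expression space, which can produce
  fractional pseudo-counts; classifiers downstream are scale-free trees, so
  this is harmless here but the balanced matrices should not be fed to
  count-based models.
- `run_all` resumability is manifest-based (md5 of artifacts + parameter
  JSON); editing an artifact by hand is detected and halts the run rather
  than silently mixing stale and fresh stages.
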