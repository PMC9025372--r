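# cellmark

Marker-gene discovery for multi-class single-cell expression data.

Given a cells × genes expression matrix and a cell-type label per cell,
`cellmark` finds a compact set of genes that discriminates the cell types
and expresses each type's signature as human-readable IF–THEN rules. It is
built for the regime real cell atlases live in: many classes, severe class
imbalance, tens of thousands of mostly uninformative genes, sparse
count-like values.

## The method

Five stages, each narrowing the candidate set for the next:

1. **Relevance filter.** Every gene is discretized into three states
   (below/within/above mean ± σ) and scored by mutual information with the
   label, *I(x, y) = Σ p̂(x,y) log₂ [p̂(x,y) / (p̂(x) p̂(y))]* (bits). Genes
   with *I* ≤ 0.001 are dropped.
2. **Shadow-feature confirmation (Boruta).** Candidates compete against
   permuted copies of themselves in repeated random forests; a gene is
   confirmed when its impurity importance beats the best shadow
   significantly more often than a fair coin (binomial test with two-step
   multiplicity correction), rejected when significantly less often.
3. **Monte Carlo feature selection.** *s* random projections of *m* genes,
   *t* entropy decision trees each; every split node credits its gene with

   RI_f = Σ_τ (wAcc_τ)^u · IG(n_f(τ)) · (no.in n_f(τ) / no.in τ)^v

   (held-out balanced accuracy × information gain × node sample fraction;
   u = v = 1). Sorting RI gives the ranked feature list.
4. **Incremental feature selection.** Nested top-k prefixes (step 5, up to
   1000) are each scored by stratified 10-fold cross-validation — training
   folds SMOTE-balanced to the majority class, test folds untouched — with
   the multiclass Matthews correlation coefficient
   MCC = cov(X,Y) / √(cov(X,X)·cov(Y,Y)) on one-hot label matrices
   (Gorodkin's R_K). The sweep yields the *optimal* feature count (max MCC)
   and the *efficient* one (smallest within 0.02 of the max), for both a
   random forest and a single decision tree.
5. **Rule extraction.** A final entropy tree on the decision-tree-optimal
   prefix is flattened into one rule per leaf (conjunction of
   `gene ≤ t` / `gene > t` conditions → cell type), ranked by support and
   confidence computed on the original cells.

A zero-inflated negative-binomial generator with planted class-exclusive
markers (`simulate_profiles()`) provides ground truth for end-to-end
validation; see the methods vignette (`vignettes/marker-discovery.Rmd`)
for model details, parameter defaults, and design rationale.

## Worked example

```r
library(cellmark)

cfg <- pipeline_config(
  seed  = 1L,
  synth = synth_config(n_classes = 4, class_sizes = c(40L, 80L, 150L, 400L),
                       n_genes = 100, markers_per_class = 4, seed = 1L),
  boruta = boruta_config(n_trees = 50, seed = 1L),
  mcfs   = list(s = 200L, t = 2L),
  ifs_folds = 5L, rf_trees = 50L)

res <- run_all(cfg, "artifacts")
length(res$mi$retained)          # genes past the MI filter
length(res$boruta$confirmed)     # genes confirmed against shadows
head(res$ranked, 5)              # top of the ranked feature list
res$curve_rf                     # IFS curve, random forest
res$rules                        # extracted rules
```

Output (4 planted markers per class, genes 1–16 are the true markers):

```
MI filter retained: 81 of 100 genes
confirmed: 16  rejected: 65  tentative: 0
      gene       ri
1 gene0012 3.329790
2 gene0016 2.873483
3 gene0010 2.753672
4 gene0011 2.626080
5 gene0014 2.365660
IFS curve over 4 feature-subset sizes
  max MCC: 0.8978 at optimal_k = 16
  efficient_k = 15 ( MCC 0.8899 )
Rule set with 84 rules
  [1] IF gene0003 <= 4.011 AND gene0013 > 2.999 AND gene0013 > 3.5
      AND gene0011 <= 12 THEN class = type04 (support=198, confidence=1)
  ...
```

Reading: the permissive MI screen removed only clearly uninformative genes;
the shadow test confirmed exactly the 16 planted markers and rejected the
rest; the Monte Carlo ranking put markers at the top; cross-validated MCC
saturates at 0.90 once all 16 markers are in; and the top rule says "low
gene0003, high gene0013 (a type04 marker) → type04", covering 198 cells at
confidence 1.

Every run writes its artifacts (`ranked_features.tsv`, `ifs_curve.tsv`,
`rules.json`, `rules.txt`, plus per-stage intermediates and a content-hash
manifest) into the output directory; re-running an identical configuration
is a no-op, and identical configurations reproduce byte-identical files.

A command-line interface wrapping the same functions is installed as
`exec/cellmark` (subcommands `simulate`, `filter-mi`, `boruta`, `mcfs`,
`ifs`, `rules`, `balance`, `run-all`).

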