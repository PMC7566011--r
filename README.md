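# treeDEG

Biomarker discovery from **class-imbalanced** tumor/normal expression
matrices, with downstream molecular subtyping. Typical bulk cancer cohorts
have many more tumor than normal samples (e.g., ~370 vs ~50 in
liver-cancer cohorts); standard differential-expression screens and
tree-based importances are both biased by that imbalance. `treeDEG`
implements a selection pipeline built around balanced resampling, for
bioinformaticians who want a small diagnostic gene panel plus the standard
downstream characterization (subtypes, survival, methylation, mutations)
from a single expression matrix.

## Method

Given a non-negative genes × samples matrix with tumor/normal labels, the
pipeline runs:

1. **Preprocessing** — drop genes unexpressed in over 50% of samples;
   min-max normalize each gene to [0, 1]; replace remaining zeros with a
   uniform draw from (0, min/10), where *min* is the gene's smallest
   non-zero value.
2. **Univariate screen** — keep genes with Fisher ratio
   `FR(i) = (μ_i1 − μ_i2)² / (σ_i1² + σ_i2²) ≥ 0.5`
   (class means μ, variances σ²; tumor = class 1).
3. **Redundancy removal** — among surviving genes, any pair with
   |Spearman ρ| > 0.7 is resolved by deleting the member with the lower
   *classified information index*
   `d(i) = |μ_i1 − μ_i2| / (2(σ_i1 + σ_i2)) + ln((σ_i1² + σ_i2²) / (2 σ_i1 σ_i2)) / 2`,
   which stays positive for equal-mean, unequal-variance genes.
4. **Ensemble importance** — build `TN` balanced subsets (all minority
   samples + an equal-size bootstrap of the majority); on each subset `i`
   run a stratified CV and measure, per fold `k`, the validation accuracy
   before (`ACC_ik`) and after (`ACCF_ijk`) replacing gene `j`'s
   validation values by the training-fold mean:
   `FI_ij = Σ_k (ACC_ik − ACCF_ijk) / CV`.
   Each subset's tree votes on every sample; trees are weighted by
   consistency with the majority vote,
   `TreeWeighted_i = [Σ_j I(Tree_ij = Ensemble_j)/S] · Acc_Ensemble`,
   and the final importance is `FI_j = Σ_i FI_ij · TreeWeighted_i`.
   Genes with positive `FI_j` are the selected DEGs.
5. **Panel validation** — hybrid sampling (SMOTE over-sampling of normals,
   k-means medoid under-sampling of tumors) builds balanced datasets; each
   trains a Gaussian naive-Bayes and an RBF-SVM member; samples are scored
   by the tumor-vote fraction and summarized by rank-based ROC/AUC on an
   80/20 stratified split.
6. **Downstream** — Ward clustering of tumor samples on the panel into
   subtypes (pluggable backend, k profiled over 2..8); per-subtype
   representative genes by one-vs-rest Welch t-tests; PCA; Kaplan–Meier
   curves and the k-group log-rank test; expression–methylation Spearman
   correlation (flagging ρ < −0.3); per-subtype mutation enrichment by
   two-sided Fisher's exact test with BH adjustment.

A synthetic-data generator (`synthetic_spec()`, `generate_expression()`,
`generate_survival()`, `generate_mutations()`, `generate_methylation()`)
plants known informative genes, correlated redundant copies, subtypes,
subtype-dependent survival and subtype-enriched mutations, so every stage
is testable without downloads.

## Worked example

```r
library(treeDEG)
spec <- synthetic_spec(seed = 1)           # 2000 genes, 300 tumor vs 40 normal
sim  <- generate_expression(spec)
surv <- generate_survival(sim$truth, spec)
mut  <- generate_mutations(sim$truth, spec)

man <- run_pipeline(sim$matrix, run_config(n_trees = 100, seed = 1),
                    out_dir = "run1", surv = surv, mut = mut)
str(man$results$counts)
#> List of 6
#>  $ genes_in              : int 2000
#>  $ samples               : int 340
#>  $ genes_after_preprocess: int 2000
#>  $ genes_after_fisher    : int 88
#>  $ genes_after_redundancy: int 42
#>  $ n_degs                : int 17
unlist(man$results$auc)
#>    train     test complete
#>        1        1        1
unlist(man$results$logrank)
#>    statistic           df            p
#> 5.104999e+01 2.000000e+00 8.215529e-12
```

Reading the funnel: of 2000 genes, 88 pass the Fisher-ratio screen, 42
survive redundancy removal, and 17 carry positive ensemble importance —
these are the selected DEG panel (written to `run1/degs.tsv` with
importance, up/down regulation and rank). The panel separates tumor from
normal perfectly on the held-out split (AUC 1), and the three subtypes
found on the panel differ strongly in survival (log-rank p ≈ 8e-12, driven
by the planted hazard-ratio-3 subtype).

The same pipeline runs from the shell:

```sh
inst/cli/treedeg simulate --seed 1 --out-dir sim
inst/cli/treedeg run-all --expression sim/expression.tsv --labels sim/labels.tsv \
    --survival sim/survival.tsv --maf sim/mutations.maf --seed 1 --out-dir run1
```

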