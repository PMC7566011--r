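---
title: "treeDEG: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{treeDEG: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`treeDEG` selects diagnostic gene panels from class-imbalanced tumor/normal
expression matrices and characterizes the resulting tumor subtypes. This
vignette explains the statistical machinery, the tunable parameters and
their defaults, what the synthetic-data generator does and does not
emulate, and the design decisions taken where the problem was genuinely
open.

## The selection model

The pipeline treats panel selection as three nested filters of increasing
cost.

**Univariate relevance.** The Fisher ratio
$FR(i) = (\mu_{i1}-\mu_{i2})^2 / (\sigma_{i1}^2+\sigma_{i2}^2)$
is the squared class-mean separation over the summed class variances —
between-class over within-class variance. It is invariant under per-gene
affine maps, so it gives the same ranking before and after min-max
normalization. The default retention threshold is 0.5, with scores exactly
at the threshold kept ("below" is deleted). Variances are unbiased
($n-1$); a `var_method` switch provides the population estimator, since
either convention is defensible and the choice is immaterial at cohort
sizes.

**Redundancy.** Correlated genes carry duplicated information into the
ensemble and would split importance mass across proxies. Pairs with
$|\rho_{\text{Spearman}}| > 0.7$ (mid-rank ties, both classes pooled) are
resolved greedily in decreasing $|\rho|$ order: the member with the lower
classified information index
$d(i) = \tfrac12 |\mu_{i1}-\mu_{i2}|/(\sigma_{i1}+\sigma_{i2}) +
\tfrac12 \ln\!\big((\sigma_{i1}^2+\sigma_{i2}^2)/(2\sigma_{i1}\sigma_{i2})\big)$
is deleted. The second term is a log arithmetic-over-geometric-mean ratio
of the class variances: it is zero when the variances agree and positive
otherwise, so the index can separate equal-mean genes that the Fisher
ratio scores zero. Greedy strongest-pair-first processing makes the result
deterministic; CII ties are broken toward the lexicographically earlier
gene identifier. After the pass, no retained pair exceeds the threshold (a
property the tests verify on correlated synthetic matrices).

**Ensemble perturbation importance.** Each of `n_trees` balanced subsets
takes every minority sample and an equal-size bootstrap of the majority —
the imbalance is corrected per subset rather than by reweighting. The
"tree" is a tree-induction procedure on the subset, not one fixed fitted
tree: a stratified `cv`-fold cross-validation grows a tree per training
fold and records, per fold, the validation accuracy before and after
perturbing one gene. The per-tree importance of gene $j$ is the fold mean
of the accuracy drop; the final importance is the consistency-weighted sum
over trees (each tree's agreement with the majority vote times the
ensemble accuracy). Genes with positive final importance, beyond a $10^{-12}$
tolerance, are the selected panel; negative importances (possible, since a
perturbation can accidentally help) are excluded and logged.

Three points deserve emphasis:

* *Perturbation operator.* "Mean perturbation" replaces the gene's
  validation values with the gene's training-fold mean, which pushes every
  validation sample to one side of any split on that gene. A permutation
  mode (`perturb = "permute"`) is provided; mean perturbation is the
  default because it is deterministic given the folds.
* *Grouped folds.* Bootstrap draws duplicate majority samples; if copies
  of one sample could land in both the training and validation part of a
  fold, the tree would be graded on memorized samples and spurious genes
  would inherit systematically positive importance. Folds are therefore
  assigned per distinct sample, with all copies kept together.
* *Accuracy convention.* $ACC_{ik}$ is validation-fold accuracy (the
  standard choice for perturbation importances), and tree weights are
  computed on the full sample set, switchable in principle but not
  exposed where no use case exists.

Balancing by bootstrap under-sampling is the default; a hybrid mode reuses
the SMOTE + k-means sampler of the validation stage for ensemble training
instead.

## Panel validation

The classifier of record is a voting committee: `n_hybrid_datasets`
(default 9) balanced datasets of `hybrid_size` (default 100) samples are
built from the training split only — `size/2` SMOTE-synthetic minority
vectors (convex combinations of a minority sample and one of its 5 nearest
minority neighbors) and `size/2` k-means medoid representatives of the
majority. Medoids rather than centroids keep features in the observed
value space (a `centroids` switch exists). Each dataset trains a Gaussian
naive-Bayes member and an RBF-kernel SVM member with standard defaults; a
sample's score is the fraction of all members voting tumor (flat pooling
across datasets), the label is the majority with ties toward tumor, and
ROC/AUC uses the mid-rank Mann–Whitney formulation. Test samples are never
synthetic: SMOTE sees only the training split, since leaking interpolated
minority points into evaluation would inflate AUC.

## Downstream characterization

Subtype discovery clusters tumor samples on the selected panel. The
clustering contract is pluggable (`method` may be any
`(matrix, k) -> labels` function); the default is agglomerative Ward
(`ward.D2`) on Euclidean distances — deterministic, tuning-free, and
adequate for the compact subtype blobs the panel exposes. The cluster
count `k` defaults to 3 and is profiled over 2..8 by within-cluster sum of
squares, reported without endorsement; the choice of `k` is the user's.
Representative genes per subtype are the `top_n` (default 100) lowest-p
genes from one-vs-rest Welch t-tests over *all* genes, not only the panel;
zero-variance-in-both-groups genes get p = 1. Survival uses the standard
Kaplan–Meier estimator and the k-group log-rank test (chi-square, k − 1
df). Methylation is related to expression by per-gene Spearman correlation
over inner-joined samples, flagging ρ < −0.3. Mutation enrichment tests,
per gene and subtype (groupwise) or per subtype pair (pairwise), the 2×2
mutated × membership table with two-sided Fisher's exact p, BH-adjusted
within the mode; never-mutated genes are reported with p = 1 untested.

## The synthetic generator

`synthetic_spec()` defines the study the tests run. Defaults: 2000 genes,
20 informative, 50 redundant, 300 tumor vs 40 normal samples, effect size
2, redundancy target ρ = 0.8, three subtypes with mixing 0.54/0.21/0.25,
hazard ratios (1, 1, 3) over a baseline of one event per two years, 30%
uniform censoring, 40 mutation genes of which 5 are enriched (rate 0.5 in
the target subtype vs 0.05 background), 5% dropout.

Expression is log-normal — `exp` of a latent standard Gaussian — giving
the non-negative, right-skewed values the preprocessing stage assumes.
Class and subtype shifts are planted **additively on the observed scale**
in units of the log-normal base's within-class SD, so "effect size 2"
means a literal 2-SD class-mean separation for any two-sample statistic;
planting the shift on the log scale instead would make the observed-scale
Fisher ratio of a nominal 2-SD gene fall below the 0.5 screen, which
contradicts the intended meaning of the effect size. Redundant genes share
their parent's latent Gaussian at the Pearson level
$\rho_P = 2\sin(\pi\rho_S/6)$ (the Gaussian rank-correlation identity;
ranks survive `exp`) and inherit the parent's planted shifts attenuated by
$\rho_P$ — they are genuine informative proxies, which is why selecting
them counts as success in the recovery tests.

Subtype structure lives in two places: round-robin blocks of the
informative genes (so subtypes are discoverable from the selected panel,
as in real tumor cohorts where the diagnostic genes fluctuate by subtype)
and dedicated marker genes outside the panel (the substrate for
representative-gene recovery over all genes). The subtype marker shift
defaults to 3 within-class SDs — strong, on/off-style markers chosen so
that the planted partition is the unambiguous optimum for a
distance-based clusterer under heavy-tailed log-normal noise; at shifts
below ~2.5 the partition itself becomes ambiguous and no clustering
method recovers it reliably. Survival censoring draws from a uniform
horizon solved numerically so the expected censored fraction matches the
target rate under the hazard mixture.

What the generator does **not** emulate: read counts and library-size
effects, batch effects, gene–gene correlation beyond the planted
redundancy, methylation array chemistry, and any real cohort's tail
behavior. Passing tests therefore demonstrate that the implementation
recovers what it plants under a clean noise model — not that the method's
published performance transfers to any particular dataset.

## Numerical choices and degenerate inputs

* Zero replacement draws from the open interval (0, min/10); the
  measure-zero endpoint is resampled so values are strictly positive.
* Constant genes are dropped at normalization (they carry no class
  information and break min-max); constant features are dropped per
  dataset for the naive-Bayes members.
* Zero-variance genes: Fisher ratio scores Inf when the means differ
  (rank-on-top) and 0 otherwise; the CII scores Inf when one class SD is
  zero.
* Whether zeros are replaced before or after normalization is ambiguous in
  principle; the default follows the listed order (filter, normalize,
  replace), and `zeros_before_normalize = TRUE` swaps it.
* Voting and ensemble ties break toward tumor, the majority class.
* Every random stage derives its seed from one master seed by stage-name
  hashing, so adding a stage never perturbs another stage's draws, and
  repeated runs are byte-identical (the manifest records checksums).

## Problem sizes used by the test suite

The recovery experiments run the default 2000-gene, 300-vs-40 cohort with
100 trees and 5-fold CV over 20 seeds; the classifier experiments use the
default nine hybrid datasets of 100; survival power uses 100 replicates at
200 tumor samples; enrichment calibration uses 200 replicates at 350
samples. These sizes were chosen so each experiment's Monte-Carlo error is
small relative to the margins being asserted while the whole suite stays
convenient to run routinely.

## Known limitations

* **The ensemble's importance is not null-calibrated on its own.** The
  final importance is a *sum* over trees, so a single spurious tree with a
  moderate accuracy drop and weight puts a noise gene above any small
  fixed cutoff. If the ensemble is forced to rank a pool of pure noise
  genes, several of them exceed 0.05 in a typical run. In the pipeline
  this does not surface, because the Fisher screen — the method's actual
  null gate — retains nothing under the null; but the ensemble stage
  should not be used as a standalone significance filter, and its positive
  selections inherit meaning from the screen that precedes it.
* **Permutation controls of the classifier need enough held-out minority
  samples.** With 40 minority samples and an 80/20 split, the held-out
  split contains 8 negatives, and the permutation-null AUC has a standard
  deviation of about 0.11 — chance-level behavior then cannot be
  distinguished from mild signal on a single split. Evaluating the control
  on the complete set instead is biased upward by in-sample memorization
  of the SVM members; and scoring a permuted-trained classifier against
  the true labels is systematically *inverted*, because k-means
  under-sampling grants the rare true-normal cluster its own medoids
  inside the pseudo-tumor class. Permutation controls should be read over
  many replicates, not against a fixed narrow band.
* Fisher's exact test is conservative at these counts: the null fraction
  of p < 0.05 sits near 0.035–0.04 rather than 0.05.
* The Ward default is a stand-in for any clustering the user prefers; the
  pluggable contract (`tumor samples → k labels`) is what downstream
  stages consume, and `k = 3` is a reporting choice, not a model-selection
  result.
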