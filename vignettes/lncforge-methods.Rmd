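---
title: "lncforge: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lncforge: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

lncforge scores the cancer potential of intergenic long non-coding RNA
(lncRNA) genes from a 44-feature multi-omics profile, using an
imbalance-aware ensemble of gradient-boosted trees, and explains every
score with additive Shapley-value attributions. This vignette documents the
modelling choices and numerical conventions; the README shows a worked
example.

## Gene models and regions

Annotation is ingested from GTF (1-based, closed intervals) and converted
to the package-internal convention: **0-based, half-open** intervals, the
same convention as BED. Each gene model carries its transcripts and exons;
`derive_regions()` produces three strand-aware region sets per gene:

* **promoter** — the 1 kb window upstream of the TSS (truncated at
  coordinate 0),
* **gene body** — the gene span minus the promoter (the promoter can split
  the body in two when it lies inside the span),
* **merged exons** — the union of all transcript exons.

Genes overlapping a protein-coding annotation can be removed at parse time
(`pcg_gtf=`), so the universe contains intergenic lncRNAs only.

## The 44 features

`feature_specs()` is the authoritative registry: 15 epigenomic, 13 genomic,
6 transcriptomic, 3 phenotype, 3 network and 4 mutation features. Each
operator is a small, separately tested function; `build_feature_table()`
assembles the genes × 44 matrix and fills registry defaults (0 everywhere;
0.5 for the replication-timing S50, its all-zero-signal midpoint) for
absent inputs or uncovered genes. Conventions worth calling out:

* Histone-mark peak width counts the **full** width of every overlapping
  peak, averaged over samples.
* Conservation uses the *mean0* convention: the per-base score sum divided
  by the total region length, with uncovered bases contributing 0.
* Tissue specificity is the tau index over per-tumor-tissue mean
  expression; all-zero expression yields tau 0.
* The exonic mutation odds ratio compares exons against
  (span − exons) ∪ promoter with Haldane +0.5 pseudocounts.
* Gene-level copy number is the overlap-length-weighted median per sample,
  averaged over covering samples.
* `kmer_pc1` and `secondary_structure_pc1` are first principal-component
  scores with a deterministic sign (largest-magnitude loading positive).

## Imbalance-aware ensemble

The positive class is rare (the default synthetic setup mirrors a
285:1661 imbalance). The core strategy is **EasyEnsemble**: negatives are
partitioned at random into `ceil(N_neg / N_pos)` groups, each padded to
exactly `N_pos` by drawing from the remaining negatives, and one classifier
is fitted per balanced subset (all positives + one group). The ensemble
score is the mean member probability, so every negative informs at least
one member while each member sees a balanced problem. Alternative
strategies (raw, class weights, random/SMOTE oversampling, random
undersampling) and base learners (logistic, random forest, naive Bayes,
kNN, SVMs, a feature-blind prevalence null) are available for the
`strategy_leaderboard()` comparison.

The boosted-tree learner is xgboost configured to match leaf-wise boosting:
`max_leaves = 45` with `grow_policy = "lossguide"`, `max_depth = 10`,
116 rounds, learning rate 0.1, histogram trees, one thread. Model selection
uses stratified 5-fold cross-validation with AUPRC as the primary score —
the metric of choice under heavy imbalance — and all resampling happens
inside training folds only.

## Thresholds and metrics

`auroc()` is the rank-based Mann-Whitney statistic (ties counted ½);
`auprc()` is the step-sum average precision. The decision rule is
`score >= threshold`. Two selectors are provided:

* `max_f1_threshold()` — exhaustive scan over unique scores; F1 ties go to
  the **larger** threshold.
* `np_threshold()` — Neyman-Pearson selection: the smallest candidate
  threshold (unique scores ∪ +Inf) whose empirical false-positive rate on
  the training negatives is at most `alpha`. With fewer than `1/alpha`
  negatives the control is necessarily coarse and a warning is issued.

## Additive attributions

Per-member attributions come from the tree-path (TreeSHAP) algorithm of the
boosted trees, computed on the margin scale and rescaled **linearly** to
the probability scale:

$$\phi^{p}_j = \phi^{m}_j \cdot
  \frac{\sigma(m) - \sigma(b)}{m - b},$$

where \(m\) is the margin, \(b\) the bias term and \(\sigma\) the logistic
function. The rescaling is exact for each gene — base value plus
contributions equals the member probability — and because the ensemble
score is the *mean* member probability, additivity carries over to the
ensemble without approximation (`base + Σ contrib = score`, residual below
1e-6; the residual is float32 rounding from the tree library). Whether to
attribute in probability or log-odds space is a genuine design choice; we
chose probability space because ensemble averaging is linear there,
preserving additivity.

Downstream tools: `feature_importance()` (sum of |SHAP| across genes),
`gene_report()` (per-gene top contributions), `feature_groups()`
(complete-linkage clustering at distance 1 − |r|, cut so that within-group
pairwise |r| ≥ 0.1; the group count is emergent, not fixed),
`feature_ablation()` (drop in CV AUPRC when a unit is removed, identical
folds and seed), `random_positive_null()` (+1-corrected permutation
p-values against fake positive sets) and `positive_size_curve()`.

## The synthetic cosmos

`generate_feature_table()` draws i.i.d. Gaussian features and shifts the
positive class of each configured **effect family** by a standardized
amount: by default `mfe = -1` (structure MFE), `abs_logfc = +1.2` (the
*magnitude* of the expression log-fold-change, with random sign),
`degrees = +1` (all three network centralities) and `peak_width = +0.8`
(all eleven histone-mark widths) — 16 informative features out of 44. A
family keys its natural registry members; any single feature name is also
accepted as a key.

`generate_cosmos()` writes a complete raw-input directory — GTF, genome
FASTA, peak/super-enhancer/methylation/repli-seq/conservation/repeat
tables, expression and structure tables, screen, interaction, variant and
CNV layers, label lists and a `truth.json` — such that running the real
ingestion and feature code on the files reproduces the same standardized
family shifts (verified within 3 SE at ≥500 genes). Shifts are planted
through gene-level latent variables (for example a per-gene peak-width
latent shared across marks and samples) so that the file-derived features
inherit the intended location shifts after the operators' aggregation. The
`mrna_centrality` shift is planted directionally through a shared
expression factor; its realized magnitude depends on the co-expression
power transform and is validated as directional only. Everything is a
deterministic function of the seed: the same configuration produces
byte-identical files.

One calibration caveat, verified empirically: with all effect sizes zero,
the cross-validated AUPRC concentrates slightly **above** the class
prevalence. This is the well-known positive finite-sample bias of average
precision under random ranking, not signal leakage; at 285/1946 the bias
is ≈ +0.015. Null calibration checks should therefore compare against a
label-permutation chance level rather than raw prevalence when the
tolerance is tighter than this bias.

## Determinism

All randomness flows from user-supplied seeds through `derive_seed(seed,
label)` (a splitmix-style hash onto `[0, 2^31)`), and `with_seed()`
restores the caller's RNG state, so library calls never perturb user
randomness. Cross-validation folds, ensemble subsets, resampling, the
cosmos and the CLI are all reproducible bit-for-bit given a seed.
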