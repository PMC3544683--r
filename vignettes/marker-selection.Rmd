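---
title: "Ranking and selecting RISH markers that separate NTAC from NTAB"
author: "rishSelect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking and selecting RISH markers that separate NTAC from NTAB}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rishSelect)
```

## The problem

Normal-looking tissue at the resection margin of a malignant tumor can
already be molecularly abnormal (field cancerization). Given a
tissue-microarray cohort in which each sample is normal tissue adjacent
either to a cancer (NTAC) or to a benign tumor (NTAB), and a panel of
tumor-related genes assayed by RNA in situ hybridization (RISH), we want
to know which genes — alone or in combination — discriminate the two
kinds of "normal".

The data unit is an ordinal score per (sample, gene): the sum of a
positive-cell ratio category (0: <25%, 1: 25–50%, 2: 51–75%, 3: >75% of
cells stained) and a staining-density category (0 no staining, 1 light,
2 deep, 3 black), so every score lies in {0, …, 6}. The published ratio
bins leave their boundaries ambiguous; `ratioScore()` resolves them as
[0, 0.25) → 0, [0.25, 0.50] → 1, (0.50, 0.75] → 2, (0.75, 1] → 3, a
convention chosen so that every fraction maps to exactly one category
while all printed anchor points keep their printed categories. Whether
an original scorer would have put exactly 50% in category 1 or 2 is
unknowable from the text; the choice matters only on a measure-zero set
of fractions.

## The analysis pipeline

Three steps, mirroring how such screening panels are analyzed:

**1. Per-gene testing.** `wilcoxonRankSum()` compares NTAC and NTAB
score distributions. With a 7-letter alphabet, ties are massive, so the
implementation uses midranks throughout and the tie-corrected null
variance

$$\mathrm{Var}(W) = \frac{n_1 n_2}{12}\Big[(N+1) -
  \frac{\sum_t (t^3 - t)}{N(N-1)}\Big],$$

with a 0.5 continuity correction on the standardized statistic. For
pooled samples of at most 20 the exact two-sided permutation P is
computed by full enumeration of the $\binom{N}{n_1}$ group assignments
of the pooled midranks; beyond that the normal approximation is used
(`method = "auto"` switches at 20). Both are exposed because at these
tie densities the two can disagree substantially in small samples: the
permutation distribution is discrete with steps much larger than
conventional approximation error, so the exact path is authoritative
whenever it is feasible. Direction calls in `differentialPanel()`
(over/under-expressed in NTAC) use the mean score difference gated on
the raw P at `alpha`; a Benjamini–Hochberg column is reported alongside
but deliberately does not drive the calls, matching the screening
character of the analysis.

**2. Filter ranking.** `rankGenes()` orders the panel by one of four
classical per-feature separability criteria: pooled two-sample |t|
(Welch available by flag), symmetric Kullback–Leibler divergence between
Gaussian fits, Bhattacharyya distance between Gaussian fits, and the
rank-sum |z|. The Gaussian-fit criteria treat the ordinal scores as
continuous, as classical filter toolboxes do. Class variances are
floored at ε = 1e−9 because an ordinal column can be constant within a
class, where the Gaussian criteria are otherwise undefined; the floor
turns such columns into large-but-finite scores instead of infinities.
The symmetric (two-directional) form of the KL divergence was chosen for
the "entropy" criterion — the one-directional form would make the
criterion depend on an arbitrary class order, which no ranking should.
Score ties are broken by original panel order so rankings are
deterministic across platforms.

**3. Wrapper selection.** `incrementalSelection()` starts from an empty
gene group and adds genes one at a time in filter-rank order, re-scoring
the group after every addition until the whole panel is included;
`bestSubset()` returns the subset with the highest mean cross-validated
AUC (ties: smaller subset, then earlier position). The score of a subset
(`cvAUC()`) is the mean over repeats of fold-averaged AUCs under
stratified 10-fold cross-validation: per fold, features are standardized
on the training rows only, a linear soft-margin SVM (cost 1) is fitted,
and the held-out *decision values* — signed distances to the separating
boundary — are scored by the Mann–Whitney AUC with half-credit for ties
(`aucFromScores()`). Decision values, not hard labels, feed the AUC:
label-based "AUC" collapses to balanced accuracy and loses the ROC
interpretation that makes AUC robust to the 244/70 class imbalance.

The classifier is fixed to a linear kernel with cost 1 by default
(`classifierSpec()`): with at most 15 ordinal features and
314 samples, a linear maximum-margin model is the minimal choice that
exercises the wrapper, and both cost and standardization are exposed for
sensitivity analysis. Fold assignment is a function of (sample IDs,
class labels, seed) only — within each class, samples are taken in ID
order and folds permuted by the seeded RNG, repeat *r* using
`seed + r` — so results are invariant to the row order of the input and
fully reproducible from the seed.

## The synthetic cohort generator

Patient-level score matrices for this design are not publicly
deposited, so validation runs on synthetic cohorts that emulate the
study structure. `defaultDesign()` fixes the cohort composition to the
printed case counts — hepatocellular carcinoma 26, rectal adenocarcinoma
48, esophageal squamous cell carcinoma 34, gastric adenocarcinoma 66,
thyroid carcinoma 32 and breast carcinoma 38 (adjacent tissue NTAC,
244 cases), thyroid adenoma 32 and breast fibroadenoma 38 (NTAB,
70 cases) — 314 cases in eight tumor groups over six organ sites. The
abstract-level description of "seven" adjacent tissue types versus the
eight printed groups is an internal inconsistency of the source
material; the generator follows the eight printed groups, which are the
only machine-usable statement of the composition. Class counts are
taken verbatim from the design, never resampled.

Per gene, scores are drawn independently from a class-conditional
distribution over {0..6} (`GeneEffect`). The calibrated family
(`latentEffect()`) discretizes a latent Normal(shift · class, 1) through
8 fixed cut points (−∞, ±2.5, ±1.5, ±0.5, ∞): at shift 0 the score
distribution is symmetric around 3 with SD ≈ 1, roughly mid-scale
staining with realistic spread; a single monotone shift parameter
controls separability, so `effectFromAUC()` can calibrate a gene to any
target pairwise AUC up to ≈ 0.997 by bisection against the *exact*
analytic AUC (`analyticAUC()`, a 7 × 7 summation — the oracle used
throughout the tests). Tissue identity does not alter score
distributions by default, since the modeled comparison pools all NTAC
against all NTAB; a `tissueEffect` hook exists for robustness studies.
Reproducibility uses one master seed with per-gene substreams (a fixed
affine map into seeds modulo 2³¹ − 1), so appending a gene to the panel
never perturbs the other genes' draws.

What the generator does *not* emulate: within-patient correlation
across genes (scores are independent given class), per-tissue
heterogeneity, duplicated-core measurement error, missing cores, and
scorer drift. Passing tests therefore demonstrate that the statistical
machinery is correct and well-calibrated under the stated sampling
model — not that real RISH cohorts satisfy that model.

## Numerical and design choices

- **Exact-test capacity.** Full enumeration is capped at pooled n = 20
  (184 756 assignments), past which `method = "auto"` switches to the
  tie-corrected normal approximation; requesting `exact` beyond the cap
  is an explicit capacity error rather than a silent fallback.
- **Variance/SD floors.** ε = 1e−9 on class variances in the filter
  criteria; 1e−8 on feature SDs in per-fold standardization and the
  heat-map z-scale, so constant features map to zeros rather than NaN.
- **Heat-map export.** `zscaleForHeatmap()` standardizes each gene with
  the sample-SD (n − 1) convention and clips to [−3, 3], the
  conventional display scale; clustering order is not computed because
  no linkage/distance is part of the modeled procedure.
- **Output formatting.** The pipeline writes P values in scientific
  notation with six digits and AUCs with four decimals, making repeated
  runs byte-identical and regression-testable.
- **Degenerate inputs.** Identical groups give z = 0, p = 1; a pooled
  sample with a single distinct value carries no rank information and
  is reported the same way.

## Known limitations

- **Weak single markers under a margin classifier.** For a single
  weakly informative ordinal feature under the 244/70 imbalance, the
  soft-margin SVM shrinks its weight toward zero and its decision
  values become uninformative, so the cross-validated AUC of genes with
  true pairwise AUC ≲ 0.75 collapses toward — and can fall below — 0.5.
  This is a property of the specified estimator, not a bug: weak
  markers are never *inflated*, and single-gene AUC profiles should be
  read as "what a linear SVM can exploit", not as the pairwise score
  AUC (use `aucFromScores()` on raw scores for that). Separability
  ordering is reliably recovered from analytic AUC ≈ 0.75 upward.
- **Normal vs exact P in small samples.** The discrete permutation
  distribution means the normal approximation can differ from the exact
  P by far more than conventional tolerances in heavily tied small
  samples; the exact method should be used (and is, by default) for
  pooled n ≤ 20.
- **No multiplicity control in the headline path.** Direction calls use
  raw P at α, matching the screening design; the BH column is
  informational.

## Problem sizes used by the validation suite

The test suite validates at the following scales, chosen to exercise
the study-sized design while keeping a full run on a single CPU
comfortable: 500 random tied datasets (pooled n ≤ 12) for exact-test
oracle equivalence; exhaustive AUC pair-counting over all score lists
of length ≤ 4 on a 3-letter alphabet; 2 000 null genes at the 244/70
design for type-I calibration; and 100 replicate cohorts with one gene
calibrated to analytic AUC 0.87 for recovery — ranking checked for all
four criteria per replicate, single-gene CV AUC at the full 10 × 10
cross-validation, and the full 15-step selection trace at 2 repeats of
10 folds, the package's standard replication-study setting for traces.

## Session info

```{r}
sessionInfo()
```
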