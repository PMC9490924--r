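---
title: "Spatial TME features from patch-level tissue maps: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial TME features from patch-level tissue maps: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmescan)
```

# What this package computes

`tmescan` starts where a patch-level tissue classifier ends. A lung-cancer
H&E slide, tiled into non-overlapping square patches (87 µm, i.e. 172 px at
~0.506 µm/px) and classified patch-by-patch into nine classes — tumor,
stroma, mixed, immune, vessel, bronchi, necrosis, lung, background — becomes
a *label grid*: a 2D map of integer codes 0–8. From such grids the package
computes interpretable slide-level descriptors of the tumor
microenvironment (TME) and feeds them into two outcome models: survival
(Cox proportional hazards, Kaplan–Meier stratification) and per-gene
mutation-status classification.

The five spatial features are:

* **Tissue prevalence (TIP)** — $t_i = n_i / N$, the fraction of tissue
  class $i$ among all $N$ non-background patches of the slide.
* **TME composition (TMEC)** — $m_j = b_j / B$ over the non-tumor tissue
  classes $j$, where $b_j$ counts class-$j$ patches among the 8-connected
  neighbors of tumor patches and $B = \sum_j b_j$.
* **ITLR** — $b_{\mathrm{IMMUNE}} / n_{\mathrm{TUMOR}}$, the patch-wise
  intra-tumor lymphocyte ratio.
* **Shannon index** — $-\sum_i t_i \log t_i$ (nats).
* **Simpson index** — $\sum_i t_i^2$.

# Upstream image handling

The tiling/filtering/normalization stage is resolution-driven, not
format-driven: any RGB raster works. Three contracts matter.

**Relevance filter.** Each patch is converted to grayscale by the Rec. 601
luma $0.299R + 0.587G + 0.114B$, *unrounded* (rounding to 8-bit grayscale
first would move pixels across the threshold; the unrounded choice is
documented so reference values stay stable). Pixels with luma < 200 count
as black, the rest as white, and a patch is kept iff black/white > 0.05,
strictly. A patch with no white pixels at all is kept: it is tissue-dense
and the ratio is undefined there — declaring it irrelevant would discard
exactly the most informative patches.

**Color normalization.** Reinhard-style transfer in the Ruderman
$\ell\alpha\beta$ space: RGB → LMS → $\log_{10}$ → decorrelated axes; each
channel is shifted/scaled to the reference image's mean/sd and mapped back.
Two numerical choices: (i) channel statistics use the population form
(denominator $n$), so duplicating an image never changes its statistics;
(ii) the LMS→RGB matrix is the exact numerical inverse of the forward
matrix rather than the independently rounded 4-decimal inverse that
circulates in the literature — with the rounded pair, the identity
transform already drifts by up to ~2 channel units per round trip, which
would break the contract that normalizing an already-matching patch is a
no-op within 8-bit tolerance. A reference with any zero-variance channel is
flagged degenerate and its sd floored; a zero-variance *patch* channel is
set to the reference mean instead of dividing by zero. Normalization is
applied per patch, not per slide.

**Labeling and uncertainty.** Per-patch class probabilities are labeled by
argmax with exact ties broken toward the lowest class code (deterministic
and testable; ties are measure-zero for real classifier output).
Uncertainty is the predictive entropy $-\sum_c p_c \ln p_c$ in *nats*: on
this scale the conventional per-class "needs more training data" threshold
of 1.5 sits sensibly below the maximum $\ln 9 \approx 2.197$, whereas in
bits the maximum is 3.17 and in log10 only 0.95. Class-wise medians use the
lower-median convention for even counts, again for stable reference values.

# Feature-counting conventions

* **Neighborhood**: the 8-connected ring (Chebyshev distance 1). The margin
  around tumor is exactly one patch ring.
* **Multiplicity**: every tumor patch is considered separately, so a
  non-tumor patch adjacent to $k$ tumor patches contributes $k$ to its
  class count $b_j$. This follows the literal per-tumor-patch summation; a
  `unique_neighbors = TRUE` switch counts distinct patches instead, for
  users who prefer the set-based reading. The 1×3 grid
  `[TUMOR, IMMUNE, TUMOR]` separates the two: multiplicity gives
  $b_{\mathrm{IMMUNE}} = 2$, unique counting gives 1.
* **ITLR denominator**: the whole-slide tumor patch count
  $n_{\mathrm{TUMOR}}$ (the formula's denominator), not the immune-side
  count — so ITLR can exceed 1 on slides with small scattered tumor areas.
* **Undefined values**: a slide with no tumor patches (or tumor patches
  with no qualifying neighbors) has *undefined* TMEC/ITLR, surfaced as `NA`
  sentinels, never as silent zeros — zero is a meaningful value (e.g.
  "tumor present but no immune contact").
* **Per-patient aggregation**: a patient's feature vector is the unweighted
  mean across their slides; slides with undefined TMEC/ITLR are excluded
  from those columns only. With typical cohorts carrying 1–2 slides per
  patient, weighting by slide size would let a single large slide dominate
  without evidence it is more representative.

# Cohort preparation

Clinical covariates use fixed encodings: age dichotomized at 65; sex male
= 1; smoking collapsed to non-smoker / light / heavy (heavy = ≥ 30 pack
years or current smoker; the free-text reformed-smoker categories resolve
the missing-pack-years cases); stage grouped early (I/Ia/Ib), locally
advanced (II/IIa/IIb/IIIa), advanced (IIIb/IV). Anything unmappable drops
the row loudly with a logged reason. Cohort-specific exclusions (the kind
of demographic cleaning some studies apply) are deliberately *not*
hard-coded; a generic `row_filter` predicate does that job and logs what it
removed. Genes are kept only with ≥ 16 mutation carriers — expressed as
"at least 16" to make the complementary "up to 15 → drop" boundary
explicit. The four tables (features, clinical, survival, mutations) meet in
an inner join on patient id with per-step row logging.

# Survival modeling

**Cutpoint stratification.** For each feature the package scans every
midpoint between consecutive distinct values whose split leaves at least
`minprop = 0.1` of patients on each side (a conventional search bound; the
method is otherwise unstable in the tails, and the bound is configurable).
Each split is scored by the standardized two-sample log-rank statistic,
computed for all candidates at once from per-event-time hypergeometric
moments; the cutoff maximizing $|z|$ wins, ties toward the smaller value.
Because the maximum over many correlated splits inflates significance, the
reported selection-adjusted p-value comes from a seeded permutation test
(default 1000 permutations) of the feature values — exact at this scale
and free of special-function approximations; the classical asymptotic
correction could be added later. The screen deliberately learns the cutoff
on the full cohort before the Kaplan–Meier comparison (matching common
practice for cutpoint discovery); the log-rank p of the resulting split is
therefore optimistically biased, which is why the permutation p is reported
alongside and the screen's Benjamini–Hochberg control (default FDR 0.1
over the 15 TIP and TMEC composition features) should be read as a
descriptive ranking. Binarization is strict: "high" means value > cutoff.

**Cox models.** Fitting is by `survival::coxph` with Efron tie handling
(the standard default of the survival ecosystem) and the library's
standard convergence control; monotone-likelihood fits (infinite
coefficients under perfect separation) are flagged via captured warnings
rather than silently reported. Categorical covariates expand against
declared basal levels — female, early stage, non-smoker, wild-type — whose
hazard ratio is reported as exactly 1. Because TIP entries sum to 1 (and
TMEC entries likewise), one column per composition vector is linearly
redundant in a proportional-hazards design; the normal-lung column is
treated as the reference tissue and omitted from Cox designs (penalized or
tree-based classifiers keep all columns). Model discrimination is
Harrell's c-index; cross-validation uses k = 10 folds stratified by event
status (unstratified folds can land all events in one fold for small
cohorts), scores held-out patients by the training-fold linear predictor,
and reports the *median* across folds.

# Mutation classification

Per gene, a binary classifier is trained on a feature-set variant
(clinical, clinical + each scalar metric, clinical + TMEC, clinical + TIP,
clinical + both, or TMEC alone). Class imbalance is handled by
oversampling: minority rows are duplicated — whole cycles
deterministically, the remainder by a seeded draw — until counts are equal.
Balancing happens *inside the training split of each fold only*: balancing
before fold assignment would place copies of training rows into test folds
and inflate every reported AUC. The balanced-set provenance index makes
this auditable. Two learners are compared: L2-penalized logistic regression
(ridge, iteration cap 2000; importances are the signed coefficients) and a
100-tree random forest with Gini splitting and sqrt-feature subsampling
(importances are mean Gini impurity decrease, normalized to sum to 1).
Both are established implementations (glmnet, randomForest) behind the
package's harness; the harness, balancing, metrics and importances are
verified against independent oracles in the test suite. The default metric
is ROC AUC in its Mann–Whitney form (ties half); an average-precision
PR-AUC switch is provided for rare genes where ROC optimism matters. The
full protocol repeats the 10-fold CV 100 times with fresh seeded fold
assignments and averages over all repeats × folds; the examples and checks
in this package run scaled-down protocols (5–10 repeats, cohorts of
120–1000 patients) chosen so the whole suite completes in minutes while
keeping Monte-Carlo error well inside the asserted margins.

# The synthetic cohort generator

Every downstream stage is testable without any image download because the
generator produces all inputs with known ground truth:

* **Label grids** — an all-background border ring around an interior
  filled by seeded multi-source region growth: classes receive integer
  patch quotas by largest-remainder apportionment of the target prevalence
  (so realized fractions match targets to within one patch per class), and
  each step either grows a class from its region frontier or, with
  probability $e^{-\text{contiguity}}$, jumps to a new blob seed. Large
  contiguity gives the large contiguous regions real segmentations show;
  contiguity → 0 gives speckle. Real cohorts constrain only median
  prevalences, not blob-size statistics, so contiguity is a free knob with
  default 5.
* **Probability tables** — the true class receives `confidence`, the rest
  is spread with Dirichlet jitter (per-component concentration 10, a mild
  near-even spread chosen so that as confidence approaches the uniform
  limit 1/9 the rows approach the uniform distribution and their mean
  entropy approaches $\ln 9$).
* **Patch images** — dark (hematoxylin-like, luma ≈ 87) and light
  (glass-like, luma ≥ 225) pixels with an exact dark-pixel count, so the
  relevance filter's 0.05 boundary can be swept to single-pixel precision.
  No attempt is made at realistic H&E texture.
* **Cohorts** — per patient, class mixtures are Dirichlet-distributed
  around the target prevalence with concentration `prevalence_dispersion`
  (default 4; real cohorts show strong slide-to-slide compositional
  variability). The tumor share is clamped to [0.05, 0.95]: diagnostic
  slides of a tumor cohort always contain tumor and are never tumor-only,
  and the clamp keeps TMEC/ITLR defined on every simulated slide. Features
  are computed from the generated grids by the package's own feature code,
  so the ground-truth hazard acts on the *realized* features. Survival
  times are exponential with rate
  $\lambda_0 \exp(\sum \beta_k x_k)$ ($\lambda_0$ defaults to a two-year
  median), censored by an independent uniform time whose upper bound is
  solved numerically so the expected censored fraction hits `censor_frac`
  (default 0.25) — uniform censoring is standard, and the numeric solve
  avoids closed-form assumptions. Mutations are Bernoulli with a logistic
  model on the same design; clinical covariates come from documented
  categorical defaults (sex and age Bernoulli(0.5), smoking 0.2/0.4/0.4,
  stage 0.5/0.35/0.15), all overridable.

All randomness flows through one seed per run with sub-seeds at fixed
offsets, so identical configurations are byte-identical; the generator
restores the caller's RNG state.

What passing tests on this generator do **not** show: the grids have no
classifier error structure (real segmentations err non-uniformly, e.g.
mixed-vs-tumor confusions), no staining artifacts, and no spatial
correlation between feature noise and outcome; parameter-recovery results
quantify estimator correctness, not real-data effect sizes.

# Problem sizes and runtime choices

The package's checks run parameter recovery at n = 1000 patients, null
calibration at 200 replicates × 99 permutations, signal-vs-null model
comparisons at n = 300–400 with 10-fold CV and 5 repeats, and oracle
equivalence on 50 random grids — sizes at which the asserted bounds hold
with comfortable Monte-Carlo margins while the whole suite runs in a few
minutes on one core.

# Known limitations

* No pyramidal WSI formats (SVS/NDPI); plain rasters only. Macenko and
  Vahadane normalizations are out of scope.
* No CNN training or inference: the classifier producing the probability
  tables is upstream and external.
* No cell-level metrics — the spatial features are deliberately
  patch-wise.
* No time-varying covariates, stratified Cox, or competing risks.
* The cutpoint screen's log-rank p-values inherit cutoff-selection
  optimism by design (see above); use the permutation p for inference.
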