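---
title: "Benchmarking connectome-derived biomarkers: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking connectome-derived biomarkers: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connbench)
```

## The question the package addresses

Functional connectivity — the parcel-by-parcel Pearson correlation of
resting-state fMRI time series — is a leading biomarker candidate for
schizophrenia, but it is enormously high-dimensional (a 1000-parcel atlas
yields 499,500 edges). Low-dimensional summaries have been proposed as
alternatives: macroscale cortical *gradients* (principal axes of the
connectivity matrix, ordering parcels from unimodal to transmodal cortex) and
*gradient dispersion* (how tightly parcels or networks cluster in gradient
space). `connbench` implements a complete comparative pipeline that asks:
which feature family — raw edges, gradients, neighborhood dispersion, or
centroid dispersion — carries the most case-control signal, and which of a
broad suite of classifiers exploits it best?

Because real multi-site clinical fMRI cannot ship with a package, the
pipeline is exercised end-to-end on synthetic cohorts with *planted* group
effects, where ground truth is known and recovery can be scored exactly.

## Synthetic cohorts

`generate_cohort()` simulates each subject's parcel-wise time series (default
150 samples, emulating short clinical scans of a few minutes) from a
multivariate normal whose covariance has a canonical block structure: within-
network covariance 0.35, between-network 0.05, unit diagonal, seven networks
named after the canonical resting-state systems. The subject's connectivity
matrix is the Pearson correlation of that series, so every matrix is
symmetric, unit-diagonal and positive semi-definite by construction — values
are never edited directly, which could break those invariants.

Group effects are planted in the *latent* covariance before simulation:

* **Edge hypoconnectivity** — case-group covariance at a designated edge set
  is lowered by `delta` (correlation units). `plant_edges()` draws
  within-network pairs with at most two planted edges per parcel; by
  Gershgorin's bound this keeps the shifted covariance positive definite, so
  no eigenvalue clipping (which would attenuate the planted effect) is
  needed. The realized effect is measured post hoc with
  `measure_edge_effect()`.
* **Gradient contraction** (optional) — between-network covariance in cases
  is raised by `contraction`, reducing functional differentiation.

Between-subject heterogeneity uses a mean-one multiplicative blend
`Sigma_subj = c * Sigma_group + (1 - c) * I`, `c ~ N(1, noise_sd)` truncated
symmetrically at three standard deviations. Where a strong planted effect
leaves little spectral slack, the jitter SD is *shrunk* rather than truncated
one-sidedly: one-sided truncation would make `E[c] < 1` and silently bias the
planted effect downward.

Covariates mirror the demographic imbalances of multi-site clinical samples:
cases average ~4 years older, are more often male, move more (mean framewise
displacement, mm), and sites differ mildly in group composition; roughly 6%
of subjects are high-motion movers. `filter_by_motion()` excludes subjects
with mean FD strictly greater than the threshold (default 0.5 mm) — a subject
at exactly 0.5 mm is retained.

What the generator does **not** emulate: temporal autocorrelation and
physiological noise, scanner-specific spatial covariance, spatial
autocorrelation of parcels on the cortical sheet, diagnosis-correlated
residual motion artefacts after filtering, and heavy-tailed or non-Gaussian
BOLD fluctuations. Passing tests therefore demonstrate that the pipeline's
*mechanics* (feature construction, selection, evaluation, localization)
behave correctly and recover known signal — not that any feature family wins
on real clinical data.

## Gradients

Per subject: Fisher z-transform (diagonal zeroed first), density
thresholding, PCA, Procrustes alignment.

* **Thresholding** is row-wise: each parcel keeps its top 10% connections
  (including the sign-aware ordering, so negative values are discarded
  first), producing an asymmetric sparse matrix. This follows the gradient
  literature's convention; a global variant is available via
  `scope = "global"` because the alternative reading ("discard the lowest 90%
  of all values") is also defensible.
* **PCA** is applied directly to the thresholded z-matrix with parcels as
  observations and connectivity profiles as (column-centered) variables. No
  cosine-affinity kernel is inserted — the embedding is the PCA of the
  thresholded matrix itself. Column centering is the statistical default;
  the choice is configurable in spirit by pre-processing the input.
* **Sign convention**: within each component the loading of largest absolute
  value is made positive. Eigenvectors are otherwise sign-indeterminate and
  reproducible tests need a fixed orientation.
* **Dimensionality**: the full-scale convention is D = 200 components at
  P = 1000 parcels (D = P/5); smaller synthetic parcellations scale D
  proportionally, with a floor of 3 so centroid dispersion stays defined.
* **Alignment**: orthogonal Procrustes (rotation + reflection, no scaling or
  translation) to a reference embedding — the gradients of the mean
  control-group matrix of a separate seeded reference cohort, standing in
  for a large external group template. Allowing reflections and excluding
  scaling is the standard orthogonal Procrustes problem; scaling would
  distort dispersion values, which are distance-based.

## Dispersion measures

**Centroid dispersion** works in the 3-dimensional space of the first three
gradients. A network's centroid is its per-dimension median (the *lower*
median for even counts, so the centroid is deterministic); within-network
dispersion is the sum of squared Euclidean distances of the network's parcels
to that centroid, and between-network dispersion is the distance between
centroids. Seven networks give 7 + 21 = 28 values per subject.

**Neighborhood dispersion** of a focal parcel is the mean Euclidean distance
to its K nearest neighbors in the embedding spanned by the first d gradients,
neighbors excluding the parcel itself, exact search, ties at the K-th
distance broken by parcel index. The feature grid runs over *nested leading*
gradient subsets d = 1..D and a ladder of K values — that nesting is the only
reading under which P = 1000, D = 200 and five K values produce the
conventional 1,000,000-value grid. The default ladder is
{10, 50, 110, 140, 170}; an evenly stepped ladder {10, 50, 90, 130, 170}
(step 40) is available via `k_ladder("even")` because both appear in the
literature this design follows, and they disagree. For small synthetic
parcellations the ladder is truncated to K < P. Grid cells are computed
incrementally (running squared distances over dimensions, one sort per
parcel per d), and a property test asserts grid-wise equals cell-wise
computation exactly.

## Blockwise PCA and permutation importance

Features are concatenated in the fixed block order
`conn | grad | disp_nbr | disp_cntr`. Covariates — age (years), sex, one-hot
site, mean FD (mm) — ride alongside and are never PCA-compressed and never
permuted.

The cohort is split by stratified sampling into train (75%) and holdout
(25%), preserving the case/control ratio on both sides. Each block is then
compressed by PCA *fitted on training rows only*: the smallest number of
components (at least 2) reaching 20% cumulative explained variance; the
centroid-dispersion block keeps all its components since it is already small.
A leakage test corrupts holdout rows and asserts the fitted model and the
training-row projections are bit-identical.

An L2-regularized logistic regression (glmnet, `alpha = 0`,
`lambda = 1/n_train`, i.e. unit penalty strength in the scikit-learn
convention; solver tolerance 1e-10) is fitted on components plus covariates,
components and continuous covariates standardized on the train rows.
Component importance is *permutation importance on the holdout*: each
component column is shuffled `n_perm` times and each shuffle's importance
sample is baseline accuracy minus permuted accuracy. The linear form of the
model admits an exact fast update (only the shuffled column's contribution to
the linear predictor changes), so the desk-scale default `n_perm = 1000`
(10,000 at full scale) costs seconds. Each component draws from its own RNG
stream derived from the seed, so results do not depend on evaluation order.

Component importances are carried back to raw features as `|W i|` — the
unsigned linear back-projection through the block's axis matrix, with no
mean re-addition. The unsigned form is the minimal faithful reading of
"inverse transform by the projection matrices"; a signed variant is exposed
via `signed = TRUE`. Its validation deserves a note: per-feature permutation
importance is known to underestimate features that share variance with
others (permuting one of several redundant features barely moves a model
that can lean on the rest), so the brute-force oracle comparison is run on a
toy with one dominant signal direction, graded loadings and unit noise,
where the oracle is well-posed; the oracle itself is evaluated on a large
fresh sample from the same generative process so that its Monte-Carlo noise
does not mask the ranking. The test requires Spearman ρ > 0.8 between the
back-projection and the oracle.

## Classifier benchmark

Thirteen classifiers are evaluated per feature subset with stratified 10-fold
cross-validation on the training set, all preprocessing (constant-column
removal, standardization) fitted inside each fold, covariates always
appended. The suite uses stock implementations with library defaults where
the environment provides them (glmnet, class, e1071, rpart, randomForest,
ranger, MASS, xgboost). Three members are written in-package: AdaBoost
(discrete SAMME over depth-1 rpart stumps, 50 rounds), a histogram/leaf-wise
gradient booster (xgboost with `grow_policy = "lossguide"`, `max_leaves =
31` — the LightGBM growth strategy), and a ridge-regularized quadratic
discriminant (class covariances shrunk toward a scaled identity), because a
plain QDA is undefined when selected features outnumber class members —
exactly the regime top-k feature selection creates.

The best classifier is the argmax of mean CV accuracy (ties to the earlier
suite entry), refitted on the full training set and scored on the holdout.
Two dummies provide the chance reference: the majority-class dummy (accuracy
equal to the majority rate; F1 for the minority positive class — cases — is
identically 0) and a uniform-random dummy. `sweep_feature_counts()` repeats
the suite over feature types and counts and reports each classifier's
best-classifier density (fractions summing to 1).

Feature types are compared by two-sided Mann-Whitney U tests on the
13-classifier metric vectors (dummies excluded), connectivity versus each
other type, flagged at α = 0.01 (0.05 Bonferroni-corrected for 5
comparisons). Exact p-values are used when there are no ties — at n = 13 per
group complete separation gives U = 169 and p = 2/C(26,13), which the tests
check against exhaustive enumeration.

For no-signal cohorts the suite's accuracies are checked against a
*permutation chance band* (`chance_band()`): the central interval of
accuracies obtained by permuting labels against each classifier's fixed
out-of-fold predictions. A plain binomial band around the majority rate
would be wrong for classifiers that predict the minority class at a nonzero
rate — their null accuracy is below the majority rate — whereas label
permutation is the exact exchangeability null. The band level is adjusted
for the thirteen simultaneous checks (1 − 0.05/13).

## Weighted degree centrality

`mask_edges()` zeroes every entry of a subject's connectivity matrix except
the selected edges (and their mirrors); a region's WDC is the row sum of the
masked matrix — the signed sum of its selected incident raw correlations (an
absolute-value variant is a flag). Group maps average over subjects;
the difference map is cases minus controls. Region sums conserve twice the
selected edge mass, which is asserted as an invariant. The per-region
rank-sum test is reported with a Bonferroni flag across regions and carries
an explicit circularity caveat: the edges were selected for their
discriminative importance in the same sample, so the test is descriptive,
not confirmatory.

## Problem sizes, determinism, degenerate inputs

The test suite and the acceptance script run the full pipeline at desk
scale: P = 100 parcels, n = 300 subjects, 50 planted edges at delta = 0.3,
D = 20 gradients, K ladder {10, 30, 50}, `n_perm = 1000`, 10-fold CV — sizes
chosen so the complete recovery experiment runs in about a minute on one
CPU while preserving the full-scale structure (seven networks, all four
feature families, stratified splits at the 0.35 case/control ratio). The
no-signal arm uses P = 60, n = 200.

Every stochastic stage takes an explicit integer seed (cohort, reference,
split, permutation, CV are seeded separately in `run_pipeline()`'s config),
and identical configurations produce byte-identical output bundles; the
manifest records an MD5 hash of the analysis configuration (output paths
excluded). Degenerate inputs are handled explicitly: |r| = 1 edges are
clipped before the z-transform with a warning, blocks with fewer than two
features are kept whole with a warning, fully tied rank-sum comparisons
report p = 1, and an empty post-filter cohort or a class emptied by the
split is an error.

## Limitations

* Synthetic cohorts are stationary multivariate Gaussians; none of the
  spatial or temporal structure of real BOLD is present, so absolute
  accuracies here say nothing about clinical performance.
* The full-scale feature grid (1.7 million columns) is represented by its
  exact dimensional accounting, not materialized; desk-scale runs keep the
  same structure at P ≤ 100.
* Classifier hyperparameters are library defaults with fixed seeds — the
  benchmark is classifier-agnostic by breadth, not by tuning.
* The WDC rank-sum inherits selection circularity, as flagged in its output.
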