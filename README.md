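# connbench

Comparative benchmarking of functional-connectome feature families as
case-control classification biomarkers, exercised end-to-end on synthetic
cohorts with known planted effects.

## The problem

Resting-state functional connectivity — the parcel × parcel Pearson
correlation matrix of fMRI time series — discriminates people with
schizophrenia from neurotypical controls, but a 1000-parcel connectome has
C(1000, 2) = 499,500 edges, inviting overfitting at clinical sample sizes.
Low-dimensional summaries built on *macroscale cortical gradients* (the
principal axes of the thresholded, Fisher z-transformed connectivity matrix)
have been proposed instead, together with two dispersion statistics in
gradient space:

- **centroid dispersion** — for each canonical network *k* with parcels *p*
  and per-dimension median centroid in 3-gradient space,
  `CD_k = Σ_p ‖g_p − median(G_k)‖²` (within) and
  `CD_kl = ‖median(G_k) − median(G_l)‖` (between): 7 + 21 = 28 values;
- **neighborhood dispersion** — per parcel *f*,
  `ND_f(K) = (1/K) Σ_{j∈KNN(f)} ‖x_f − x_j‖` in the first *d* gradients,
  over a grid d = 1..200 and K ∈ {10, 50, 110, 140, 170}: 1,000,000 values
  at full scale.

`connbench` implements the full comparison: seeded two-group cohorts of
valid correlation matrices with plantable edge hypoconnectivity and realistic
covariate confounds (age, sex, site, head motion, with motion-based
exclusion at mean FD > 0.5 mm); gradients with Procrustes alignment to a
reference; both dispersion families; blockwise-PCA compression (20% variance
per block) feeding an L2-logistic model whose holdout *permutation component
importance* is inverse-projected (`|W i|`) to rank every raw feature; a
13-classifier benchmark over top-importance feature subsets with dummy
baselines and Bonferroni-corrected Mann-Whitney comparisons between feature
types; and weighted degree centrality (`WDC_i = Σ_j masked C_subj[i, j]`) to
map selected edges back to regions.

## Worked example

Plant hypoconnectivity (delta = 0.3 on 30 within-network edges) in a
200-subject cohort, rank features by permutation importance, and benchmark
the top connectivity edges:

```r
library(connbench)

labels <- make_network_labels(60, 7)
edges  <- plant_edges(labels, 30, seed = 2)
sim    <- generate_cohort(200, 60, labels,
                          effect_spec(target_edges = edges, delta = 0.3),
                          seed = 42)
flt    <- filter_by_motion(sim$cohort, sim$matrices, 0.5)  # drops 13 movers

ref       <- generate_cohort(40, 60, labels, effect_spec(), seed = 7)
reference <- reference_gradients(ref$cohort, ref$matrices, 12)

blocks <- compute_feature_blocks(flt$cohort, flt$matrices, labels, reference,
                                 n_components = 12, K_set = c(10, 30))
fb  <- assemble_features(blocks$conn, blocks$grad, blocks$disp_nbr,
                         blocks$disp_cntr, flt$cohort)
fb
#> feature_blocks: 187 subjects x 3958 features
#>   blocks: conn=1770 grad=720 disp_nbr=1440 disp_cntr=28
#>   covariates: age, sex_M, site_siteA, site_siteB, site_siteC, mean_fd

sp    <- split_cohort(fb, 0.25, seed = 13)
pca   <- fit_block_pca(fb, 0.20, train_rows = sp$train)
comps <- transform_blocks(pca, fb)
model <- fit_importance_model(comps, fb$covariates, fb$group, sp$train)
imp   <- permutation_component_importance(model, comps, fb$covariates,
                                          fb$group, sp$holdout,
                                          n_perm = 1000, seed = 14)
imp
#> importance_report: baseline holdout accuracy 1.000, n_perm = 1000
#>   conn       mean importance 0.0198
#>   disp_cntr  mean importance 0.0001
#>   disp_nbr   mean importance 0.0000
#>   grad       mean importance 0.0116
```

The connectivity block, where the signal was planted, dominates the
importance ranking (gradients inherit part of it, being functions of the
same matrix). Selecting the top 30 edges and running the classifier suite:

```r
fi  <- importance_to_feature_space(imp, pca)
top <- select_top_features(fi, n = 30, scope = "conn")
res <- run_classifier_suite(fb$values[, top], fb$group, fb$covariates,
                            sp$train, sp$holdout, folds = 10, seed = 15)
res
#> benchmark_result: 10 -fold CV over 13 classifiers
#>   lr     CV acc 1.000  CV F1 1.000
#>   ...
#>   best: lr | holdout acc 1.000 F1 1.000 | majority baseline acc 0.723 F1 0.000

wdc_map(flt$cohort, flt$matrices, top)
#> wdc_map over 30 selected edges; 60 regions
#>   mean WDC: NC 0.345, SCZ 0.053; mean difference -0.292
#>   44 regions flagged by rank-sum (Bonferroni); note: edges were selected on
#>   importance in the same sample; treat as descriptive
```

A planted delta of 0.3 at this sample size is an easy target — the point of
the example is the pipeline's bookkeeping: the majority dummy scores the
majority rate with minority-class F1 = 0, and the WDC difference map is
negative (hypoconnectivity in cases) exactly on the regions touched by the
selected edges. `run_pipeline()` chains all stages from one seeded config
and writes a diff-able TSV/JSON bundle with a config-hash manifest.

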