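Package: connbench
Title: Benchmarking Functional-Connectivity Biomarkers for Psychiatric
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative evaluation of functional-connectome feature families
    as case-control classification biomarkers. Simulates seeded two-group
    cohorts of parcelwise correlation matrices with plantable edge-level
    hypoconnectivity and demographic confounds, derives macroscale cortical
    gradients (thresholded PCA embedding with Procrustes alignment), centroid
    and neighborhood gradient-dispersion measures, and raw edge vectors, then
    ranks features by blockwise-PCA permutation importance, benchmarks a
    thirteen-classifier suite across feature subsets with dummy baselines and
    rank-sum comparisons, and localizes selected edges via weighted degree
    centrality maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    class,
    e1071,
    glmnet,
    jsonlite,
    MASS,
    randomForest,
    ranger,
    rpart,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
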