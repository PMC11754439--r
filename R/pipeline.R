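# End-to-end driver: simulate -> motion filter -> features -> blockwise PCA
# importance -> classifier benchmark -> WDC, with a manifest tying every
# output to the configuration hash.

#' Default pipeline configuration
#'
#' Desk-scale defaults; every entry can be overridden via `modifyList()` or
#' the `...` of [run_pipeline()]. Seeds are split per stage (cohort, split,
#' permutation, CV) so stages can be re-run independently.
#'
#' @return Named list.
#' @export
default_config <- function() {
  list(
    seeds = list(cohort = 11, reference = 12, split = 13, perm = 14, cv = 15),
    n_subjects = 200, n_parcels = 60, n_networks = 7,
    n_reference = 40, ts_length = 150,
    delta = 0.3, n_target_edges = 30, class_ratio = 0.35, noise_sd = 0.05,
    contraction = 0,
    motion_threshold = 0.5,
    density = 0.10, n_components = NULL,
    K_set = NULL, d_range = NULL,
    variance_target = 0.20, holdout_fraction = 0.25,
    n_perm = 1000,
    counts = c(25, 50), types = c("conn", "grad", "disp_nbr", "mixed"),
    folds = 10, wdc_top = 50,
    out_dir = NULL
  )
}

validate_config <- function(config) {
  need <- names(default_config())
  missing <- setdiff(need, names(config))
  if (length(missing)) stop("config missing entries: ",
                            paste(missing, collapse = ", "))
  s <- config$seeds
  if (!all(c("cohort", "reference", "split", "perm", "cv") %in% names(s)) ||
      !all(vapply(s, function(v) is.numeric(v) && v == round(v), logical(1)))) {
    stop("config$seeds must hold integer seeds: cohort, reference, split, perm, cv")
  }
  for (f in c("density", "variance_target", "holdout_fraction")) {
    if (config[[f]] <= 0 || config[[f]] > 1) stop(f, " must be in (0, 1]")
  }
  invisible(config)
}

# Hash of the analysis configuration; output paths do not change the
# analysis, so they are excluded.
config_hash <- function(config) {
  config$out_dir <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  unname(tools::md5sum(tmp))
}

#' Run the full benchmarking pipeline
#'
#' Stage order: simulate (reference cohort, then study cohort) -> motion
#' filter -> per-subject features -> assemble + stratified split -> blockwise
#' PCA + L2-logistic + permutation component importance -> inverse projection
#' -> classifier sweep over feature types and counts -> WDC mapping of the
#' top connectivity edges. Deterministic given the config seeds. When
#' `out_dir` is set, writes cohort.tsv, component_importance.json,
#' feature_importance.tsv, leaderboard.tsv, wdc.tsv and manifest.json.
#'
#' @param config Configuration list ([default_config()]).
#' @param ... Overrides merged into `config`.
#' @return Invisible list with all stage outputs (`cohort`, `features`,
#'   `split`, `pca`, `importance`, `feature_importance`, `sweep`, `wdc`,
#'   `config`, `hash`).
#' @export
run_pipeline <- function(config = default_config(), ...) {
  dots <- list(...)
  if (length(dots)) config <- utils::modifyList(config, dots)
  validate_config(config)
  hash <- config_hash(config)
  msg <- function(...) message("[connbench] ", ...)

  msg("simulate: reference cohort (n = ", config$n_reference, ")")
  labels <- make_network_labels(config$n_parcels, config$n_networks)
  ref_cohort <- generate_cohort(config$n_reference, config$n_parcels, labels,
                                effect_spec(class_ratio = config$class_ratio,
                                            noise_sd = config$noise_sd),
                                seed = config$seeds$reference,
                                ts_length = config$ts_length)
  n_comp <- if (is.null(config$n_components)) max(3, config$n_parcels %/% 5) else
    config$n_components
  reference <- reference_gradients(ref_cohort$cohort, ref_cohort$matrices,
                                   n_comp, config$density)

  msg("simulate: study cohort (n = ", config$n_subjects, ", delta = ",
      config$delta, ")")
  edges <- if (config$n_target_edges > 0 && config$delta != 0) {
    plant_edges(labels, config$n_target_edges, seed = config$seeds$cohort)
  } else NULL
  eff <- effect_spec(target_edges = edges, delta = config$delta,
                     noise_sd = config$noise_sd,
                     class_ratio = config$class_ratio,
                     contraction = config$contraction)
  sim <- generate_cohort(config$n_subjects, config$n_parcels, labels, eff,
                         seed = config$seeds$cohort,
                         ts_length = config$ts_length)

  flt <- filter_by_motion(sim$cohort, sim$matrices, config$motion_threshold)
  msg("motion filter: excluded ", flt$n_excluded, " of ", nrow(sim$cohort))

  msg("features: gradients, dispersion, edges")
  blocks <- compute_feature_blocks(flt$cohort, flt$matrices, labels, reference,
                                   n_components = n_comp,
                                   density = config$density,
                                   K_set = config$K_set,
                                   d_range = config$d_range)
  features <- assemble_features(blocks$conn, blocks$grad, blocks$disp_nbr,
                                blocks$disp_cntr, flt$cohort)
  split <- split_cohort(features, config$holdout_fraction, config$seeds$split)

  msg("importance: blockwise PCA + L2-logistic + ", config$n_perm,
      " permutations/component")
  pca <- fit_block_pca(features, config$variance_target,
                       train_rows = split$train)
  comps <- transform_blocks(pca, features)
  model <- fit_importance_model(comps, features$covariates, features$group,
                                split$train)
  importance <- permutation_component_importance(model, comps,
                                                 features$covariates,
                                                 features$group, split$holdout,
                                                 n_perm = config$n_perm,
                                                 seed = config$seeds$perm)
  feat_imp <- importance_to_feature_space(importance, pca)

  msg("benchmark: ", length(config$types), " types x ",
      length(config$counts), " counts, ", config$folds, "-fold CV")
  sweep <- sweep_feature_counts(feat_imp, features, config$counts,
                                types = config$types,
                                train_rows = split$train,
                                holdout_rows = split$holdout,
                                folds = config$folds, seed = config$seeds$cv)

  msg("wdc: top ", config$wdc_top, " connectivity edges")
  conn_top <- select_top_features(feat_imp, n = config$wdc_top, scope = "conn")
  # conn features are the leading block, so data.frame rows == edge indices
  wdc <- wdc_map(flt$cohort, flt$matrices, selected = conn_top)

  bundle <- list(cohort = flt$cohort, effect = eff, reference = reference,
                 features = features, split = split, pca = pca,
                 model = model, importance = importance,
                 feature_importance = feat_imp, sweep = sweep, wdc = wdc,
                 config = config, hash = hash)
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  invisible(bundle)
}

# Write the diff-able report bundle; every file is listed in manifest.json
# together with the config hash that produced it.
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_cohort(bundle$cohort, p("cohort.tsv"))
  jsonlite::write_json(
    list(config_hash = bundle$hash,
         baseline_accuracy = bundle$importance$baseline_accuracy,
         n_perm = bundle$importance$n_perm,
         components = bundle$importance$component_importance),
    p("component_importance.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "columns")
  utils::write.table(bundle$feature_importance, p("feature_importance.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  lb <- do.call(rbind, lapply(names(bundle$sweep$results), function(k) {
    s <- bundle$sweep$results[[k]]$summary
    cbind(run = k, s)
  }))
  utils::write.table(lb, p("leaderboard.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  wdc_tab <- data.frame(region = seq_along(bundle$wdc$nc),
                        wdc_nc = bundle$wdc$nc, wdc_scz = bundle$wdc$scz,
                        difference = bundle$wdc$difference,
                        U = bundle$wdc$ranksum$U, p = bundle$wdc$ranksum$p,
                        significant = bundle$wdc$ranksum$significant)
  utils::write.table(wdc_tab, p("wdc.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest <- list(
    config_hash = bundle$hash,
    package_version = as.character(utils::packageVersion("connbench")),
    edge_indexing = "strict upper triangle, i < j, row-major, 1-based",
    config = bundle$config,
    outputs = c("cohort.tsv", "component_importance.json",
                "feature_importance.tsv", "leaderboard.tsv", "wdc.tsv"))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(out_dir)
}
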