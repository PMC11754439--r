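# Synthetic two-group connectome cohorts.
#
# Cohorts are generated from latent Gaussian time series with a
# network-structured covariance, so every subject-level matrix is a valid
# (positive semi-definite, unit-diagonal) Pearson correlation matrix. Group
# effects are injected by shifting the latent covariance before simulation,
# never by editing correlation values directly.

#' Assign parcels to canonical networks
#'
#' Splits `n_parcels` parcels into contiguous, near-equal blocks. With the
#' default 7 networks the blocks carry the canonical resting-state network
#' names (visual, somatomotor, dorsal/ventral attention, limbic, control,
#' default mode).
#'
#' @param n_parcels Number of parcels (>= 2 per network).
#' @param n_networks Number of networks (default 7).
#' @return Named character vector of length `n_parcels`; names are parcel ids
#'   (`p001`, ...), values network labels.
#' @export
make_network_labels <- function(n_parcels, n_networks = 7) {
  stopifnot(n_networks >= 1, n_parcels >= 2 * n_networks)
  nets <- if (n_networks == 7) {
    c("Vis", "SomMot", "DorsAttn", "SalVentAttn", "Limbic", "Cont", "Default")
  } else {
    sprintf("Net%d", seq_len(n_networks))
  }
  sizes <- rep(n_parcels %/% n_networks, n_networks)
  extra <- n_parcels %% n_networks
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  labels <- rep(nets, times = sizes)
  names(labels) <- sprintf("p%03d", seq_len(n_parcels))
  labels
}

#' Specify a plantable group effect
#'
#' @param target_edges Two-column matrix/data.frame of parcel index pairs
#'   (unordered) receiving the connectivity shift, or `NULL` for no edge
#'   effect.
#' @param delta Magnitude of the planted hypoconnectivity on the correlation
#'   scale: case-group latent covariance at `target_edges` is lowered by
#'   `|delta|` (controls minus cases ~ `+|delta|`). Must satisfy `|delta| < 2`.
#' @param noise_sd Standard deviation of the per-subject covariance jitter
#'   (multiplicative, mean 1).
#' @param class_ratio Case/control ratio `N_SCZ / N_NC` (default 0.35).
#' @param contraction Optional increase of between-network latent covariance
#'   in the case group; emulates gradient contraction (less functional
#'   differentiation). Default 0 (off).
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(target_edges = NULL, delta = 0, noise_sd = 0.05,
                        class_ratio = 0.35, contraction = 0) {
  stopifnot(abs(delta) < 2, class_ratio > 0, noise_sd >= 0, contraction >= 0)
  if (!is.null(target_edges)) {
    target_edges <- as.matrix(target_edges)
    if (ncol(target_edges) != 2) stop("target_edges must have two columns (i, j)")
    storage.mode(target_edges) <- "integer"
    if (any(target_edges[, 1] == target_edges[, 2])) {
      stop("target_edges must not include self-pairs")
    }
    # store as i < j
    target_edges <- cbind(pmin(target_edges[, 1], target_edges[, 2]),
                          pmax(target_edges[, 1], target_edges[, 2]))
    colnames(target_edges) <- c("i", "j")
  }
  structure(list(target_edges = target_edges, delta = delta,
                 noise_sd = noise_sd, class_ratio = class_ratio,
                 contraction = contraction),
            class = "effect_spec")
}

#' Sample within-network edges for effect planting
#'
#' Draws `n_edges` distinct within-network parcel pairs with each parcel
#' incident to at most `max_per_parcel` selected edges. The incidence cap
#' bounds the spectral perturbation of the latent covariance (Gershgorin), so
#' shifted matrices remain positive definite without eigenvalue clipping.
#'
#' @param network_labels Output of [make_network_labels()].
#' @param n_edges Number of edges to select.
#' @param seed RNG seed.
#' @param max_per_parcel Incidence cap per parcel (default 2).
#' @return Integer matrix with columns `i`, `j` (i < j).
#' @export
plant_edges <- function(network_labels, n_edges, seed, max_per_parcel = 2) {
  nets <- split(seq_along(network_labels), network_labels)
  pairs <- do.call(rbind, lapply(nets, function(idx) {
    if (length(idx) < 2) return(NULL)
    t(utils::combn(sort(idx), 2))
  }))
  set.seed(as.integer(seed))
  pairs <- pairs[sample.int(nrow(pairs)), , drop = FALSE]
  use <- integer(length(network_labels))
  keep <- matrix(0L, 0, 2)
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    if (use[i] < max_per_parcel && use[j] < max_per_parcel) {
      keep <- rbind(keep, pairs[r, , drop = FALSE])
      use[i] <- use[i] + 1L; use[j] <- use[j] + 1L
      if (nrow(keep) == n_edges) break
    }
  }
  if (nrow(keep) < n_edges) {
    stop("could not place ", n_edges, " edges under the per-parcel cap; got ",
         nrow(keep))
  }
  colnames(keep) <- c("i", "j")
  keep
}

# Latent network-structured correlation: rho_within inside network blocks,
# rho_between elsewhere, unit diagonal.
base_latent_cov <- function(network_labels, rho_within, rho_between) {
  p <- length(network_labels)
  sigma <- matrix(rho_between, p, p)
  for (net in unique(network_labels)) {
    idx <- which(network_labels == net)
    sigma[idx, idx] <- rho_within
  }
  diag(sigma) <- 1
  sigma
}

# Force positive definiteness by clipping eigenvalues and rescaling back to a
# correlation matrix. A no-op for matrices already PD.
ensure_pd <- function(sigma, floor = 1e-6) {
  e <- eigen(sigma, symmetric = TRUE)
  if (min(e$values) > floor) return(sigma)
  v <- pmax(e$values, floor)
  s <- e$vectors %*% (v * t(e$vectors))
  stats::cov2cor(s)
}

#' Generate a seeded two-group cohort of connectivity matrices
#'
#' Subjects belong to `NC` (controls) or `SCZ` (cases) with
#' `N_SCZ / N_NC = effect$class_ratio`. Each subject's parcelwise time series
#' (length `ts_length`) is drawn from a multivariate normal whose covariance
#' is the group latent covariance under a mean-one multiplicative jitter; the
#' Pearson correlation of the series is the subject's connectivity matrix.
#' Case-group covariance is lowered by `|effect$delta|` at
#' `effect$target_edges` (hypoconnectivity) and optionally raised between
#' networks by `effect$contraction`.
#'
#' Covariates mirror the demographic imbalances typical of multi-site
#' clinical samples: cases are on average older, more often male, have higher
#' head motion (mean framewise displacement, mm), and sites differ mildly in
#' group composition; a small fraction of subjects are high-motion "movers"
#' exceeding the conventional 0.5 mm exclusion threshold.
#'
#' @param n_subjects Total number of subjects.
#' @param n_parcels Number of parcels P (>= 10).
#' @param network_labels Parcel-to-network map ([make_network_labels()]).
#' @param effect An [effect_spec()].
#' @param seed Integer RNG seed; fixed seed + config gives a bit-identical
#'   cohort.
#' @param ts_length Latent time-series length (default 150 samples, emulating
#'   short resting-state scans).
#' @param rho_within,rho_between Latent within-/between-network covariance.
#' @param confound_strength Scales the group dependence of age, sex, site and
#'   motion (0 = fully exchangeable covariates, 1 = default mild imbalance).
#' @param p_mover Probability of a high-motion subject (default 0.06).
#' @return A list with `cohort` (data.frame: subject_id, group, age, sex,
#'   site, mean_fd), `matrices` (list of P x P correlation matrices, index-
#'   aligned with cohort rows), and `network_labels`.
#' @export
generate_cohort <- function(n_subjects, n_parcels, network_labels,
                            effect = effect_spec(), seed,
                            ts_length = 150,
                            rho_within = 0.35, rho_between = 0.05,
                            confound_strength = 1, p_mover = 0.06) {
  stopifnot(n_parcels >= 10, length(network_labels) == n_parcels,
            ts_length >= 10)
  if (min(table(network_labels)) < 2) stop("every network needs >= 2 parcels")
  r <- effect$class_ratio
  n_scz <- round(n_subjects * r / (1 + r))
  n_nc <- n_subjects - n_scz
  if (n_scz < 1 || n_nc < 1) {
    stop("class_ratio ", r, " yields an empty class for n = ", n_subjects)
  }
  edges <- effect$target_edges
  if (!is.null(edges) && any(edges > n_parcels)) {
    stop("target_edges reference parcels beyond n_parcels = ", n_parcels)
  }

  sigma_nc <- base_latent_cov(network_labels, rho_within, rho_between)
  sigma_scz <- sigma_nc
  if (!is.null(edges) && effect$delta != 0) {
    d <- abs(effect$delta)
    for (rr in seq_len(nrow(edges))) {
      i <- edges[rr, 1]; j <- edges[rr, 2]
      sigma_scz[i, j] <- sigma_scz[i, j] - d
      sigma_scz[j, i] <- sigma_scz[i, j]
    }
  }
  if (effect$contraction > 0) {
    between <- outer(network_labels, network_labels, FUN = "!=")
    sigma_scz[between] <- sigma_scz[between] + effect$contraction
    diag(sigma_scz) <- 1
  }
  sigma_nc <- ensure_pd(sigma_nc)
  sigma_scz <- ensure_pd(sigma_scz)

  set.seed(as.integer(seed))
  group <- factor(c(rep("NC", n_nc), rep("SCZ", n_scz)), levels = c("NC", "SCZ"))
  n <- n_subjects
  cs <- confound_strength
  is_scz <- group == "SCZ"

  age <- ifelse(is_scz, stats::rnorm(n, 33.5 + cs * 3.9, 11),
                stats::rnorm(n, 33.5, 13))
  age <- pmin(pmax(age, 18), 75)
  p_f <- ifelse(is_scz, 0.395 - cs * 0.076, 0.395)
  sex <- factor(ifelse(stats::runif(n) < p_f, "F", "M"), levels = c("F", "M"))
  site_probs_nc <- c(0.40, 0.35, 0.25)
  site_probs_scz <- (1 - cs) * site_probs_nc + cs * c(0.50, 0.28, 0.22)
  site <- character(n)
  site[!is_scz] <- sample(c("siteA", "siteB", "siteC"), n_nc, TRUE, site_probs_nc)
  site[is_scz] <- sample(c("siteA", "siteB", "siteC"), n_scz, TRUE, site_probs_scz)
  site <- factor(site)
  fd <- abs(stats::rnorm(n, 0.15 + cs * 0.04 * is_scz, 0.07)) + 0.02
  mover <- stats::runif(n) < p_mover
  fd[mover] <- 0.5 + stats::rexp(sum(mover), rate = 10)

  chol_nc <- chol(sigma_nc)
  chol_scz <- chol(sigma_scz)
  # subject covariance = cj * Sigma_group + (1 - cj) * I with mean-one cj, so
  # the expected connectivity is unbiased. The jitter SD is shrunk (never
  # truncated one-sidedly, which would bias the planted effect) so that
  # 1 + 3 sd keeps the blend positive definite.
  eigmin <- min(eigen(sigma_nc, symmetric = TRUE, only.values = TRUE)$values,
                eigen(sigma_scz, symmetric = TRUE, only.values = TRUE)$values)
  cj_max <- if (eigmin < 1) (1 - 1e-3) / (1 - eigmin) else Inf
  sd_eff <- min(effect$noise_sd, max(0, cj_max - 1) / 3)
  matrices <- vector("list", n)
  for (s in seq_len(n)) {
    cj <- if (sd_eff > 0) {
      min(max(stats::rnorm(1, 1, sd_eff), 1 - 3 * sd_eff), 1 + 3 * sd_eff)
    } else 1
    ch <- if (cj == 1) {
      if (is_scz[s]) chol_scz else chol_nc
    } else {
      sig <- cj * (if (is_scz[s]) sigma_scz else sigma_nc)
      diag(sig) <- 1
      chol(sig)
    }
    z <- matrix(stats::rnorm(ts_length * n_parcels), ts_length, n_parcels) %*% ch
    m <- stats::cor(z)
    dimnames(m) <- list(names(network_labels), names(network_labels))
    matrices[[s]] <- m
  }

  cohort <- data.frame(
    subject_id = sprintf("sub%04d", seq_len(n)),
    group = group, age = age, sex = sex, site = site, mean_fd = fd,
    stringsAsFactors = FALSE
  )
  list(cohort = cohort, matrices = matrices, network_labels = network_labels)
}

#' Measure the realized planted edge effect
#'
#' Group-mean difference (controls minus cases) of connectivity at a set of
#' edges; the post-hoc check that a planted latent shift survived simulation.
#'
#' @param cohort Cohort data.frame (with `group`).
#' @param matrices List of connectivity matrices aligned with `cohort`.
#' @param edges Two-column matrix of parcel pairs.
#' @return List with `per_edge` (mean NC - mean SCZ per edge) and `mean`.
#' @export
measure_edge_effect <- function(cohort, matrices, edges) {
  edges <- as.matrix(edges)
  vals <- sapply(seq_len(nrow(edges)), function(r) {
    x <- vapply(matrices, function(m) m[edges[r, 1], edges[r, 2]], numeric(1))
    mean(x[cohort$group == "NC"]) - mean(x[cohort$group == "SCZ"])
  })
  list(per_edge = vals, mean = mean(vals))
}

#' Exclude high-motion subjects
#'
#' Retains subjects whose mean framewise displacement does not exceed the
#' threshold; exclusion is strict (`mean_fd > threshold` is removed), matching
#' the conventional FD > 0.5 mm rule.
#'
#' @param cohort Cohort data.frame with a `mean_fd` column (mm).
#' @param matrices List of matrices index-aligned with `cohort`; may be `NULL`.
#' @param threshold Exclusion threshold in mm (default 0.5).
#' @return List with filtered `cohort`, `matrices`, and `n_excluded`.
#' @export
filter_by_motion <- function(cohort, matrices = NULL, threshold = 0.5) {
  stopifnot(threshold > 0)
  keep <- cohort$mean_fd <= threshold
  if (!any(keep)) {
    stop("motion filter removed all ", nrow(cohort),
         " subjects at threshold ", threshold, " mm")
  }
  list(
    cohort = cohort[keep, , drop = FALSE],
    matrices = if (is.null(matrices)) NULL else matrices[keep],
    n_excluded = sum(!keep)
  )
}
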