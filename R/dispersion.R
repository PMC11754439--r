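# Gradient dispersion: centroid dispersion in 3-gradient space (within- and
# between-network) and per-parcel neighborhood dispersion over a grid of
# embedding dimensions and neighbor counts.

# Lower median per column: deterministic for even counts (takes the lower of
# the two central order statistics).
lower_median <- function(x) sort(x)[(length(x) + 1L) %/% 2L]

#' Centroid dispersion of networks in 3-gradient space
#'
#' The centroid of a network is the per-dimension (lower) median of its
#' parcels' first three gradient values. Within-network dispersion is the sum
#' of squared Euclidean distances from parcels to their network centroid;
#' between-network dispersion is the Euclidean distance between centroids.
#' Seven networks give 7 + 21 = 28 values.
#'
#' @param gradients A `gradient_set` (or score matrix) with >= 3 components;
#'   only the first three are used and exactly three must be supplied when a
#'   plain matrix is given.
#' @param labels Parcel-to-network map aligned with score rows.
#' @return List of class `centroid_dispersion`: `within` (named per network),
#'   `between` (named `<netA>_<netB>` over unordered pairs), and `values`
#'   (the 28-style flat named vector, within first).
#' @export
centroid_dispersion <- function(gradients, labels) {
  scores <- if (inherits(gradients, "gradient_set")) gradients$scores else gradients
  if (ncol(scores) < 3) stop("centroid dispersion needs at least 3 gradients")
  scores <- scores[, 1:3, drop = FALSE]
  if (nrow(scores) != length(labels)) stop("labels must align with parcels")
  nets <- sort(unique(as.character(labels)))
  if (any(table(labels) == 0)) stop("empty network in labels")
  centroids <- t(vapply(nets, function(k) {
    g <- scores[labels == k, , drop = FALSE]
    apply(g, 2, lower_median)
  }, numeric(3)))
  within <- vapply(nets, function(k) {
    g <- scores[labels == k, , drop = FALSE]
    sum(sweep(g, 2, centroids[k, ])^2)
  }, numeric(1))
  pairs <- utils::combn(nets, 2)
  between <- apply(pairs, 2, function(kl) {
    sqrt(sum((centroids[kl[1], ] - centroids[kl[2], ])^2))
  })
  names(between) <- paste(pairs[1, ], pairs[2, ], sep = "_")
  values <- c(stats::setNames(within, paste0("within_", nets)),
              stats::setNames(between, paste0("between_", names(between))))
  structure(list(within = within, between = between, values = values),
            class = "centroid_dispersion")
}

#' Neighborhood dispersion of each parcel
#'
#' Mean Euclidean distance from each focal parcel to its K nearest neighbors
#' in the embedding spanned by the first `d` gradients. Neighbors exclude the
#' focal parcel; ties at the K-th distance are broken by parcel index (exact
#' search, no approximation).
#'
#' @param gradients `gradient_set` or score matrix.
#' @param d Number of leading gradients defining the embedding (1 <= d <= D).
#' @param K Number of nearest neighbors (1 <= K <= P-1).
#' @return Numeric vector of length P.
#' @export
neighborhood_dispersion <- function(gradients, d, K) {
  scores <- if (inherits(gradients, "gradient_set")) gradients$scores else gradients
  p <- nrow(scores)
  if (d < 1 || d > ncol(scores)) stop("d must be in [1, ", ncol(scores), "]")
  if (K < 1 || K >= p) stop("K must be in [1, P-1] with P = ", p)
  x <- scores[, seq_len(d), drop = FALSE]
  dm <- as.matrix(stats::dist(x))
  vapply(seq_len(p), function(f) {
    ord <- order(dm[f, -f])  # stable: ties keep ascending parcel index
    mean(dm[f, -f][ord[seq_len(K)]])
  }, numeric(1))
}

#' Feature grid layout for neighborhood dispersion
#'
#' The stable flattened order of the dispersion grid: `d` varies slowest,
#' then `K`, then parcel. Used for naming grid columns and for feature
#' accounting (P = 1000, D = 200, five K values give 1,000,000 features).
#'
#' @param n_parcels P.
#' @param d_range Vector of embedding dimensions.
#' @param K_set Vector of neighbor counts.
#' @return Character vector of feature names `nd_p<parcel>_d<dim>_k<K>`.
#' @export
nd_grid_features <- function(n_parcels, d_range, K_set) {
  unlist(lapply(d_range, function(d) {
    lapply(K_set, function(k) sprintf("nd_p%d_d%d_k%d", seq_len(n_parcels), d, k))
  }), use.names = FALSE)
}

#' Neighborhood dispersion over a (d, K) grid
#'
#' Computes [neighborhood_dispersion()] for every combination of leading-
#' gradient subsets `d_range` and neighbor counts `K_set`. Squared distances
#' are accumulated incrementally over dimensions and each parcel's distances
#' are sorted once per `d`, so grid cells share work; results are identical
#' to cell-wise computation.
#'
#' The default `K_set` follows the five-point ladder {10, 50, 110, 140, 170};
#' an evenly stepped alternative {10, 50, 90, 130, 170} is available via
#' `k_ladder("even")`.
#'
#' @param gradients `gradient_set` or score matrix.
#' @param K_set Neighbor counts (all < P).
#' @param d_range Embedding dimensions, subset of 1..D (default 1..D).
#' @return Named numeric vector over the grid in [nd_grid_features()] order.
#' @export
neighborhood_dispersion_grid <- function(gradients, K_set = k_ladder(),
                                         d_range = NULL) {
  scores <- if (inherits(gradients, "gradient_set")) gradients$scores else gradients
  p <- nrow(scores); dd <- ncol(scores)
  if (is.null(d_range)) d_range <- seq_len(dd)
  if (length(K_set) == 0) stop("K_set must be nonempty")
  if (any(K_set < 1 | K_set >= p)) stop("all K must be in [1, P-1]")
  if (any(d_range < 1 | d_range > dd)) stop("d_range must lie in [1, ", dd, "]")
  K_set <- as.integer(K_set); d_range <- as.integer(d_range)
  kmax <- max(K_set)
  d2 <- matrix(0, p, p)  # running squared distances over leading dims
  prev <- 0L
  ordered <- order(d_range)
  # accumulate in ascending d, then emit in the documented (given) order
  vals <- vector("list", length(d_range))
  for (ii in seq_along(ordered)) {
    d <- d_range[ordered[ii]]
    while (prev < d) {
      prev <- prev + 1L
      dif <- outer(scores[, prev], scores[, prev], `-`)
      d2 <- d2 + dif * dif
    }
    dmat <- sqrt(d2)
    csum <- matrix(0, kmax, p)
    for (f in seq_len(p)) {
      ds <- sort(dmat[f, -f], partial = kmax)[seq_len(kmax)]
      csum[, f] <- cumsum(sort(ds))
    }
    cell <- matrix(0, p, length(K_set))
    for (kk in seq_along(K_set)) cell[, kk] <- csum[K_set[kk], ] / K_set[kk]
    vals[[ordered[ii]]] <- cell
  }
  out <- unlist(lapply(vals, function(m) as.numeric(m)), use.names = FALSE)
  names(out) <- nd_grid_features(p, d_range, K_set)
  out
}

#' Neighbor-count ladders for the dispersion grid
#'
#' @param which `"default"` for {10, 50, 110, 140, 170} or `"even"` for the
#'   evenly stepped {10, 50, 90, 130, 170}.
#' @return Integer vector of K values.
#' @export
k_ladder <- function(which = c("default", "even")) {
  which <- match.arg(which)
  if (which == "default") c(10L, 50L, 110L, 140L, 170L)
  else c(10L, 50L, 90L, 130L, 170L)
}
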