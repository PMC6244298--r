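#' Principal component analysis of delay features
#'
#' Mean-centred PCA via [stats::prcomp()]. Component signs are fixed so
#' each component's largest-magnitude coefficient is positive, making
#' component coefficient maps reproducible across runs. For propagating
#' plane waves the delay features are affine in the electrode coordinates,
#' so a handful of components capture nearly all variance — the geometric
#' reason three components suffice for wave classification.
#'
#' @param features numeric matrix `[n_events x n_features]`.
#' @return An object of class `pca_model`: `components` (orthonormal
#'   columns), `explained_variance_ratio` (non-increasing), `mean`, `sdev`.
#' @export
pca_fit <- function(features) {
  features <- as.matrix(features)
  if (nrow(features) < 2L) stop("need at least 2 events for PCA")
  p <- stats::prcomp(features, center = TRUE, scale. = FALSE)
  comp <- p$rotation
  for (k in seq_len(ncol(comp))) {
    i <- which.max(abs(comp[, k]))
    if (comp[i, k] < 0) comp[, k] <- -comp[, k]
  }
  v <- p$sdev^2
  structure(list(components = comp,
                 explained_variance_ratio = v / sum(v),
                 mean = p$center, sdev = p$sdev),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  ev <- x$explained_variance_ratio
  cat(sprintf("pca_model: %d components; first 3 explain %.2f%%\n",
              ncol(x$components), 100 * sum(ev[seq_len(min(3, length(ev)))])))
  invisible(x)
}

#' Project features onto leading principal components
#'
#' @param features matrix with the same columns the model was fitted on.
#' @param model a [pca_fit()] result.
#' @param n number of components (default 3).
#' @return numeric matrix `[n_events x n]`.
#' @export
project <- function(features, model, n = 3L) {
  features <- as.matrix(features)
  if (ncol(features) != length(model$mean))
    stop("feature dimension does not match the PCA model")
  if (n > ncol(model$components))
    stop("requested more components than the model holds")
  sweep(features, 2L, model$mean) %*% model$components[, seq_len(n), drop = FALSE]
}

# k-means++ center seeding (Arthur & Vassilvitskii style)
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1L, ] <- x[sample.int(n, 1L), ]
  d2 <- rowSums(sweep(x, 2L, centers[1L, ])^2)
  for (j in seq_len(k - 1L) + 1L) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j, ] <- x[sample.int(n, 1L, prob = p), ]
    d2 <- pmin(d2, rowSums(sweep(x, 2L, centers[j, ])^2))
  }
  centers
}

#' Seeded best-of-n k-means clustering of projected features
#'
#' Runs [stats::kmeans()] `n_init` times from k-means++ seedings and keeps
#' the run with the lowest within-cluster sum of squares. Fully
#' deterministic given `seed` (the caller's RNG stream is untouched);
#' k-means is seed-dependent by nature, so best-of-many plus an explicit
#' logged seed makes classifications reproducible.
#'
#' @param x numeric matrix `[n_events x d]` (typically 3 projected
#'   components).
#' @param k number of clusters (>= 2 here; k = 1 only makes sense inside
#'   [elbow_wk()]).
#' @param seed integer seed.
#' @param n_init restarts (default 50).
#' @return An object of class `wave_clustering`: `labels` (1..k, every
#'   cluster non-empty), `centroids`, `tot_withinss`, `k`, `seed`,
#'   `n_init`, `semantic_labels` (filled by [assign_semantic_labels()]).
#' @export
kmeans_cluster <- function(x, k, seed = 1L, n_init = 50L) {
  x <- as.matrix(x)
  if (k < 2L) stop("k must be >= 2 for clustering (k = 1 only in elbow_wk)")
  if (nrow(x) < k) stop("fewer events than clusters")
  fit <- with_seed(seed, kmeans_best_of(x, k, n_init))
  structure(list(labels = fit$cluster, centroids = fit$centers,
                 tot_withinss = fit$tot.withinss, k = k,
                 seed = as.integer(seed), n_init = as.integer(n_init),
                 semantic_labels = NULL),
            class = "wave_clustering")
}

# best-of-n_init k-means; assumes an RNG stream is already in place
kmeans_best_of <- function(x, k, n_init) {
  best <- NULL
  for (i in seq_len(n_init)) {
    fit <- tryCatch(
      suppressWarnings(stats::kmeans(x, kmeanspp_centers(x, k),
                                     iter.max = 100L, algorithm = "Lloyd")),
      error = function(e) NULL)
    if (is.null(fit) || any(fit$size == 0)) next
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  if (is.null(best)) stop("k-means failed to produce a valid partition")
  best
}

#' @export
print.wave_clustering <- function(x, ...) {
  cat(sprintf("wave_clustering: k = %d, n = %d, W_k = %.4g (seed %d, %d inits)\n",
              x$k, length(x$labels), x$tot_withinss, x$seed, x$n_init))
  if (!is.null(x$semantic_labels))
    cat("  semantic:", paste(sprintf("%d=%s", seq_along(x$semantic_labels),
                                     x$semantic_labels), collapse = ", "), "\n")
  invisible(x)
}

#' Elbow curve for cluster-number selection
#'
#' Computes the within-cluster sum of squares W_k over a range of k (best
#' of `n_init` restarts each; W_1 is the total sum of squares about the
#' mean). The suggested k is the interior point of maximum curvature —
#' the largest second difference `W_(k-1) - 2 W_k + W_(k+1)` — i.e. where
#' the decrease of W_k flattens. When the maximum curvature is under twice
#' the median curvature the curve has no clear elbow and the suggestion is
#' flagged low-confidence.
#'
#' @param x numeric matrix of projected features.
#' @param k_range integers to evaluate (default 1:8).
#' @param seed,n_init as in [kmeans_cluster()].
#' @return An object of class `elbow_curve`: `k_values`, `W_k`,
#'   `suggested_k`, `low_confidence`.
#' @export
elbow_wk <- function(x, k_range = 1:8, seed = 1L, n_init = 50L) {
  x <- as.matrix(x)
  k_range <- sort(unique(as.integer(k_range)))
  stopifnot(min(k_range) >= 1L, max(k_range) <= nrow(x))
  Wk <- with_seed(seed, vapply(k_range, function(k) {
    if (k == 1L) sum(sweep(x, 2L, colMeans(x))^2)
    else if (k == nrow(x)) 0
    else kmeans_best_of(x, k, n_init)$tot.withinss
  }, 0))
  Wk <- cummin(Wk)  # nested optima: enforce monotone non-increase
  suggested <- NA_integer_; lowconf <- TRUE
  if (length(k_range) >= 3L) {
    curv <- Wk[-c(length(Wk) - 1L, length(Wk))] -
      2 * Wk[-c(1L, length(Wk))] + Wk[-(1:2)]
    suggested <- k_range[-c(1L, length(k_range))][which.max(curv)]
    lowconf <- max(curv) < 2 * stats::median(curv)
  }
  structure(list(k_values = k_range, W_k = Wk, suggested_k = suggested,
                 low_confidence = lowconf),
            class = "elbow_curve")
}

#' Attach semantic direction labels to wave clusters
#'
#' For each cluster the per-event delay maps are averaged into a centroid
#' map, then classified geometrically:
#' \enumerate{
#'   \item a plane is fitted to the map over good channels; if R^2 >= 0.8
#'     the label is the gradient's cardinal direction — the gradient of a
#'     delay map points along the propagation direction (later arrivals
#'     downstream), so e.g. a negative x-gradient is `right_to_left`;
#'   \item otherwise the winding of the map around the array centre is
#'     measured on the angular ordering of the channels; unit |winding|
#'     labels the cluster `spiral`;
#'   \item otherwise `other` (e.g. an all-zero map: no gradient, no
#'     winding).
#' }
#'
#' Directions are in the array frame (columns increase to the "right",
#' rows downward), not anatomical.
#'
#' @param clustering a [kmeans_cluster()] result.
#' @param delay_maps list of `grid_map`s, one per event (same order as the
#'   feature rows that were clustered).
#' @return The clustering with `semantic_labels` filled (one per cluster).
#' @export
assign_semantic_labels <- function(clustering, delay_maps) {
  stopifnot(length(delay_maps) == length(clustering$labels))
  geometry <- attr(delay_maps[[1L]], "geometry")
  labs <- character(clustering$k)
  for (cl in seq_len(clustering$k)) {
    maps <- delay_maps[clustering$labels == cl]
    cen <- Reduce(`+`, lapply(maps, unclass)) / length(maps)
    labs[cl] <- classify_delay_map(cen, geometry)
  }
  clustering$semantic_labels <- labs
  clustering
}

# classify one [n_rows x n_cols] delay map: plane direction / spiral / other
classify_delay_map <- function(m, geometry) {
  co <- geometry$channel_order
  gc <- good_channels(geometry)
  v <- m[cbind(co[gc, "row"], co[gc, "col"])]
  pos <- channel_positions(geometry)[gc, , drop = FALSE]
  ok <- is.finite(v)
  v <- v[ok]; pos <- pos[ok, , drop = FALSE]
  if (length(v) < 4L || stats::sd(v) == 0) return("other")
  fit <- stats::lm.fit(cbind(1, pos), v)
  r2 <- 1 - sum(fit$residuals^2) / sum((v - mean(v))^2)
  if (is.finite(r2) && r2 >= 0.8) {
    g <- fit$coefficients[2:3]   # (d delay/dx, d delay/dy): propagation dir
    return(if (abs(g[1]) >= abs(g[2])) {
      if (g[1] < 0) "right_to_left" else "left_to_right"
    } else {
      if (g[2] > 0) "top_to_bottom" else "bottom_to_top"
    })
  }
  w <- map_winding(v, pos)
  if (is.finite(w) && abs(w) == 1L) "spiral" else "other"
}

# winding number of a delay field around the channel centroid: delays are
# rescaled to phases over their span and the wrapped increments along the
# angular ordering are summed; a pure rotation gives +/-1, a plane 0
map_winding <- function(v, pos) {
  ctr <- colMeans(pos)
  theta <- atan2(pos[, 2] - ctr[2], pos[, 1] - ctr[1])
  o <- order(theta)
  span <- diff(range(v))
  if (span == 0) return(0L)
  phi <- 2 * pi * (v[o] - min(v)) / span * (1 - 1e-9)
  d <- diff(c(phi, phi[1L]))
  d <- (d + pi) %% (2 * pi) - pi   # wrap increments to (-pi, pi]
  as.integer(round(sum(d) / (2 * pi)))
}
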