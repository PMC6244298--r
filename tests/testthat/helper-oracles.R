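# Independent oracles and generators used across the suite.

# exhaustive lag-scan delay oracle: per-lag Pearson via stats::cor on the
# overlapping segments, ties broken toward smallest |lag| then negative
oracle_xcorr_lag <- function(a, b, max_lag) {
  n <- length(a)
  lags <- (-max_lag):max_lag
  r <- vapply(lags, function(L) {
    if (L >= 0) { x <- a[seq_len(n - L)]; y <- b[(1 + L):n] }
    else        { x <- a[(1 - L):n];      y <- b[seq_len(n + L)] }
    if (stats::sd(x) == 0 || stats::sd(y) == 0) -Inf else stats::cor(x, y)
  }, 0)
  ord <- order(abs(lags), lags)
  lags[ord][which.max(r[ord])]
}

# every set partition of n elements, as rows of membership labels
# (restricted growth strings)
all_partitions <- function(n) {
  out <- list()
  rec <- function(pref, maxv) {
    if (length(pref) == n) { out[[length(out) + 1L]] <<- pref; return() }
    for (v in seq_len(maxv + 1L)) rec(c(pref, v), max(maxv, v))
  }
  rec(integer(0), 0L)
  do.call(rbind, out)
}

# exhaustive maximum modularity via the independent pairwise form
# Q(p) = sum_{i,j same community} ( w_ij / tw - d_i d_j / tw^2 )
oracle_max_modularity <- function(w) {
  diag(w) <- 0
  w[w < 0] <- 0
  tw <- sum(w)
  d <- rowSums(w)
  B <- w / tw - outer(d, d) / tw^2
  P <- all_partitions(nrow(w))
  max(apply(P, 1L, function(p) sum(B[outer(p, p, "==")])))
}

# independent double-sum modularity (per-community accumulation)
oracle_modularity <- function(w, labels, resolution = 1) {
  diag(w) <- 0
  w[w < 0] <- 0
  tw <- sum(w)
  d <- rowSums(w)
  B <- w / tw - resolution * outer(d, d) / tw^2
  sum(B[outer(labels, labels, "==")])
}

# independent Pearson chi-squared: explicit expected-count double sum
oracle_chi2 <- function(tab) {
  n <- sum(tab)
  E <- outer(rowSums(tab), colSums(tab)) / n
  sum((tab - E)^2 / E)
}

# isotropic Gaussian blobs with known labels
make_blobs <- function(n_per, centers, sd = 1) {
  x <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
    sweep(matrix(stats::rnorm(n_per * ncol(centers), sd = sd),
                 n_per, ncol(centers)), 2L, -centers[i, ])))
  list(x = x, labels = rep(seq_len(nrow(centers)), each = n_per))
}

# a mixed set of synthetic spike events: right-to-left / left-to-right
# plane waves (direction jittered +-15 degrees) and spirals (centre
# jittered), with per-event white noise; returns events and true labels
make_wave_event_set <- function(n_per, fs = 1000, geom = grid_geometry(),
                                noise_sd = 0, seed0 = 0, window_s = 0.2) {
  events <- list(); truth <- integer(0)
  id <- 0L
  add <- function(ev, lab) {
    events[[length(events) + 1L]] <<- ev$event
    truth[length(truth) + 1L] <<- lab
  }
  for (i in seq_len(n_per)) {
    id <- id + 1L
    ang <- pi + stats::runif(1, -pi / 12, pi / 12)
    add(gen_plane_wave_event(geom, fs,
          wave_spec("plane", direction = c(cos(ang), sin(ang))),
          noise_spec(white_sd = noise_sd, seed = seed0 + id),
          window_s = window_s, event_id = id), 1L)
    id <- id + 1L
    ang <- stats::runif(1, -pi / 12, pi / 12)
    add(gen_plane_wave_event(geom, fs,
          wave_spec("plane", direction = c(cos(ang), sin(ang))),
          noise_spec(white_sd = noise_sd, seed = seed0 + id),
          window_s = window_s, event_id = id), 2L)
    id <- id + 1L
    ctr <- colMeans(channel_positions(geom)) +
      stats::runif(2, -geom$pitch / 2, geom$pitch / 2) + geom$pitch / 7
    add(gen_spiral_wave_event(geom, fs,
          wave_spec("spiral", center = ctr),
          noise_spec(white_sd = noise_sd, seed = seed0 + id),
          window_s = window_s, event_id = id), 3L)
  }
  list(events = events, truth = truth)
}

# ARI oracle from mclust (Suggests); the suite requires it
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
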