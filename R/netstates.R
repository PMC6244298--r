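#' Per-event high-gamma functional connection matrix
#'
#' Power-based connectivity: for each good channel pair the amplitude
#' envelopes (analytic-signal magnitudes) of the high-gamma-filtered,
#' common-mode-subtracted segment are cross-correlated and the maximum
#' normalised correlation over lags in `[-max_lag, max_lag]` is taken.
#' Maximising over signed lags makes the measure symmetric and robust to
#' the propagation delays between channels — a connectivity estimate that
#' punished time delays would bias the comparison across propagation
#' types. Per-channel amplitude scaling cancels in the normalisation.
#'
#' The caller band-limits first (80–120 Hz preset) and subtracts the
#' common mode; see [preset_filter()] and [subtract_common_mode()].
#'
#' @param ev a [spike_event()] whose segment is already high-gamma
#'   filtered and re-referenced, or a plain `[channels x samples]` matrix
#'   (then `fs` and `geometry` are required).
#' @param max_lag_ms lag range, ms (default 20).
#' @param use_envelope correlate amplitude envelopes (default) or the
#'   band-passed signals themselves (sensitivity variant).
#' @param fs,geometry used only when `ev` is a bare matrix.
#' @return An object of class `connection_matrix`: `c` (symmetric, unit
#'   diagonal, `NA` rows for bad or zero-variance channels), `event_id`,
#'   `max_lag_ms`.
#' @export
connection_matrix <- function(ev, max_lag_ms = 20, use_envelope = TRUE,
                              fs = NULL, geometry = NULL) {
  if (inherits(ev, "spike_event")) {
    seg <- ev$segment; fs <- ev$fs; geometry <- ev$geometry
    id <- ev$event_id
  } else {
    seg <- as.matrix(ev); id <- NA
    stopifnot(!is.null(fs), !is.null(geometry))
  }
  gc <- good_channels(geometry)
  if (length(gc) < 2L) stop("need at least 2 good channels")
  sig <- seg[gc, , drop = FALSE]
  zv <- apply(sig, 1L, stats::var) == 0
  if (any(zv)) {
    warning("zero-variance channel(s) excluded: ",
            paste(gc[zv], collapse = ", "))
    gc <- gc[!zv]; sig <- sig[!zv, , drop = FALSE]
  }
  if (use_envelope)
    sig <- t(apply(sig, 1L, function(x) Mod(analytic_signal(x))))
  ml <- min(round(max_lag_ms / 1000 * fs), ncol(sig) - 2L)
  n_ch <- nrow(seg)
  C <- matrix(NA_real_, n_ch, n_ch)
  C[cbind(gc, gc)] <- 1
  for (ii in seq_along(gc)) for (jj in seq_along(gc)) {
    if (jj <= ii) next
    r <- max(xcorr_all_lags(sig[ii, ], sig[jj, ], ml)$r)
    C[gc[ii], gc[jj]] <- C[gc[jj], gc[ii]] <- r
  }
  structure(list(c = C, event_id = id, max_lag_ms = max_lag_ms,
                 use_envelope = use_envelope, geometry = geometry),
            class = "connection_matrix")
}

#' Similarity graph over events
#'
#' Pearson correlation between the vectorised strict upper triangles of
#' every pair of connection matrices (the matrices are symmetric with unit
#' diagonal, so the full vectorisation would double-count and inflate the
#' correlations). The result is an undirected weighted graph on events:
#' symmetric, unit diagonal, entries in \[-1, 1\].
#'
#' @param cms list of [connection_matrix()] objects with consistent
#'   channel sets.
#' @return numeric `[n_events x n_events]` similarity matrix of class
#'   `similarity_graph`.
#' @export
similarity_graph <- function(cms) {
  stopifnot(length(cms) >= 2L)
  vecs <- lapply(cms, function(cm) {
    v <- cm$c[upper.tri(cm$c)]
    v[is.finite(v)]
  })
  len <- lengths(vecs)
  if (length(unique(len)) != 1L)
    stop("connection matrices have inconsistent channel sets")
  for (i in seq_along(vecs)) if (stats::sd(vecs[[i]]) == 0)
    stop("constant connection matrix for event ",
         format(cms[[i]]$event_id), ": similarity undefined")
  V <- do.call(cbind, vecs)
  s <- stats::cor(V)
  diag(s) <- 1
  structure(s, class = c("similarity_graph", "matrix"))
}

# non-negative weight matrix for modularity: clip negatives, zero diagonal
clip_graph <- function(g) {
  w <- unclass(as.matrix(g))
  diag(w) <- 0
  n_clipped <- sum(w < 0)
  w[w < 0] <- 0
  attr(w, "n_clipped") <- n_clipped
  w
}

#' Newman–Girvan modularity of a partition
#'
#' Weighted modularity `Q = sum_c [ e_c / m - gamma (d_c / 2m)^2 ]` on the
#' clipped (non-negative, zero-diagonal) graph, where `e_c` is the total
#' edge weight inside community c, `d_c` the total degree of its nodes and
#' `m` the total edge weight. The all-in-one partition scores exactly 0.
#'
#' @param g a [similarity_graph()] (or any symmetric weight matrix).
#' @param communities integer labels per node; gaps in the id set are
#'   tolerated (relabelled internally).
#' @param resolution gamma, default 1 (classic modularity).
#' @return scalar Q in \[-1, 1\].
#' @export
modularity_q <- function(g, communities, resolution = 1) {
  w <- clip_graph(g)
  n <- nrow(w)
  stopifnot(length(communities) == n)
  communities <- match(communities, unique(communities))
  tw <- sum(w)                 # 2m; shared by both terms so that the
  if (tw == 0) return(0)       # all-in-one partition scores exactly 0
  Q <- 0
  for (c in unique(communities)) {
    i <- communities == c
    e2 <- sum(w[i, i])                   # 2 e_c
    d <- sum(w[i, , drop = FALSE])       # d_c
    Q <- Q + e2 / tw - resolution * (d / tw)^2
  }
  Q
}

# one sweep of greedy single-node moves (phase 1 of Louvain); returns labels
refine_moves <- function(w, labels, resolution) {
  n <- nrow(w)
  m <- sum(w) / 2
  if (m == 0) return(labels)
  deg <- rowSums(w)
  improved <- TRUE
  guard <- 0L
  while (improved && guard < 100L) {
    improved <- FALSE; guard <- guard + 1L
    for (v in seq_len(n)) {
      cur <- labels[v]
      cand <- unique(labels[w[v, ] > 0])
      cand <- union(cand, cur)
      # gain of moving v into community c (v removed from its own first)
      lab_v <- labels; lab_v[v] <- 0L
      d_tot <- vapply(cand, function(c) sum(deg[lab_v == c]), 0)
      k_in <- vapply(cand, function(c) sum(w[v, lab_v == c]), 0)
      gain <- k_in / m - resolution * deg[v] * d_tot / (2 * m^2)
      best <- cand[which.max(gain)]
      if (best != cur && max(gain) > gain[cand == cur] + 1e-12) {
        labels[v] <- best
        improved <- TRUE
      }
    }
  }
  match(labels, unique(labels))
}

# greedy community merges (the aggregation move of Louvain): apply the
# best Q-improving pairwise merge until none remains
merge_communities <- function(w, labels, resolution) {
  repeat {
    labels <- match(labels, unique(labels))
    ids <- unique(labels)
    if (length(ids) < 2L) return(labels)
    q0 <- modularity_q(w, labels, resolution)
    best_gain <- 0; best_pair <- NULL
    for (a in seq_along(ids)) for (b in seq_along(ids)) {
      if (b <= a) next
      lab2 <- labels
      lab2[lab2 == ids[b]] <- ids[a]
      gain <- modularity_q(w, lab2, resolution) - q0
      if (gain > best_gain + 1e-12) { best_gain <- gain; best_pair <- c(a, b) }
    }
    if (is.null(best_pair)) return(labels)
    labels[labels == ids[best_pair[2]]] <- ids[best_pair[1]]
  }
}

# local optimum under both node moves and community merges
polish_partition <- function(w, labels, resolution) {
  repeat {
    q0 <- modularity_q(w, labels, resolution)
    labels <- refine_moves(w, labels, resolution)
    labels <- merge_communities(w, labels, resolution)
    if (modularity_q(w, labels, resolution) <= q0 + 1e-12) return(labels)
  }
}

#' Community detection on the event similarity graph
#'
#' Louvain-style greedy modularity maximisation: negative similarities are
#' clipped to zero (classic modularity is defined for non-negative
#' weights; clip counts are recorded), then `n_init` restarts of the
#' Louvain algorithm under seeded node permutations, each polished to a
#' local optimum under single-node moves and community merges, and the
#' partition with the highest
#' [modularity_q()] wins. Deterministic given `seed`. The returned Q is
#' never below the all-in-one partition's 0.
#'
#' @param g a [similarity_graph()].
#' @param resolution modularity resolution gamma (default 1).
#' @param seed integer seed.
#' @param n_init restarts (default 20).
#' @return An object of class `network_partition`: `communities` (integer
#'   state per event, every state non-empty), `Q`, `resolution`, `seed`,
#'   `n_clipped`.
#' @export
detect_communities <- function(g, resolution = 1, seed = 1L, n_init = 20L) {
  w <- clip_graph(g)
  n <- nrow(w)
  if (sum(w) == 0) {
    warning("all edges zero after clipping; returning a single community")
    return(structure(list(communities = rep(1L, n), Q = 0,
                          resolution = resolution, seed = as.integer(seed),
                          n_clipped = attr(w, "n_clipped")),
                     class = "network_partition"))
  }
  best_lab <- rep(1L, n); best_q <- 0   # all-in-one baseline, Q = 0
  with_seed(seed, {
    for (i in seq_len(n_init)) {
      perm <- sample.int(n)
      gi <- igraph::graph_from_adjacency_matrix(w[perm, perm],
                                                mode = "undirected",
                                                weighted = TRUE)
      cl <- igraph::cluster_louvain(gi, resolution = resolution)
      lab <- integer(n)
      lab[perm] <- as.integer(igraph::membership(cl))
      # two polished candidates per restart: the Louvain partition and a
      # random coarse partition (escapes interleaved local optima)
      rand0 <- sample.int(sample(2:4, 1L), n, replace = TRUE)
      for (lab0 in list(lab, rand0)) {
        labp <- polish_partition(w, lab0, resolution)
        q <- modularity_q(w, labp, resolution)
        if (q > best_q + 1e-12) { best_q <- q; best_lab <- labp }
      }
    }
  })
  structure(list(communities = match(best_lab, unique(best_lab)),
                 Q = best_q, resolution = resolution,
                 seed = as.integer(seed),
                 n_clipped = attr(w, "n_clipped")),
            class = "network_partition")
}

#' @export
print.network_partition <- function(x, ...) {
  cat(sprintf("network_partition: %d states over %d events, Q = %.4f\n",
              length(unique(x$communities)), length(x$communities), x$Q))
  invisible(x)
}
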