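g4 <- grid_geometry(2, 2)
fs <- 1000

test_that("connectivity is delay-robust and scale-invariant", {
  set.seed(6)
  x <- as.numeric(stats::filter(rnorm(560), rep(0.2, 5), sides = 1))
  x[is.na(x)] <- 0
  seg <- rbind(x[51:550], x[41:540],            # delayed copy, 10 samples
               rnorm(500), rnorm(500))
  cm <- connection_matrix(seg, max_lag_ms = 20, use_envelope = FALSE,
                          fs = fs, geometry = g4)
  expect_equal(cm$c[1, 2], 1, tolerance = 1e-6)
  expect_identical(cm$c, t(cm$c))
  expect_true(all(diag(cm$c) == 1))
  expect_true(all(abs(cm$c) <= 1 + 1e-12))

  # per-channel amplitude scaling changes nothing (normalised correlation)
  seg2 <- seg * c(0.2, 5, 1, 3)
  cm2 <- connection_matrix(seg2, max_lag_ms = 20, use_envelope = FALSE,
                           fs = fs, geometry = g4)
  expect_equal(cm2$c, cm$c, tolerance = 1e-9)

  # envelope variant still sees the delayed copy as strongly connected
  cme <- connection_matrix(seg, max_lag_ms = 20, fs = fs, geometry = g4)
  expect_gte(cme$c[1, 2], 0.95)
})

test_that("independent white noise yields weak connectivity (Monte-Carlo null)", {
  set.seed(8)
  vals <- replicate(60, {
    cm <- connection_matrix(matrix(rnorm(4 * 1000), 4, 1000),
                            max_lag_ms = 10, fs = fs, geometry = g4)
    mean(abs(cm$c[upper.tri(cm$c)]))
  })
  expect_lte(mean(vals), 0.15)
})

test_that("planted high-gamma blocks show up in the connection matrix", {
  geom <- grid_geometry()
  set.seed(12)
  hgd <- cortiwave:::gen_hg_drive(64, 400, fs, list(1:32, 33:64), 30,
                                  c(80, 120), 0.8)
  cm <- connection_matrix(hgd, max_lag_ms = 20, fs = fs, geometry = geom)
  within <- c(cm$c[1:32, 1:32][upper.tri(diag(32))],
              cm$c[33:64, 33:64][upper.tri(diag(32))])
  across <- cm$c[1:32, 33:64]
  expect_gt(mean(within), mean(across))
})

test_that("zero-variance channels are excluded with a warning", {
  seg <- rbind(rnorm(300), 0, rnorm(300), rnorm(300))
  expect_warning(cm <- connection_matrix(seg, max_lag_ms = 10, fs = fs,
                                         geometry = g4), "zero-variance")
  expect_true(all(is.na(cm$c[2, ])))
})

test_that("similarity equals the Pearson correlation of strict upper triangles", {
  mk <- function(v) {
    C <- diag(4); C[upper.tri(C)] <- v; C <- C + t(C) - diag(diag(C))
    structure(list(c = C, event_id = 1), class = "connection_matrix")
  }
  set.seed(14)
  tri <- replicate(5, runif(6, -0.5, 0.9), simplify = FALSE)
  s <- similarity_graph(lapply(tri, mk))
  # independent formula oracle on the flattened triangles
  for (i in 1:5) for (j in 1:5) {
    a <- tri[[i]]; b <- tri[[j]]
    r <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(s[i, j], r, tolerance = 1e-12)
  }
  expect_equal(unname(diag(s)), rep(1, 5))

  # duplicates correlate at 1; negated off-diagonals at -1
  s2 <- similarity_graph(list(mk(tri[[1]]), mk(tri[[1]]), mk(-tri[[1]])))
  expect_equal(s2[1, 2], 1)
  expect_equal(s2[1, 3], -1)

  expect_error(similarity_graph(list(mk(rep(0.5, 6)), mk(tri[[1]]))),
               "constant connection matrix")
})

test_that("modularity matches closed forms and independent oracles", {
  w <- matrix(0, 6, 6); w[1:3, 1:3] <- 1; w[4:6, 4:6] <- 1; diag(w) <- 0
  expect_equal(modularity_q(w, c(1, 1, 1, 2, 2, 2)), 0.5)
  expect_identical(modularity_q(w, rep(1, 6)), 0)

  set.seed(19)
  for (i in 1:20) {
    n <- sample(5:9, 1)
    a <- matrix(runif(n * n, -0.2, 1), n, n)
    w <- (a + t(a)) / 2; diag(w) <- 0
    lab <- sample(1:3, n, replace = TRUE)
    expect_equal(modularity_q(w, lab), oracle_modularity(w, lab),
                 tolerance = 1e-12)
    # and against igraph on the clipped graph
    wc <- w; wc[wc < 0] <- 0
    gi <- igraph::graph_from_adjacency_matrix(wc, mode = "undirected",
                                              weighted = TRUE)
    expect_equal(modularity_q(w, lab),
                 igraph::modularity(gi, lab, weights = igraph::E(gi)$weight),
                 tolerance = 1e-9)
  }
})

test_that("community detection recovers planted partitions and homogeneous cliques", {
  # equal-weight clique: all-in-one is optimal, Q = 0
  s <- matrix(0.8, 10, 10); diag(s) <- 1
  p <- detect_communities(s, seed = 3)
  expect_equal(length(unique(p$communities)), 1L)
  expect_identical(p$Q, 0)

  # planted 3 blocks, 20 events each, within 0.9 / across 0.1
  truth <- rep(1:3, each = 20)
  s <- 0.1 + 0.8 * outer(truth, truth, "==")
  diag(s) <- 1
  p <- detect_communities(s, seed = 5)
  expect_equal(ari(p$communities, truth), 1)

  # all-zero graph after clipping
  expect_warning(p0 <- detect_communities(matrix(-0.2, 5, 5), seed = 1),
                 "single community")
  expect_equal(p0$communities, rep(1L, 5))
})

test_that("greedy maximisation attains the exhaustive optimum on small graphs", {
  set.seed(29)
  for (i in 1:20) {
    n <- sample(5:8, 1)
    a <- matrix(runif(n * n) * rbinom(n * n, 1, 0.7), n, n)
    w <- (a + t(a)) / 2; diag(w) <- 0
    if (sum(w) == 0) next
    p <- detect_communities(w, seed = i, n_init = 20)
    expect_equal(p$Q, oracle_max_modularity(w), tolerance = 1e-9)
  }
})

test_that("planted per-type high-gamma structure yields matching network states", {
  geom <- grid_geometry()
  blocks <- list(A = list(1:21, 22:42, 43:64),
                 B = list(c(1:11, 33:42), 12:32, 43:64),
                 C = list(seq(1, 64, 2), seq(2, 64, 2)))
  truth <- rep(c("A", "B", "C"), times = 8)
  set.seed(33)
  cms <- lapply(seq_along(truth), function(i) {
    hgd <- cortiwave:::gen_hg_drive(64, 300, fs, blocks[[truth[i]]], 30,
                                    c(80, 120), 0.9)
    connection_matrix(hgd, max_lag_ms = 20, fs = fs, geometry = geom)
  })
  part <- detect_communities(similarity_graph(cms), seed = 11)
  expect_gte(ari(part$communities, truth), 0.8)
})
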