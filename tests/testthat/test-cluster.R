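test_that("mutual KNN graph reproduces brute-force distances", {
  set.seed(20)
  X <- matrix(rnorm(50 * 3), 50, 3)
  g <- knn_distances(X, K = 6)
  D <- as.matrix(dist(X))
  expect_equal(g$dist,
               D[cbind(g$edges[, 1], g$edges[, 2])], tolerance = 1e-12)
  # mutuality: each endpoint lists the other among its K nearest
  for (e in sample(nrow(g$edges), 20)) {
    i <- g$edges[e, 1]; j <- g$edges[e, 2]
    expect_lte(rank(D[i, -i])[match(j, (1:50)[-i])], 6)
    expect_lte(rank(D[j, -j])[match(i, (1:50)[-j])], 6)
  }

  # identical points give a zero-length edge
  X2 <- rbind(c(0, 0), c(0, 0), c(5, 5))
  g2 <- knn_distances(X2, K = 1)
  expect_true(any(g2$dist == 0))

  # K >= M - 1 yields the complete graph
  g3 <- knn_distances(X[1:10, ], K = 20)
  expect_equal(nrow(g3$edges), choose(10, 2))
})

test_that("Potts interaction strengths follow the closed form", {
  X <- matrix(c(0, 0, 1, 0, 0, 1, 1, 1), 4, 2, byrow = TRUE)
  g <- knn_distances(X, K = 3)
  J <- interaction_strengths(g)
  a <- mean(g$dist)
  khat <- g$avg_neighbours
  expect_equal(J, (1 / khat) * exp(-g$dist^2 / (2 * a^2)), tolerance = 1e-12)

  # closed-form anchors on a synthetic graph with unit average neighbour
  # count: e = 0 gives J = 1/Khat, e = a*sqrt(2) gives J = (1/Khat) e^-1.
  gs <- structure(list(edges = cbind(1:3, 4:6), dist = c(0, 1, 2),
                       n_nodes = 6, K = 1, avg_neighbours = 1),
                  class = "ss_knn_graph")
  as_ <- mean(gs$dist)
  gs$dist <- c(0, as_ * sqrt(2), 3 * as_ - as_ * sqrt(2)) # keep mean = as_
  Js <- interaction_strengths(gs)
  expect_equal(Js[1], 1)
  expect_equal(Js[2], exp(-1))

  # monotone: ordering of J inversely matches ordering of e
  set.seed(21)
  gr <- knn_distances(matrix(rnorm(60), 30, 2), K = 5)
  Jr <- interaction_strengths(gr)
  expect_identical(order(Jr), rev(order(gr$dist)))
})

test_that("Swendsen-Wang correlations hit both temperature limits", {
  blobs <- three_blob_points(n_per = 30, sep = 15)
  g <- knn_distances(blobs$X, K = 5)
  J <- interaction_strengths(g)
  cfg <- spc_config(temperatures = c(0, 5), sweeps = 300, seed = 1)
  G <- spc_sweep(g, J, cfg)

  # T = 0: ferromagnetic limit, G = 1 within every connected component
  expect_true(all(G[, 1] == 1))
  # very hot: independence, G ~ 1/q
  expect_lt(max(abs(G[, 2] - 1 / cfg$q_states)), 0.05)
  expect_true(all(G >= 0 & G <= 1))

  # reproducibility at a fixed seed
  G2 <- spc_sweep(g, J, cfg)
  expect_identical(G, G2)
})

test_that("two dense blobs with one weak bridge decouple at intermediate T", {
  set.seed(22)
  X <- rbind(matrix(rnorm(60, sd = 0.5), 30, 2),
             matrix(rnorm(60, sd = 0.5), 30, 2) + 8)
  g <- knn_distances(X, K = 5)
  # add a single explicit bridge edge between the blobs
  bridge <- c(1L, 31L)
  g$edges <- rbind(g$edges, bridge)
  g$dist <- c(g$dist, sqrt(sum((X[1, ] - X[31, ])^2)))
  J <- interaction_strengths(g)
  cfg <- spc_config(temperatures = 0.05, sweeps = 400, seed = 3)
  G <- spc_sweep(g, J, cfg)
  within <- G[g$edges[, 1] <= 30 & g$edges[, 2] <= 30, 1]
  between <- G[nrow(g$edges), 1]
  expect_gt(mean(within), 0.8)
  expect_lt(between, 0.3)
})

test_that("cluster extraction and temperature selection recover blob structure", {
  blobs <- three_blob_points(n_per = 80, sep = 12)
  cfg <- test_spc_config()
  out <- spc_cluster(blobs$X, cfg)

  expect_equal(length(out$sizes), 3)
  expect_equal(sum(out$sizes) + sum(out$labels == 0), nrow(blobs$X))
  # clusters are (near-)pure: labels agree with construction up to permutation
  tab <- table(out$labels[out$labels > 0], blobs$labels[out$labels > 0])
  expect_gte(sum(apply(tab, 1, max)) / sum(out$sizes), 0.98)

  # with every edge correlated on a connected (complete) graph, one cluster
  gc <- knn_distances(blobs$X, K = nrow(blobs$X))
  one <- extract_clusters(rep(1, nrow(gc$edges)), gc,
                          spc_config(correlation_threshold = 0.5,
                                     min_cluster_size = 10))
  expect_equal(length(one$sizes), 1)
  expect_equal(one$sizes[1], nrow(blobs$X))

  # no edge above threshold leaves all unassigned
  g <- attr(out, "graph")
  none <- extract_clusters(rep(0, nrow(g$edges)), g, cfg)
  expect_equal(length(none$sizes), 0)
  expect_true(all(none$labels == 0))

  # single blob resolves at the lowest grid temperature
  single <- matrix(rnorm(200), 100, 2)
  out1 <- spc_cluster(single, test_spc_config())
  expect_equal(length(out1$sizes), 1)
  expect_equal(out1$chosen_temperature, 0)
})

test_that("cluster labels are invariant to row order up to relabelling", {
  blobs <- three_blob_points(n_per = 60, sep = 12, seed = 5)
  cfg <- test_spc_config()
  a <- spc_cluster(blobs$X, cfg)
  set.seed(77)
  perm <- sample(nrow(blobs$X))
  b <- spc_cluster(blobs$X[perm, ], cfg)
  # partitions agree: contingency table has one nonzero cell per row/col
  tab <- table(a$labels[perm], b$labels)
  agree <- sum(apply(tab, 1, max)) / length(b$labels)
  expect_gte(agree, 0.95)
})

test_that("OPTICS separates blobs and leaves border points unassigned", {
  set.seed(24)
  X <- rbind(matrix(rnorm(160, sd = 0.6), 80, 2),
             matrix(rnorm(160, sd = 0.6), 80, 2) + 10)
  res <- optics_cluster(X, min_samples = 5)
  expect_equal(length(res$sizes), 2)
  tab <- table(res$labels[res$labels > 0], rep(1:2, each = 80)[res$labels > 0])
  expect_equal(sum(apply(tab, 1, max)), sum(res$sizes))

  # eps -> 0: nothing is a core point, everything unassigned
  res0 <- optics_cluster(X, min_samples = 5, eps = 1e-9)
  expect_true(all(res0$labels == 0))

  # permutation invariance up to relabelling
  perm <- sample(nrow(X))
  res2 <- optics_cluster(X[perm, ], min_samples = 5)
  tab2 <- table(res$labels[perm], res2$labels)
  expect_equal(sum(apply(tab2, 1, max)), nrow(X))
})
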