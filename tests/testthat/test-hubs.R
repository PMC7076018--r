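test_that("the absolute graph keeps every nonzero entry as an edge", {
  m <- random_difference(12, p_edge = 0.25, seed = 3)
  g <- absolute_graph(m)
  expect_equal(igraph::ecount(g), sum(m != 0))
  adj <- as.matrix(igraph::as_adjacency_matrix(g))
  expect_equal(adj, (m != 0) + 0, ignore_attr = TRUE)
})

test_that("star and cycle centralities follow closed forms", {
  star <- matrix(0L, 6, 6); star[1, 2:6] <- 1L
  part <- icn_partition(rep(1, 6))
  ct <- centralities(absolute_graph(star), part)
  expect_equal(ct$deg_out, c(5, 0, 0, 0, 0, 0))
  expect_equal(ct$deg_in, c(0, 1, 1, 1, 1, 1))
  expect_equal(ct$pl_out[1], 1)
  expect_true(all(is.nan(ct$pl_out[-1])))   # leaves reach nothing
  cyc <- matrix(0L, 3, 3); cyc[1, 2] <- cyc[2, 3] <- cyc[3, 1] <- 1L
  ct2 <- centralities(absolute_graph(cyc), icn_partition(rep(1, 3)))
  expect_equal(ct2$betweenness, rep(1, 3))
  expect_equal(ct2$pl_out, rep(1.5, 3))     # one node at 1 hop, one at 2
})

test_that("participation is zero when all edges stay within one module", {
  m <- matrix(0L, 6, 6)
  m[1, 2] <- m[1, 3] <- 1L       # node 1's out-edges all in module 1
  m[1, 4] <- 0L
  part <- icn_partition(c(1, 1, 1, 2, 2, 2))
  ct <- centralities(absolute_graph(m), part)
  expect_equal(ct$pc_out[1], 0)
  m[1, 4] <- 1L                   # spread one third of edges to module 2
  ct2 <- centralities(absolute_graph(m), part)
  expect_equal(ct2$pc_out[1], 1 - (2 / 3)^2 - (1 / 3)^2)
  expect_gt(ct2$pc_out[1], ct$pc_out[1])    # spreading raises participation
})

test_that("centralities match first-principles oracles on random graphs", {
  for (i in 1:50) {
    n <- sample(8:30, 1)
    m <- random_difference(n, p_edge = 0.15, seed = 700 + i)
    part <- random_partition(n, 3, seed = 800 + i)
    ct <- centralities(absolute_graph(m), part)
    adj <- (m != 0) + 0
    orc <- oracle_centralities(adj, part$labels)
    expect_equal(ct$deg_in, orc$deg_in, ignore_attr = TRUE)
    expect_equal(ct$deg_out, orc$deg_out, ignore_attr = TRUE)
    expect_equal(ct$betweenness, orc$betweenness, tolerance = 1e-9)
    expect_equal(ct$pc_in, orc$pc_in, tolerance = 1e-12)
    expect_equal(ct$pc_out, orc$pc_out, tolerance = 1e-12)
    expect_equal(ct$pl_in, orc$pl_in, tolerance = 1e-12)
    expect_equal(ct$pl_out, orc$pl_out, tolerance = 1e-12)
  }
})

test_that("hub-score classification equals the rank-and-count oracle", {
  for (i in 1:50) {
    n <- sample(10:30, 1)
    m <- random_difference(n, p_edge = 0.2, seed = 900 + i)
    part <- random_partition(n, 3, seed = 950 + i)
    ct <- centralities(absolute_graph(m), part)
    hs <- hub_score_classify(ct)
    expect_identical(hs$is_hub, oracle_hub_score(ct))
  }
})

test_that("hub criterion boundaries behave as specified", {
  # node 1 dominates every measure -> hub; node ranked in the top third on
  # only two measures per profile -> not a hub
  ct <- data.frame(
    deg_in = c(9, 5, 4, 3, 2, 1, 1, 1, 1),
    deg_out = c(9, 5, 4, 3, 2, 1, 1, 1, 1),
    betweenness = c(9, 1, 5, 4, 3, 2, 1, 1, 1),
    pc_in = c(0.9, 0.8, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7),
    pc_out = c(0.9, 0.8, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7),
    pl_in = c(1, 3, 3, 3, 3, 1.5, 1.2, 2, 2.5),
    pl_out = c(1, 3, 3, 3, 3, 1.5, 1.2, 2, 2.5),
    reach_in = 1, reach_out = 1)
  hs <- hub_score_classify(ct)
  expect_true(hs$is_hub[1])
  # node 2: top-3 of 9 on degree and pc only (betweenness rank 8, pl worst)
  expect_false(hs$is_hub[2])
})

test_that("k-means recovers clearly separated hub groups deterministically", {
  withr::with_seed(17, {
    base <- data.frame(
      deg_in = c(rnorm(5, 20), rnorm(15, 2)),
      deg_out = c(rnorm(5, 20), rnorm(15, 2)),
      betweenness = c(rnorm(5, 50), rnorm(15, 5)),
      pc_in = c(rnorm(5, 0.8, 0.02), rnorm(15, 0.2, 0.02)),
      pc_out = c(rnorm(5, 0.8, 0.02), rnorm(15, 0.2, 0.02)),
      pl_in = c(rnorm(5, 1.2, 0.05), rnorm(15, 3, 0.05)),
      pl_out = c(rnorm(5, 1.2, 0.05), rnorm(15, 3, 0.05)),
      reach_in = 1, reach_out = 1)
  })
  km <- kmeans_classify(base, seed = 2)
  expect_equal(km$is_hub, rep(c(TRUE, FALSE), c(5, 15)))
  expect_identical(km, kmeans_classify(base, seed = 2))
})

test_that("zero-variance centrality features are dropped with a warning", {
  ct <- data.frame(deg_in = rep(3, 10), deg_out = rep(3, 10),
                   betweenness = runif(10), pc_in = runif(10),
                   pc_out = runif(10), pl_in = runif(10) + 1,
                   pl_out = runif(10) + 1, reach_in = 1, reach_out = 1)
  expect_warning(kmeans_classify(ct, seed = 1), "zero-variance")
})

test_that("hub concentration in one module is detected by permutation", {
  part <- icn_partition(rep(1:4, each = 6))
  hubs <- structure(list(method = "hub_score",
                         is_hub = c(rep(TRUE, 6), rep(FALSE, 18))),
                    class = "hub_set")
  res <- hub_icn_test(hubs, part, n_perm = 999, seed = 3)
  expect_equal(res$density[1], 1)
  expect_lte(res$p_high[1], 2 / 1000)
  expect_true(res$significant[1])
  # evenly spread hubs are never significant
  even <- structure(list(method = "hub_score",
                         is_hub = rep(c(TRUE, FALSE), 12)),
                    class = "hub_set")
  res2 <- hub_icn_test(even, part, n_perm = 499, seed = 4)
  expect_false(any(res2$significant))
})

test_that("edge classes sum to the edge count and match brute force", {
  for (i in 1:30) {
    n <- sample(8:25, 1)
    m <- random_difference(n, p_edge = 0.3, seed = 1200 + i)
    withr::with_seed(1300 + i,
                     hubs <- structure(list(is_hub = sample(c(TRUE, FALSE), n,
                                                            replace = TRUE)),
                                       class = "hub_set"))
    cnt <- edge_class_counts(m, hubs)
    expect_equal(sum(cnt), sum(m != 0))
    expect_equal(cnt, oracle_edge_classes(m, hubs$is_hub))
  }
  none <- structure(list(is_hub = rep(FALSE, 6)), class = "hub_set")
  all_h <- structure(list(is_hub = rep(TRUE, 6)), class = "hub_set")
  m <- random_difference(6, p_edge = 0.5, seed = 1)
  expect_equal(unname(edge_class_counts(m, none)["periphery_periphery"]),
               sum(m != 0))
  expect_equal(unname(edge_class_counts(m, all_h)["hub_hub"]), sum(m != 0))
})
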