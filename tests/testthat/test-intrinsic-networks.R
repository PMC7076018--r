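test_that("two-node partial correlation reduces to the pairwise correlation", {
  withr::with_seed(2, {
    x <- rnorm(500)
    y <- 0.6 * x + rnorm(500, sd = 0.8)
  })
  pc <- partial_correlation_lw(cbind(a = x, b = y), shrinkage = 0)
  expect_equal(pc[1, 2], atanh(cor(x, y)), tolerance = 1e-10)
  expect_equal(pc[1, 2], pc[2, 1])
  expect_equal(diag(pc), c(a = 0, b = 0))
})

test_that("Fisher transform matches the closed form", {
  expect_equal(atanh(0.5), 0.5493, tolerance = 1e-4)
})

test_that("partial correlations recover a known precision matrix", {
  # tridiagonal precision: only adjacent nodes are conditionally dependent
  n <- 8
  omega <- diag(2, n)
  for (i in 1:(n - 1)) omega[i, i + 1] <- omega[i + 1, i] <- -0.7
  sigma <- solve(omega)
  withr::with_seed(31, {
    x <- matrix(rnorm(5000 * n), 5000) %*% chol(sigma)
  })
  pc <- tanh(partial_correlation_lw(x))
  truth <- -omega / sqrt(tcrossprod(diag(omega)))
  diag(truth) <- 0
  expect_lt(max(abs(pc - truth)), 0.05)
})

test_that("zero-shrinkage estimate agrees with the naive inverse covariance", {
  withr::with_seed(7, x <- matrix(rnorm(2000 * 5), 2000))
  pc <- tanh(partial_correlation_lw(x, shrinkage = 0))
  prec <- solve(cov(x) * (2000 - 1) / 2000)
  naive <- -prec / sqrt(tcrossprod(diag(prec)))
  diag(naive) <- 0
  expect_equal(unclass(pc), naive, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("analytic shrinkage lies in [0, 1] and grows when T shrinks", {
  # factor-structured data: the scaled-identity target is wrong, so the
  # optimal shrinkage is small at large T and grows as T shrinks
  withr::with_seed(8, {
    f <- matrix(rnorm(4000 * 3), 4000)
    load <- matrix(rnorm(3 * 20), 3)
    big <- f %*% load + matrix(rnorm(4000 * 20), 4000)
  })
  s_big <- attr(ledoit_wolf_cov(big), "shrinkage")
  s_small <- attr(ledoit_wolf_cov(big[1:30, ]), "shrinkage")
  expect_gte(s_big, 0); expect_lte(s_small, 1)
  expect_gt(s_small, s_big)
  expect_lt(s_big, 0.05)
})

test_that("constant nodes are reported by name", {
  x <- cbind(a = rnorm(50), b = rep(1, 50))
  expect_error(partial_correlation_lw(x), "b")
})

test_that("proportional threshold keeps the exact edge budget", {
  withr::with_seed(12, {
    m <- matrix(rnorm(273^2), 273)
    m <- (m + t(m)) / 2; diag(m) <- 0
  })
  thr <- proportional_threshold(m, 0.035)
  expect_equal(sum(thr[upper.tri(thr)] != 0), 1299)  # floor(.035*273*272/2)
  expect_equal(thr, t(thr))
  # kept edges are the largest signed values
  kept <- thr[upper.tri(thr)][thr[upper.tri(thr)] != 0]
  dropped <- m[upper.tri(m)][thr[upper.tri(thr)] == 0]
  expect_gte(min(kept), max(dropped))
})

test_that("threshold tie-breaking and degenerate costs are deterministic", {
  ones <- matrix(1, 10, 10); diag(ones) <- 0
  t1 <- proportional_threshold(ones, 0.2)
  t2 <- proportional_threshold(ones, 0.2)
  expect_identical(t1, t2)
  expect_equal(sum(t1[upper.tri(t1)] != 0), floor(0.2 * 45))
  expect_warning(empty <- proportional_threshold(ones, 0.001), "empty")
  expect_equal(sum(empty), 0)
})

test_that("negative survivors are zeroed for the community detector", {
  m <- matrix(-1, 4, 4); diag(m) <- 0
  expect_message(thr <- proportional_threshold(m, 0.9), "negative")
  expect_true(all(thr >= 0))
})

test_that("map-equation codelength matches hand-computed two-clique value", {
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- 1; w[3, 4] <- w[4, 3] <- 1
  # two disconnected dyads, split partition: no exit flow, q = 0;
  # codelength = -sum p log p over nodes within modules = 1 bit
  expect_equal(map_equation_codelength(w, c(1, 1, 2, 2)), 1)
  # merging everything into one module costs the same here (no exits)
  expect_equal(map_equation_codelength(w, rep(1, 4)), 2)
})

test_that("community detection separates planted cliques every run", {
  w <- matrix(0, 20, 20)
  w[1:10, 1:10] <- 1; w[11:20, 11:20] <- 1; diag(w) <- 0
  w[10, 11] <- w[11, 10] <- 1
  runs <- detect_communities(w, n_runs = 20, seed = 5)
  truth <- rep(1:2, each = 10)
  for (lab in runs) expect_equal(ari(lab, truth), 1)
  expect_identical(runs, detect_communities(w, n_runs = 20, seed = 5))
  # cross-check against an independent map-equation implementation
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE)
  im <- igraph::cluster_infomap(g)
  expect_equal(ari(igraph::membership(im), runs[[1]]), 1)
})

test_that("empty graphs yield an all-unassigned partition", {
  runs <- detect_communities(matrix(0, 5, 5), n_runs = 3, seed = 1)
  expect_equal(length(runs), 1)
  expect_true(all(is.na(runs[[1]])))
})

test_that("co-assignment frequencies match a brute-force count", {
  parts <- list(c(1, 1, 2, 2, NA), c(1, 2, 2, 2, NA), c(1, 1, 1, 2, NA))
  cm <- coassignment_matrix(parts)
  for (i in 1:5) for (j in 1:5) {
    if (i == j) { expect_equal(cm[i, j], 1); next }
    manual <- mean(vapply(parts, function(p)
      !is.na(p[i]) && !is.na(p[j]) && p[i] == p[j], logical(1)))
    expect_equal(cm[i, j], manual)
  }
  expect_equal(attr(cm, "n_runs"), 3)
})

test_that("consensus clustering recovers a noisy planted partition", {
  # six noisy copies of a 3-module block matrix stand in for subjects
  truth <- rep(1:3, each = 8)
  mats <- lapply(1:6, function(s) {
    withr::with_seed(40 + s, {
      m <- matrix(rnorm(24^2, sd = 0.2), 24)
      m <- (m + t(m)) / 2
      m[outer(truth, truth, "==")] <- m[outer(truth, truth, "==")] + 1
      diag(m) <- 0
      structure(m, node_ids = sprintf("n%03d", 1:24))
    })
  })
  part <- consensus_cluster(mats, subject_cost = 0.3, subject_runs = 10,
                            group_threshold = 0.3, group_runs = 20, seed = 2)
  expect_equal(ari(part$labels, truth), 1)
  expect_equal(part$n_modules, 3)
})

test_that("identical subjects give the single-subject consensus", {
  truth <- rep(1:2, each = 6)
  m <- matrix(0.1, 12, 12)
  m[outer(truth, truth, "==")] <- 1
  diag(m) <- 0
  m <- structure(m, node_ids = sprintf("n%03d", 1:12))
  grp <- consensus_cluster(list(m, m, m), subject_cost = 0.4,
                           subject_runs = 10, group_threshold = 0.4,
                           group_runs = 10, seed = 9)
  single <- detect_communities(proportional_threshold(m, 0.4), 10, 11)[[1]]
  expect_equal(ari(grp$labels, single), 1)
})

test_that("node-id mismatches across subjects are rejected", {
  a <- structure(diag(3) * 0, node_ids = c("x", "y", "z"))
  b <- structure(diag(3) * 0, node_ids = c("x", "y", "w"))
  expect_error(consensus_cluster(list(a, b)), "node ids")
})

test_that("ari agrees with mclust and handles unassigned nodes", {
  withr::with_seed(3, {
    for (i in 1:10) {
      a <- sample.int(4, 30, replace = TRUE)
      b <- sample.int(3, 30, replace = TRUE)
      expect_equal(ari(a, b), mclust::adjustedRandIndex(a, b))
    }
  })
  a <- c(1, 1, 2, 2, NA)
  b <- c(1, 1, 2, 2, 2)
  expect_equal(ari(a, b), 1)   # NA pair dropped before comparison
})
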