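test_that("densities match a hand count on the worked example", {
  m <- matrix(0L, 5, 5)
  m[1, 2] <- 1L; m[2, 3] <- 1L; m[1, 4] <- 1L
  part <- icn_partition(c(1, 1, 1, 2, 2))
  dp <- density_by_partition(m, part, "positive")
  expect_equal(dp[1, 1], 2 / 6)
  expect_equal(dp[1, 2], 1 / 6)
  expect_equal(dp[2, 1], 0)
  expect_equal(density_by_partition(m, part, "negative"),
               matrix(0, 2, 2), ignore_attr = TRUE)
})

test_that("empty and complete matrices hit the density bounds", {
  part <- icn_partition(rep(1:2, each = 3))
  zero <- matrix(0L, 6, 6)
  expect_true(all(density_by_partition(zero, part, "positive") == 0))
  full <- matrix(1L, 6, 6); diag(full) <- 0L
  expect_true(all(density_by_partition(full, part, "positive") == 1))
})

test_that("size-1 modules report NaN within-density", {
  m <- matrix(0L, 3, 3); m[1, 2] <- 1L
  part <- icn_partition(c(1, 1, 2))
  d <- density_by_partition(m, part, "positive")
  expect_true(is.nan(d[2, 2]))
})

test_that("densities agree with the brute-force oracle on random instances", {
  for (i in 1:50) {
    m <- random_difference(10, p_edge = 0.3, seed = i)
    part <- random_partition(10, 3, seed = i + 500)
    for (sgn in c(1L, -1L)) {
      mine <- density_by_partition(m, part,
                                   if (sgn > 0) "positive" else "negative")
      expect_equal(unname(mine), oracle_density(m, part$labels, sgn),
                   tolerance = 1e-12)
    }
  }
})

test_that("rewiring preserves signed in/out degrees exactly", {
  for (i in 1:25) {
    m <- random_difference(15, p_edge = 0.2, seed = 100 + i)
    r <- rewire_signed_directed(m, swaps_per_edge = 10, seed = i)
    for (sgn in c(1L, -1L)) {
      expect_identical(rowSums(m == sgn), rowSums(unclass(r) == sgn))
      expect_identical(colSums(m == sgn), colSums(unclass(r) == sgn))
    }
    expect_identical(sum(m == 1L), sum(unclass(r) == 1L))
  }
})

test_that("the two-edge graph admits exactly one alternative configuration", {
  m <- matrix(0L, 4, 4)
  m[1, 2] <- 1L; m[3, 4] <- 1L
  # exhaustive enumeration: the only other two-edge placement with the same
  # in/out degrees is {1->4, 3->2}
  same_degrees <- list()
  for (e1 in 1:16) for (e2 in 1:16) {
    if (e2 <= e1) next
    cand <- matrix(0L, 4, 4); cand[c(e1, e2)] <- 1L
    if (any(diag(cand) != 0)) next
    if (identical(rowSums(cand), rowSums(m)) &&
        identical(colSums(cand), colSums(m)))
      same_degrees <- c(same_degrees, list(cand))
  }
  expect_equal(length(same_degrees), 2)
  swapped <- matrix(0L, 4, 4); swapped[1, 4] <- 1L; swapped[3, 2] <- 1L
  expect_true(any(vapply(same_degrees, identical, logical(1), y = swapped)))
  # the rewirer never leaves this two-state space
  for (s in 1:10) {
    r <- unclass(rewire_signed_directed(m, swaps_per_edge = 5, seed = s))
    edges_at <- which(r == 1L)
    expect_equal(sum(r != 0L), 2)
    expect_true(setequal(edges_at, which(m == 1L)) ||
                  setequal(edges_at, which(swapped == 1L)))
  }
})

test_that("rewiring is deterministic under a fixed seed", {
  m <- random_difference(12, p_edge = 0.25, seed = 9)
  expect_identical(rewire_signed_directed(m, seed = 4),
                   rewire_signed_directed(m, seed = 4))
})

test_that("density permutation p-values are add-one corrected and bounded", {
  withr::with_seed(55, {
    m <- matrix(0L, 24, 24)
    # dense positive block inside module 1, sparse elsewhere
    m[1:8, 1:8][sample(56, 40)] <- 1L
    off <- which(row(m) > 8 | col(m) > 8, arr.ind = TRUE)
    m[off[sample(nrow(off), 30), ]] <- 1L
    diag(m) <- 0L
  })
  part <- icn_partition(rep(1:3, each = 8))
  # n_perm must be large enough that the two-sided permutation floor
  # 2/(1 + n_perm) can clear the Bonferroni level alpha / (2 K^2)
  res <- density_permutation_test(m, part, n_perm = 999, seed = 8)
  expect_true(all(res$p_positive > 0 & res$p_positive <= 1))
  expect_equal(res$n_tests, 2 * 9)
  # planted within-module enrichment sits at the permutation floor
  expect_lte(res$p_positive_enrich[1, 1], 2 / 1000)
  expect_true(res$sig_positive[1, 1])
})

test_that("network degree and chi-square match hand computations", {
  sig_p <- matrix(FALSE, 12, 12); sig_n <- matrix(FALSE, 12, 12)
  # uniform: every module exactly one significant in and out cell
  for (m in 1:12) sig_p[m, (m %% 12) + 1] <- TRUE
  dm <- list(sig_positive = sig_p, sig_negative = sig_n,
             module_names = NULL)
  res <- network_degree_and_chi2(dm)
  expect_true(all(res$degree == 2))
  expect_equal(res$chi2, 0)
  expect_equal(res$p, 1)
  expect_equal(res$df, 11)
  # concentrated: all 12 significant cells involve module 1
  sig_c <- matrix(FALSE, 12, 12); sig_c[1, ] <- TRUE
  # module 1 row gives it degree 12 out; each module one in-degree
  res2 <- network_degree_and_chi2(list(sig_positive = sig_c,
                                       sig_negative = sig_n,
                                       module_names = NULL))
  expect_equal(unname(res2$degree[1]), 12 + 1)  # diagonal adds in + out
  expect_equal(res2$df, 11)
  # all-zero degree vector is undefined
  res0 <- network_degree_and_chi2(list(sig_positive = sig_n,
                                       sig_negative = sig_n,
                                       module_names = NULL))
  expect_true(is.nan(res0$chi2))
})

test_that("a significant within-module cell adds one in- and one out-degree", {
  sig <- matrix(FALSE, 3, 3); sig[2, 2] <- TRUE
  res <- network_degree_and_chi2(list(sig_positive = sig,
                                      sig_negative = matrix(FALSE, 3, 3),
                                      module_names = NULL))
  expect_equal(unname(res$degree), c(0, 2, 0))
})

test_that("relabeling modules leaves density statistics unchanged", {
  m <- random_difference(12, p_edge = 0.3, seed = 77)
  lab <- rep(1:3, each = 4)
  perm <- c(3, 1, 2)
  d1 <- density_by_partition(m, icn_partition(lab), "positive")
  d2 <- density_by_partition(m, icn_partition(perm[lab]), "positive")
  expect_equal(unname(d1), unname(d2[perm, perm]))
})
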