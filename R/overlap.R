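#' Node set within a labelled universe
#'
#' @param members Node indices (or ids) in the set.
#' @param universe Universe size N (indices 1..N) or vector of all ids.
#' @return `node_set` object.
#' @export
node_set <- function(members, universe) {
  if (length(universe) == 1 && is.numeric(universe))
    universe <- seq_len(universe)
  members <- unique(members)
  if (!all(members %in% universe))
    stopf("set members outside the universe")
  structure(list(members = members, universe = universe), class = "node_set")
}

check_same_universe <- function(a, b) {
  if (!identical(a$universe, b$universe))
    stopf("node sets live in different universes")
}

#' Jaccard index of two node sets
#'
#' Intersection over union; 0 when both sets are empty.
#'
#' @param a,b `node_set` objects over the same universe.
#' @return Proportion in \[0, 1\].
#' @export
jaccard <- function(a, b) {
  check_same_universe(a, b)
  u <- length(union(a$members, b$members))
  if (u == 0) return(0)
  length(intersect(a$members, b$members)) / u
}

#' Maximum attainable Jaccard index for given set sizes
#'
#' @param size_a,size_b Set sizes.
#' @return `min(a, b) / max(a, b)`; 0 if either size is zero.
#' @export
max_jaccard <- function(size_a, size_b) {
  if (size_a == 0 || size_b == 0) return(0)
  min(size_a, size_b) / max(size_a, size_b)
}

#' Permutation p-value for a Jaccard index
#'
#' The null redraws set `a` uniformly (same size) from the universe and
#' recomputes its Jaccard index with `b`; the one-sided (enrichment)
#' p-value is `(1 + #null >= observed) / (1 + n_perm)`.
#'
#' @param a,b `node_set` objects over the same universe.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed.
#' @param two_sided If `TRUE`, returns `min(1, 2 min(enrich, deplete))`.
#' @param tie_break `"conservative"` (default) counts ties as extreme (the
#'   add-one rule), the right choice for inference; `"randomized"` breaks
#'   ties uniformly at random, which makes the p-value exactly uniform
#'   under the null and is the appropriate form for calibration checks of
#'   a discrete statistic.
#' @return p-value with attributes `observed` and `null` (the null sample).
#' @export
jaccard_permutation_p <- function(a, b, n_perm = 1000, seed = 1L,
                                  two_sided = FALSE,
                                  tie_break = c("conservative",
                                                "randomized")) {
  tie_break <- match.arg(tie_break)
  check_same_universe(a, b)
  if (n_perm < 100) stopf("n_perm must be >= 100")
  obs <- jaccard(a, b)
  k <- length(a$members)
  draw <- with_seed(seed, {
    null <- vapply(seq_len(n_perm), function(i) {
      jaccard(node_set(sample(a$universe, k), a$universe), b)
    }, numeric(1))
    list(null = null, tie_u = stats::runif(1))
  })
  null <- draw$null
  tie_u <- draw$tie_u
  one_sided <- function(greater) {
    n_beyond <- if (greater) sum(null > obs) else sum(null < obs)
    n_tie <- sum(null == obs)
    if (tie_break == "conservative") {
      (1 + n_beyond + n_tie) / (1 + n_perm)
    } else {
      (n_beyond + tie_u * (1 + n_tie)) / (1 + n_perm)
    }
  }
  p_hi <- one_sided(TRUE)
  p <- if (two_sided) min(1, 2 * min(p_hi, one_sided(FALSE))) else p_hi
  attr(p, "observed") <- obs
  attr(p, "null") <- null
  p
}

#' Reconstruct the 2x2 overlap contingency table
#'
#' Given the universe size, the two set sizes and their Jaccard index, the
#' intersection count is `J (|a| + |b|) / (1 + J)` and the table is unique.
#'
#' @param n Universe size.
#' @param size_a,size_b Set sizes.
#' @param jaccard_index Observed Jaccard index.
#' @return 2x2 matrix `(both, a_only // b_only, neither)`.
#' @export
contingency_from_overlap <- function(n, size_a, size_b, jaccard_index) {
  x <- jaccard_index * (size_a + size_b) / (1 + jaccard_index)
  x <- round(x)
  if (x > min(size_a, size_b) || x < 0 ||
      abs(x / (size_a + size_b - x) - jaccard_index) > 0.005)
    stopf("Jaccard index %g inconsistent with set sizes %d and %d",
          jaccard_index, size_a, size_b)
  tab <- matrix(c(x, size_a - x, size_b - x, n - size_a - size_b + x),
                2, 2, byrow = TRUE,
                dimnames = list(c("in_a", "not_a"), c("in_b", "not_b")))
  if (any(tab < 0)) stopf("sizes exceed the universe")
  tab
}

#' Overlap contingency table of two node sets
#'
#' @param a,b `node_set` objects over the same universe.
#' @return 2x2 matrix (both, a-only // b-only, neither), summing to N.
#' @export
contingency_table <- function(a, b) {
  check_same_universe(a, b)
  x <- length(intersect(a$members, b$members))
  matrix(c(x, length(a$members) - x, length(b$members) - x,
           length(a$universe) - length(union(a$members, b$members))),
         2, 2, byrow = TRUE,
         dimnames = list(c("in_a", "not_a"), c("in_b", "not_b")))
}

#' Odds ratio of a 2x2 table with Wald confidence interval
#'
#' `OR = (a d)/(b c)`; the 95% CI is Wald on the log odds ratio with
#' `SE = sqrt(1/a + 1/b + 1/c + 1/d)`. A single zero cell triggers the
#' Haldane-Anscombe +0.5 correction (flagged in the result); two zero cells
#' in one row or column leave the ratio undefined.
#'
#' @param tab 2x2 matrix of counts.
#' @return List with `or`, `ci95` (length 2), `log_or`, `se`, `corrected`.
#' @export
odds_ratio <- function(tab) {
  tab <- as.matrix(tab)
  if (!identical(dim(tab), c(2L, 2L)) || any(tab < 0))
    stopf("need a 2x2 table of non-negative counts")
  if (any(rowSums(tab == 0) == 2) || any(colSums(tab == 0) == 2))
    stopf("odds ratio undefined: a full row or column of the table is zero")
  corrected <- any(tab == 0)
  t2 <- if (corrected) tab + 0.5 else tab
  or <- (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
  se <- sqrt(sum(1 / t2))
  ci <- exp(log(or) + c(-1, 1) * stats::qnorm(0.975) * se)
  list(or = or, ci95 = ci, log_or = log(or), se = se, corrected = corrected)
}

#' Compare association scores between hubs and non-hubs
#'
#' Statistic: mean score of hubs minus mean score of non-hubs, over the
#' whole brain and within each module (per-module nulls shuffle hub labels
#' within the module). One-sided permutation p with the add-one rule;
#' per-module p-values are additionally Bonferroni-corrected over the K
#' modules.
#'
#' @param scores Numeric per-node association scores (finite).
#' @param hubs A `hub_set`.
#' @param partition [icn_partition()].
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed.
#' @return List with `global` (data frame) and `per_module` (data frame
#'   with `p_bonferroni`); modules lacking hubs or non-hubs get `NaN` with
#'   a warning.
#' @export
association_comparison <- function(scores, hubs, partition, n_perm = 1000,
                                   seed = 1L) {
  if (any(!is.finite(scores))) stopf("association scores must be finite")
  if (n_perm < 100) stopf("n_perm must be >= 100")
  h <- hubs$is_hub
  if (length(scores) != length(h)) stopf("scores and hub set differ in size")
  diff_stat <- function(sc, hh) mean(sc[hh]) - mean(sc[!hh])
  perm_p <- function(sc, hh, seed_i) {
    if (!any(hh) || all(hh)) return(c(NaN, NaN))
    obs <- diff_stat(sc, hh)
    null <- with_seed(seed_i, vapply(seq_len(n_perm), function(i)
      diff_stat(sc, sample(hh)), numeric(1)))
    c(obs, (1 + sum(null >= obs)) / (1 + n_perm))
  }
  g <- perm_p(scores, h, child_seed(seed, 0))
  global <- data.frame(mean_difference = g[1], p = g[2])
  lab <- partition$labels
  k <- partition$n_modules
  rows <- lapply(seq_len(k), function(m) {
    idx <- which(!is.na(lab) & lab == m)
    hm <- h[idx]
    if (!any(hm) || all(hm)) {
      warnf("module %d has no hubs or no non-hubs; NaN", m)
      return(data.frame(module = m, mean_difference = NaN, p = NaN,
                        p_bonferroni = NaN))
    }
    r <- perm_p(scores[idx], hm, child_seed(seed, m))
    data.frame(module = m, mean_difference = r[1], p = r[2],
               p_bonferroni = min(1, r[2] * k))
  })
  list(global = global, per_module = do.call(rbind, rows))
}
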