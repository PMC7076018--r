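#' Within/between-module edge densities of a signed difference matrix
#'
#' For the chosen sign, the (a, b) entry is the number of sign-matching
#' directed edges from module a to module b divided by the number of
#' possible ordered pairs (`n_a (n_a - 1)` within, `n_a n_b` between).
#' Matrices are generally asymmetric because the edges are directed.
#'
#' @param d `difference_matrix` (or plain matrix in {-1, 0, 1}).
#' @param partition [icn_partition()]; unassigned nodes are ignored.
#' @param sign `"positive"` or `"negative"`.
#' @return K x K matrix of proportions (`NaN` within for size-1 modules).
#' @export
density_by_partition <- function(d, partition,
                                 sign = c("positive", "negative")) {
  sign <- match.arg(sign)
  d <- unclass(as.matrix(d))
  lab <- partition$labels
  if (length(lab) != nrow(d))
    stopf("partition covers %d nodes, matrix has %d", length(lab), nrow(d))
  k <- partition$n_modules
  target <- if (sign == "positive") 1L else -1L
  hits <- (d == target)
  diag(hits) <- FALSE
  ok <- !is.na(lab)
  sizes <- tabulate(lab[ok], nbins = k)
  counts <- matrix(0, k, k)
  h <- hits[ok, ok, drop = FALSE]
  lo <- lab[ok]
  counts <- rowsum(t(rowsum(h + 0, lo)), lo)   # K x K edge counts (a -> b)
  counts <- t(as.matrix(counts))
  denom <- outer(sizes, sizes)
  diag(denom) <- sizes * (sizes - 1)
  out <- counts / denom
  out[!is.finite(out)] <- NaN
  dimnames(out) <- list(partition$module_names, partition$module_names)
  out
}

#' Sign- and degree-preserving rewiring of a difference matrix
#'
#' Double-edge swaps applied independently to the positive and the negative
#' edge set: a swap replaces edges a->b, c->d with a->d, c->b when neither
#' target slot is occupied by any edge (either sign) and no self-loop would
#' arise. Per node, in- and out-degree within each sign are preserved
#' exactly. The attempted number of swaps is `swaps_per_edge` times the edge
#' count of each sign; failed attempts are counted in attribute
#' `failed_swaps`.
#'
#' @param d `difference_matrix`.
#' @param swaps_per_edge Rewiring attempts per edge (default 10).
#' @param seed Integer seed.
#' @return Rewired matrix of the same class and attributes.
#' @export
rewire_signed_directed <- function(d, swaps_per_edge = 10, seed = 1L) {
  m <- unclass(as.matrix(d))
  with_seed(seed, {
    failed <- 0L
    for (sgn in c(1L, -1L)) {
      edges <- which(m == sgn, arr.ind = TRUE)
      n_e <- nrow(edges)
      if (n_e < 2) {
        if (n_e > 0) warnf("too few %s edges to swap", ifelse(sgn > 0, "positive", "negative"))
        next
      }
      n_att <- swaps_per_edge * n_e
      for (it in seq_len(n_att)) {
        pick <- sample.int(n_e, 2)
        a <- edges[pick[1], 1]; b <- edges[pick[1], 2]
        cc <- edges[pick[2], 1]; dd <- edges[pick[2], 2]
        if (a == dd || cc == b || b == dd || a == cc) { failed <- failed + 1L; next }
        if (m[a, dd] != 0L || m[cc, b] != 0L) { failed <- failed + 1L; next }
        m[a, b] <- 0L; m[cc, dd] <- 0L
        m[a, dd] <- sgn; m[cc, b] <- sgn
        edges[pick[1], 2] <- dd
        edges[pick[2], 2] <- b
      }
    }
    out <- m
    attributes(out) <- attributes(d)
    attr(out, "failed_swaps") <- failed
    out
  })
}

#' Permutation test of network densities against the rewiring null
#'
#' Observed within/between densities per sign are compared with densities of
#' `n_perm` rewired matrices. Per cell and sign, one-sided enrichment and
#' depletion p-values use the add-one rule `(1 + #null >= obs)/(1 + n_perm)`
#' (and `<=` for depletion); the reported two-sided p is twice the smaller
#' one (capped at 1), assessed against `alpha` Bonferroni-divided by the
#' `2 K^2` density tests.
#'
#' @param d `difference_matrix`.
#' @param partition [icn_partition()].
#' @param n_perm Number of rewired null matrices (>= 100).
#' @param alpha Family-wise level.
#' @param seed Integer seed.
#' @param swaps_per_edge Rewiring attempts per edge per permutation.
#' @return Object of class `density_matrices`: list with `positive`,
#'   `negative` (observed densities), `p_positive`, `p_negative` (two-sided
#'   permutation p), one-sided `p_*_enrich` / `p_*_deplete`, significance
#'   flags `sig_positive` / `sig_negative`, `n_tests` and `alpha`.
#' @export
density_permutation_test <- function(d, partition, n_perm = 1000,
                                     alpha = 0.05, seed = 1L,
                                     swaps_per_edge = 10) {
  if (n_perm < 100) stopf("n_perm must be >= 100")
  k <- partition$n_modules
  obs_p <- density_by_partition(d, partition, "positive")
  obs_n <- density_by_partition(d, partition, "negative")
  ge_p <- le_p <- matrix(0, k, k)
  ge_n <- le_n <- matrix(0, k, k)
  for (i in seq_len(n_perm)) {
    r <- rewire_signed_directed(d, swaps_per_edge, child_seed(seed, i))
    null_p <- density_by_partition(r, partition, "positive")
    null_n <- density_by_partition(r, partition, "negative")
    ge_p <- ge_p + (null_p >= obs_p); le_p <- le_p + (null_p <= obs_p)
    ge_n <- ge_n + (null_n >= obs_n); le_n <- le_n + (null_n <= obs_n)
  }
  one_sided <- function(cnt) (1 + cnt) / (1 + n_perm)
  p_pe <- one_sided(ge_p); p_pd <- one_sided(le_p)
  p_ne <- one_sided(ge_n); p_nd <- one_sided(le_n)
  two_sided <- function(a, b) {
    m <- 2 * pmin(a, b)   # pmin against a scalar would drop the dims
    m[m > 1] <- 1
    m
  }
  p_pos <- two_sided(p_pe, p_pd)
  p_neg <- two_sided(p_ne, p_nd)
  n_tests <- 2 * k^2
  structure(list(positive = obs_p, negative = obs_n,
                 p_positive = p_pos, p_negative = p_neg,
                 p_positive_enrich = p_pe, p_positive_deplete = p_pd,
                 p_negative_enrich = p_ne, p_negative_deplete = p_nd,
                 sig_positive = !is.na(p_pos) & p_pos < alpha / n_tests,
                 sig_negative = !is.na(p_neg) & p_neg < alpha / n_tests,
                 n_tests = n_tests, alpha = alpha, n_perm = n_perm,
                 module_names = partition$module_names),
            class = "density_matrices")
}

#' Network-level degree and uniformity chi-square test
#'
#' Binarizes the significant density cells per sign and counts, per module,
#' its in- plus out-degree over both sign matrices (a significant
#' within-module cell contributes one in- and one out-degree to its own
#' module). The summed degree vector is tested against a uniform
#' distribution with a chi-square goodness-of-fit test (df = K - 1).
#'
#' @param dm A `density_matrices` object (or a list with `sig_positive` and
#'   `sig_negative` logical K x K matrices).
#' @return List with `degree` (K-vector), `chi2`, `df`, `p` (`NaN` when the
#'   degree vector is all zero).
#' @export
network_degree_and_chi2 <- function(dm) {
  deg <- function(sig) rowSums(sig) + colSums(sig)
  degree <- deg(dm$sig_positive) + deg(dm$sig_negative)
  k <- length(degree)
  names(degree) <- dm$module_names %||% seq_len(k)
  if (sum(degree) == 0)
    return(list(degree = degree, chi2 = NaN, df = k - 1, p = NaN))
  expected <- sum(degree) / k
  chi2 <- sum((degree - expected)^2 / expected)
  list(degree = degree, chi2 = chi2, df = k - 1,
       p = stats::pchisq(chi2, k - 1, lower.tail = FALSE))
}
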