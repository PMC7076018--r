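#' Ledoit-Wolf shrinkage covariance
#'
#' Analytic convex combination of the maximum-likelihood sample covariance
#' with a scaled identity. The shrinkage intensity minimizes the expected
#' Frobenius loss and guarantees an invertible estimate even when the number
#' of nodes approaches the number of time points.
#'
#' @param x T x N data matrix (rows = observations).
#' @param shrinkage Optional fixed intensity in \[0, 1\]; `NULL` (default)
#'   uses the analytic Ledoit-Wolf value.
#' @return Covariance matrix with attribute `shrinkage`.
#' @export
ledoit_wolf_cov <- function(x, shrinkage = NULL) {
  x <- as.matrix(x)
  n_t <- nrow(x); n <- ncol(x)
  if (n_t <= 3) stopf("need more than 3 time points, got %d", n_t)
  xc <- sweep(x, 2, colMeans(x))
  s <- crossprod(xc) / n_t
  mu <- sum(diag(s)) / n
  if (is.null(shrinkage)) {
    delta2 <- sum((s - diag(mu, n))^2) / n
    # E||x_t x_t' - S||^2_F summed over t, using sum_t outer_t = T * S
    beta2bar <- (sum(rowSums(xc^2)^2) - n_t * sum(s^2)) / (n * n_t^2)
    shrinkage <- if (delta2 > 0) min(beta2bar, delta2) / delta2 else 0
  }
  stopifnot(shrinkage >= 0, shrinkage <= 1)
  out <- (1 - shrinkage) * s + shrinkage * diag(mu, n)
  attr(out, "shrinkage") <- shrinkage
  out
}

#' Fisher-z partial correlation matrix with Ledoit-Wolf shrinkage
#'
#' Inverts the shrunk covariance; the partial correlation between nodes i
#' and j given all others is `-P_ij / sqrt(P_ii P_jj)` for precision P, and
#' the returned values are its Fisher r-to-z transform (zero diagonal).
#'
#' @param ts A [roi_timeseries()] (or plain T x N matrix).
#' @param shrinkage Optional fixed shrinkage intensity (0 = sample
#'   covariance).
#' @return N x N symmetric `connectivity_matrix` with attributes
#'   `node_ids` and `shrinkage`.
#' @export
partial_correlation_lw <- function(ts, shrinkage = NULL) {
  x <- if (inherits(ts, "roi_timeseries")) ts$values else as.matrix(ts)
  node_ids <- colnames(x)
  if (is.null(node_ids)) node_ids <- sprintf("n%03d", seq_len(ncol(x)))
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stopf("constant time series for node(s): %s",
          paste(node_ids[sds == 0], collapse = ", "))
  sigma <- ledoit_wolf_cov(x, shrinkage)
  prec <- chol2inv(chol(sigma))
  d <- sqrt(diag(prec))
  pc <- -prec / tcrossprod(d)
  diag(pc) <- 0
  pc <- pmin(pmax(pc, -1 + 1e-12), 1 - 1e-12)
  z <- atanh(pc)
  dimnames(z) <- list(node_ids, node_ids)
  structure(z, shrinkage = attr(sigma, "shrinkage"), node_ids = node_ids,
            class = c("connectivity_matrix", "matrix"))
}

#' Proportional threshold of a weighted undirected matrix
#'
#' Retains the `floor(cost * N(N-1)/2)` largest-valued undirected edges
#' (signed value, not magnitude) and zeroes the rest. Ties at the cutoff are
#' broken deterministically by (weight descending, node pair lexicographic).
#' Surviving negative weights, if any, are set to zero with a message, since
#' downstream community detection requires non-negative weights.
#'
#' @param m Symmetric numeric matrix.
#' @param cost Proportion of edges to keep, in (0, 1).
#' @return Sparse (mostly zero) symmetric matrix of retained weights.
#' @export
proportional_threshold <- function(m, cost) {
  m <- unclass(as.matrix(m))
  if (!(cost > 0 && cost < 1)) stopf("cost must lie in (0, 1)")
  n <- nrow(m)
  ut <- which(upper.tri(m))
  k <- floor(cost * n * (n - 1) / 2)
  out <- matrix(0, n, n, dimnames = dimnames(m))
  if (k == 0) {
    warnf("cost %g keeps no edges on %d nodes: empty graph", cost, n)
    return(out)
  }
  w <- m[ut]
  ord <- order(-w, ut)   # weight descending, then lexicographic pair index
  keep <- ut[ord[seq_len(min(k, length(ut)))]]
  out[keep] <- m[keep]
  n_neg <- sum(out[keep] < 0)
  if (n_neg > 0) {
    message(sprintf("proportional_threshold: zeroing %d surviving negative weight(s)",
                    n_neg))
    out[keep][out[keep] < 0] <- 0
  }
  out[lower.tri(out)] <- t(out)[lower.tri(out)]
  out
}
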