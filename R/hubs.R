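#' Absolute (unsigned) directed graph of a difference matrix
#'
#' Every nonzero entry, positive or negative, becomes a directed unweighted
#' edge — nodal statistics treat increases and decreases alike.
#'
#' @param d `difference_matrix`.
#' @return An [igraph::graph] (directed, unweighted).
#' @export
absolute_graph <- function(d) {
  m <- abs(unclass(as.matrix(d)))
  diag(m) <- 0
  igraph::graph_from_adjacency_matrix(m, mode = "directed")
}

#' Directed centrality profile of every node
#'
#' Computes, on the absolute directed graph: in/out degree, betweenness
#' (directed, shortest-path ties credited fractionally), in/out
#' participation coefficients over the partition's modules
#' (`1 - sum_m (k_im / k_i)^2`), and in/out nodal path length (mean
#' shortest-path hops to/from all reachable nodes). Unreachable pairs are
#' excluded from the path-length mean; a node with no reachable targets
#' gets `NaN` and is flagged in `reach_out` / `reach_in`.
#'
#' @param g Directed [igraph::graph] (from [absolute_graph()]).
#' @param partition [icn_partition()] covering all nodes of `g`.
#' @return `centrality_table` data frame with columns `deg_in`, `deg_out`,
#'   `betweenness`, `pc_in`, `pc_out`, `pl_in`, `pl_out`, `reach_in`,
#'   `reach_out`.
#' @export
centralities <- function(g, partition) {
  n <- igraph::vcount(g)
  if (length(partition$labels) != n)
    stopf("partition covers %d nodes, graph has %d", length(partition$labels), n)
  a <- as.matrix(igraph::as_adjacency_matrix(g))
  deg_in <- colSums(a)
  deg_out <- rowSums(a)
  btw <- igraph::betweenness(g, directed = TRUE)
  lab <- partition$labels
  k <- partition$n_modules
  pc <- function(adj_rows, deg) {
    ok <- !is.na(lab)
    per_mod <- rowsum(t(adj_rows[, ok, drop = FALSE]), lab[ok])  # K x n
    frac2 <- sweep(t(per_mod), 1, pmax(deg, 1), "/")^2
    ifelse(deg > 0, 1 - rowSums(frac2), 0)
  }
  pc_out <- pc(a, deg_out)
  pc_in <- pc(t(a), deg_in)
  d_out <- igraph::distances(g, mode = "out")
  diag(d_out) <- NA
  pl <- function(dmat) {
    reach <- rowSums(is.finite(dmat), na.rm = TRUE)
    m <- apply(dmat, 1, function(r) {
      r <- r[is.finite(r)]
      if (length(r) == 0) NaN else mean(r)
    })
    list(pl = m, reach = reach / (ncol(dmat) - 1))
  }
  po <- pl(d_out)
  pi_ <- pl(t(d_out))   # distances into each node
  out <- data.frame(node = partition$node_ids,
                    deg_in = deg_in, deg_out = deg_out, betweenness = btw,
                    pc_in = pc_in, pc_out = pc_out,
                    pl_in = pi_$pl, pl_out = po$pl,
                    reach_in = pi_$reach, reach_out = po$reach)
  rownames(out) <- NULL
  class(out) <- c("centrality_table", "data.frame")
  out
}

# Rank-based top-fraction membership: `value` ranked descending (ascending
# when smaller is more central), stable ties by node index; nodes flagged
# `worst` are pushed to the bottom regardless of value.
top_fraction_mask <- function(value, n_top, ascending = FALSE,
                              worst = rep(FALSE, length(value))) {
  v <- if (ascending) value else -value
  v[is.na(v)] <- Inf
  v[worst] <- Inf
  ord <- order(v, seq_along(v))
  mask <- logical(length(v))
  mask[ord[seq_len(min(n_top, length(v)))]] <- TRUE
  mask
}

#' Hub classification by hub scores
#'
#' A node qualifies within a profile (in-profile: `deg_in`, `betweenness`,
#' `pc_in`, `pl_in`; out-profile analogous) when it ranks in the top
#' `top_fraction` on at least `min_measures` of the four measures; path
#' length is ranked ascending (shorter = more central) and nodes reaching
#' fewer than 5% of the graph get the worst path-length rank. A node is a
#' hub when its ingoing or outgoing profile qualifies.
#'
#' @param ct A `centrality_table`.
#' @param top_fraction Fraction defining "top" ranks (default 1/3; the cut
#'   is `floor(N * top_fraction)` nodes).
#' @param min_measures Minimum qualifying measures per profile (default 3).
#' @return `hub_set`: list with `is_hub`, per-profile flags, `method` and
#'   threshold parameters.
#' @export
hub_score_classify <- function(ct, top_fraction = 1 / 3, min_measures = 3) {
  stopifnot(top_fraction > 0, top_fraction < 1,
            min_measures >= 1, min_measures <= 4)
  n <- nrow(ct)
  n_top <- floor(n * top_fraction)
  if (n_top < 1) warnf("fewer nodes (%d) than 1/top_fraction: no top ranks", n)
  profile_hits <- function(deg, btw, pc, pl, reach) {
    hits <- top_fraction_mask(deg, n_top) +
      top_fraction_mask(btw, n_top) +
      top_fraction_mask(pc, n_top) +
      top_fraction_mask(pl, n_top, ascending = TRUE, worst = reach < 0.05)
    hits >= min_measures
  }
  in_q <- profile_hits(ct$deg_in, ct$betweenness, ct$pc_in, ct$pl_in, ct$reach_in)
  out_q <- profile_hits(ct$deg_out, ct$betweenness, ct$pc_out, ct$pl_out, ct$reach_out)
  structure(list(method = "hub_score", is_hub = in_q | out_q,
                 in_qualifies = in_q, out_qualifies = out_q,
                 top_fraction = top_fraction, min_measures = min_measures,
                 node = ct$node),
            class = "hub_set")
}

#' Hub classification by k-means (k = 2) on centrality profiles
#'
#' The four in-profile measures (degree, betweenness, participation, path
#' length negated so larger = more central) are z-scored and clustered with
#' k-means, k = 2, multiple seeded restarts; the cluster with the higher
#' mean standardized degree is the hub cluster. Repeated for the
#' out-profile; a node is a hub when either profile says so. Zero-variance
#' features are dropped with a warning; unreachable path lengths get the
#' least-central finite value.
#'
#' @param ct A `centrality_table`.
#' @param seed Integer seed for the restarts.
#' @return A `hub_set` (method `"kmeans"`).
#' @export
kmeans_classify <- function(ct, seed = 1L) {
  n <- nrow(ct)
  if (n < 4) stopf("need at least 4 nodes for k-means hub classification")
  cluster_profile <- function(deg, btw, pc, pl, reach) {
    pl_use <- pl
    worst <- !is.finite(pl) | reach < 0.05
    if (any(!worst)) pl_use[worst] <- max(pl[!worst]) else pl_use[worst] <- 0
    feats <- cbind(deg = deg, betweenness = btw, pc = pc, pl = -pl_use)
    sds <- apply(feats, 2, stats::sd)
    if (any(sds == 0)) {
      warnf("dropping zero-variance feature(s): %s",
            paste(colnames(feats)[sds == 0], collapse = ", "))
      feats <- feats[, sds > 0, drop = FALSE]
    }
    if (ncol(feats) == 0) return(rep(FALSE, n))
    z <- scale(feats)
    km <- with_seed(seed, stats::kmeans(z, centers = 2, nstart = 25))
    zdeg <- if ("deg" %in% colnames(z)) z[, "deg"] else rowMeans(z)
    hub_cluster <- which.max(tapply(zdeg, km$cluster, mean))
    km$cluster == as.integer(hub_cluster)
  }
  in_q <- cluster_profile(ct$deg_in, ct$betweenness, ct$pc_in, ct$pl_in, ct$reach_in)
  out_q <- cluster_profile(ct$deg_out, ct$betweenness, ct$pc_out, ct$pl_out, ct$reach_out)
  structure(list(method = "kmeans", is_hub = in_q | out_q,
                 in_qualifies = in_q, out_qualifies = out_q, seed = seed,
                 node = ct$node),
            class = "hub_set")
}

#' Per-module hub density permutation test
#'
#' Module hub density = hubs in module / module size. The null shuffles the
#' same number of hub labels uniformly over all nodes; one-sided enrichment
#' and depletion p-values use the add-one rule and are Bonferroni-corrected
#' over the K modules.
#'
#' @param hubs A `hub_set`.
#' @param partition [icn_partition()].
#' @param n_perm Number of label shuffles (>= 100).
#' @param alpha Family-wise level.
#' @param seed Integer seed.
#' @return Data frame per module: `density`, `p_low`, `p_high`,
#'   `p_low_bonf`, `p_high_bonf`, `significant`.
#' @export
hub_icn_test <- function(hubs, partition, n_perm = 1000, alpha = 0.05,
                         seed = 1L) {
  if (n_perm < 100) stopf("n_perm must be >= 100")
  lab <- partition$labels
  is_hub <- hubs$is_hub
  if (length(is_hub) != length(lab)) stopf("hub set and partition differ in size")
  k <- partition$n_modules
  sizes <- tabulate(lab[!is.na(lab)], nbins = k)
  dens <- function(h) {
    cnt <- vapply(seq_len(k), function(m) sum(h & !is.na(lab) & lab == m), 0)
    cnt / sizes
  }
  obs <- dens(is_hub)
  ge <- le <- numeric(k)
  with_seed(seed, {
    for (i in seq_len(n_perm)) {
      null_d <- dens(sample(is_hub))
      ge <- ge + (null_d >= obs)
      le <- le + (null_d <= obs)
    }
  })
  p_high <- (1 + ge) / (1 + n_perm)
  p_low <- (1 + le) / (1 + n_perm)
  data.frame(module = seq_len(k), size = sizes, n_hubs = round(obs * sizes),
             density = obs, p_high = p_high, p_low = p_low,
             p_high_bonf = pmin(1, p_high * k),
             p_low_bonf = pmin(1, p_low * k),
             significant = 2 * pmin(p_high, p_low) * k < alpha)
}

#' Edge counts by endpoint hub status
#'
#' Classifies every nonzero entry of the difference matrix by whether its
#' endpoints are hubs: hub-hub, hub-periphery (either direction), or
#' periphery-periphery. The three counts always sum to the number of
#' nonzero entries.
#'
#' @param d `difference_matrix`.
#' @param hubs A `hub_set` aligned with `d`'s nodes.
#' @return Named integer vector `hub_hub`, `hub_periphery`,
#'   `periphery_periphery`.
#' @export
edge_class_counts <- function(d, hubs) {
  m <- unclass(as.matrix(d)) != 0
  diag(m) <- FALSE
  h <- hubs$is_hub
  if (length(h) != nrow(m)) stopf("hub set size != matrix size")
  hh <- sum(m[h, h, drop = FALSE])
  pp <- sum(m[!h, !h, drop = FALSE])
  hp <- sum(m) - hh - pp
  c(hub_hub = hh, hub_periphery = hp, periphery_periphery = pp)
}
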