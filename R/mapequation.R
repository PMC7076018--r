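#' Two-level map-equation codelength
#'
#' Expected per-step description length (bits) of a random walk on an
#' undirected weighted graph under a two-level coding scheme: one index
#' codebook over modules plus one codebook per module. Node visit rates are
#' proportional to strength; module exit rates to the weight of edges
#' leaving the module.
#'
#' @param w Symmetric non-negative adjacency matrix.
#' @param membership Integer module label per node (`NA` allowed for
#'   isolated nodes, which carry no flow).
#' @return Codelength in bits (0 for an empty graph).
#' @export
map_equation_codelength <- function(w, membership) {
  w <- unclass(as.matrix(w))
  tw <- sum(w)
  if (tw <= 0) return(0)
  plogp <- function(x) { x <- x[x > 0]; sum(x * log2(x)) }
  p <- rowSums(w) / tw                       # node visit rates
  ok <- !is.na(membership)
  f <- rowsum(w[ok, , drop = FALSE], membership[ok])        # K x n flows
  ff <- rowsum(t(f)[ok, , drop = FALSE], membership[ok])    # K x K
  ff <- as.matrix(ff)
  w_in <- diag(ff)
  q <- (rowSums(ff) - w_in) / tw             # module exit rates
  p_circ <- q + rowsum(p[ok], membership[ok])[, 1]
  plogp(sum(q)) - 2 * plogp(q) + plogp(p_circ) - plogp(p)
}

# Node-moving sweep with incremental codelength deltas. Module aggregates:
# S[m] = sum of node strengths, W[m] = sum of internal weights (both
# endpoints in m, each undirected edge counted twice). Moving node i only
# touches the donor and recipient terms of the codelength, so each
# candidate move costs O(degree).
mapeq_sweep <- function(w, labels, tol = 1e-10) {
  tw <- sum(w)
  strength <- rowSums(w)
  k_max <- length(labels)
  s_mod <- w_mod <- numeric(k_max)
  for (m in unique(labels)) {
    idx <- labels == m
    s_mod[m] <- sum(strength[idx])
    w_mod[m] <- sum(w[idx, idx])
  }
  plogp <- function(x) ifelse(x > 0, x * log2(x), 0)
  # module terms of the codelength, given raw aggregates
  mod_term <- function(s, wi) {
    q <- (s - wi) / tw
    -2 * plogp(q) + plogp(q + s / tw)
  }
  q_of <- function(s, wi) (s - wi) / tw
  sum_q <- sum(q_of(s_mod, w_mod)[s_mod > 0])
  improved_any <- FALSE
  repeat {
    improved <- FALSE
    for (i in sample.int(length(labels))) {
      a <- labels[i]
      self_w <- w[i, i]   # self-weight moves with the node, counted once
      nbr <- which(w[i, ] > 0)
      nbr <- nbr[nbr != i]
      if (length(nbr) == 0) next
      k_i <- tapply(w[i, nbr], labels[nbr], sum)
      cand <- as.integer(names(k_i))
      k_ia <- if (as.character(a) %in% names(k_i)) k_i[[as.character(a)]] else 0
      cand <- cand[cand != a]
      if (length(cand) == 0) next
      s_i <- strength[i]
      # donor aggregates after removal
      s_a2 <- s_mod[a] - s_i
      w_a2 <- w_mod[a] - 2 * k_ia - self_w
      base_old <- mod_term(s_mod[a], w_mod[a])
      q_a_old <- q_of(s_mod[a], w_mod[a]); q_a_new <- q_of(s_a2, w_a2)
      best_delta <- -tol; best_b <- NA_integer_
      for (b in cand) {
        k_ib <- k_i[[as.character(b)]]
        s_b2 <- s_mod[b] + s_i
        w_b2 <- w_mod[b] + 2 * k_ib + self_w
        q_b_old <- q_of(s_mod[b], w_mod[b]); q_b_new <- q_of(s_b2, w_b2)
        sum_q_new <- sum_q - q_a_old - q_b_old + q_a_new + q_b_new
        delta <- (plogp(sum_q_new) - plogp(sum_q)) +
          (mod_term(s_a2, w_a2) - base_old) +
          (mod_term(s_b2, w_b2) - mod_term(s_mod[b], w_mod[b]))
        if (delta < best_delta) { best_delta <- delta; best_b <- b }
      }
      if (!is.na(best_b)) {
        b <- best_b
        k_ib <- k_i[[as.character(b)]]
        w_b2 <- w_mod[b] + 2 * k_ib + self_w
        sum_q <- sum_q - q_a_old - q_of(s_mod[b], w_mod[b]) +
          q_a_new + q_of(s_mod[b] + s_i, w_b2)
        s_mod[a] <- s_a2; w_mod[a] <- w_a2
        s_mod[b] <- s_mod[b] + s_i; w_mod[b] <- w_b2
        labels[i] <- b
        improved <- TRUE; improved_any <- TRUE
      }
    }
    if (!improved) break
  }
  list(labels = labels, improved = improved_any)
}

# One greedy map-equation run: Louvain-style node-moving passes in random
# order, then aggregation of modules into supernodes, repeated until no
# move improves the codelength. Returns an integer membership per node.
mapeq_run <- function(w, tol = 1e-10) {
  n <- nrow(w)
  node_map <- seq_len(n)   # original node -> current supernode
  agg <- w
  repeat {
    m <- nrow(agg)
    sw <- mapeq_sweep(agg, seq_len(m), tol)
    labels <- match(sw$labels, sort(unique(sw$labels)))
    k <- max(labels)
    if (!sw$improved || k == m) {
      node_map <- labels[node_map]
      break
    }
    pool <- rowsum(t(rowsum(agg, labels)), labels)
    node_map <- labels[node_map]
    agg <- as.matrix(pool)
  }
  match(node_map, sort(unique(node_map)))
}

#' Map-equation community detection (repeated stochastic runs)
#'
#' Runs the greedy two-level map-equation optimizer `n_runs` times with
#' independent random node orders derived from `seed`. Isolated nodes
#' (zero strength) are unassigned (`NA`) in every run; an empty graph yields
#' a single all-unassigned partition.
#'
#' @param w Symmetric non-negative weighted adjacency matrix.
#' @param n_runs Number of independent optimization runs.
#' @param seed Integer seed; run `r` uses a derived child seed.
#' @return List of integer membership vectors (one per run, `NA` =
#'   unassigned).
#' @export
detect_communities <- function(w, n_runs = 100, seed = 1L) {
  w <- unclass(as.matrix(w))
  if (any(w < 0)) stopf("negative edge weights; threshold/clean upstream")
  n <- nrow(w)
  isolated <- rowSums(w) == 0
  if (all(isolated)) return(list(rep(NA_integer_, n)))
  lapply(seq_len(n_runs), function(r) {
    lab <- with_seed(child_seed(seed, r), mapeq_run(w))
    lab[isolated] <- NA_integer_
    match(lab, sort(unique(lab[!is.na(lab)])))
  })
}
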