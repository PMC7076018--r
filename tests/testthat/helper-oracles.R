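# Independent brute-force oracles used by several test files. These are
# deliberately naive (loops, explicit enumeration) and share no code with
# the package implementation.

# random ternary directed matrix with controlled density
random_difference <- function(n, p_edge = 0.15, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(0L, n, n)
    off <- which(row(m) != col(m))
    pick <- off[stats::runif(length(off)) < p_edge]
    m[pick] <- sample(c(-1L, 1L), length(pick), replace = TRUE)
    m
  })
}

random_partition <- function(n, k, seed = 1) {
  withr::with_seed(seed, {
    lab <- c(seq_len(k), sample.int(k, n - k, replace = TRUE))
    icn_partition(sample(lab))
  })
}

# densities by explicit edge loop
oracle_density <- function(m, labels, sgn) {
  k <- max(labels, na.rm = TRUE)
  out <- matrix(0, k, k)
  sizes <- sapply(seq_len(k), function(a) sum(labels == a, na.rm = TRUE))
  for (a in seq_len(k)) for (b in seq_len(k)) {
    cnt <- 0
    for (i in which(labels == a)) for (j in which(labels == b)) {
      if (i != j && !is.na(m[i, j]) && m[i, j] == sgn) cnt <- cnt + 1
    }
    denom <- if (a == b) sizes[a] * (sizes[a] - 1) else sizes[a] * sizes[b]
    out[a, b] <- if (denom > 0) cnt / denom else NaN
  }
  out
}

# all-pairs BFS shortest paths with path counts (unweighted directed)
oracle_shortest <- function(adj) {
  n <- nrow(adj)
  dist <- matrix(Inf, n, n)
  npaths <- matrix(0, n, n)
  for (s in seq_len(n)) {
    dist[s, s] <- 0; npaths[s, s] <- 1
    frontier <- s; d <- 0
    while (length(frontier) > 0) {
      nxt <- integer(0)
      for (u in frontier) for (v in which(adj[u, ] > 0)) {
        if (is.infinite(dist[s, v])) {
          dist[s, v] <- d + 1
          nxt <- c(nxt, v)
        }
        if (dist[s, v] == d + 1) npaths[s, v] <- npaths[s, v] + npaths[s, u]
      }
      frontier <- unique(nxt); d <- d + 1
    }
  }
  list(dist = dist, npaths = npaths)
}

# betweenness with fractional credit via explicit path enumeration
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  sp <- oracle_shortest(adj)
  btw <- numeric(n)
  enum_paths <- function(s, t) {
    if (s == t || is.infinite(sp$dist[s, t])) return(list())
    paths <- list()
    grow <- function(path) {
      u <- path[length(path)]
      if (u == t) { paths[[length(paths) + 1]] <<- path; return(invisible()) }
      for (v in which(adj[u, ] > 0)) {
        if (sp$dist[s, v] == sp$dist[s, u] + 1 &&
            sp$dist[s, v] + sp$dist[v, t] == sp$dist[s, t]) grow(c(path, v))
      }
    }
    grow(s)
    paths
  }
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t || is.infinite(sp$dist[s, t])) next
    paths <- enum_paths(s, t)
    for (p in paths) {
      inner <- setdiff(p, c(s, t))
      for (v in inner) btw[v] <- btw[v] + 1 / length(paths)
    }
  }
  btw
}

# full centrality profile by first principles
oracle_centralities <- function(adj, labels) {
  n <- nrow(adj)
  sp <- oracle_shortest(adj)
  k <- max(labels, na.rm = TRUE)
  pc_dir <- function(i, incoming) {
    links <- if (incoming) adj[, i] else adj[i, ]
    ktot <- sum(links)
    if (ktot == 0) return(0)
    s <- 0
    for (m in seq_len(k)) s <- s + (sum(links[which(labels == m)]) / ktot)^2
    1 - s
  }
  pl_dir <- function(i, incoming) {
    d <- if (incoming) sp$dist[, i] else sp$dist[i, ]
    d <- d[-i]; d <- d[is.finite(d)]
    if (length(d) == 0) NaN else mean(d)
  }
  data.frame(deg_in = colSums(adj), deg_out = rowSums(adj),
             betweenness = oracle_betweenness(adj),
             pc_in = sapply(seq_len(n), pc_dir, incoming = TRUE),
             pc_out = sapply(seq_len(n), pc_dir, incoming = FALSE),
             pl_in = sapply(seq_len(n), pl_dir, incoming = TRUE),
             pl_out = sapply(seq_len(n), pl_dir, incoming = FALSE))
}

# hub-score criterion re-implemented from its definition
oracle_hub_score <- function(ct, top_fraction = 1 / 3, min_measures = 3) {
  n <- nrow(ct)
  n_top <- floor(n * top_fraction)
  in_top_desc <- function(v) {
    v[is.na(v)] <- -Inf
    rank_pos <- order(-v, seq_along(v))
    res <- logical(n); res[rank_pos[seq_len(n_top)]] <- TRUE; res
  }
  in_top_asc <- function(v, reach) {
    v[is.na(v) | reach < 0.05] <- Inf
    rank_pos <- order(v, seq_along(v))
    res <- logical(n); res[rank_pos[seq_len(n_top)]] <- TRUE; res
  }
  inq <- (in_top_desc(ct$deg_in) + in_top_desc(ct$betweenness) +
            in_top_desc(ct$pc_in) + in_top_asc(ct$pl_in, ct$reach_in)) >= min_measures
  outq <- (in_top_desc(ct$deg_out) + in_top_desc(ct$betweenness) +
             in_top_desc(ct$pc_out) + in_top_asc(ct$pl_out, ct$reach_out)) >= min_measures
  inq | outq
}

oracle_edge_classes <- function(m, is_hub) {
  hh <- hp <- pp <- 0
  n <- nrow(m)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || m[i, j] == 0) next
    nh <- is_hub[i] + is_hub[j]
    if (nh == 2) hh <- hh + 1 else if (nh == 1) hp <- hp + 1 else pp <- pp + 1
  }
  c(hub_hub = hh, hub_periphery = hp, periphery_periphery = pp)
}

oracle_jaccard <- function(a, b) {
  u <- unique(c(a, b))
  if (length(u) == 0) 0 else length(intersect(a, b)) / length(u)
}

oracle_odds_ratio <- function(tab) (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
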