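# Brute-force oracles, deliberately independent of the package's
# igraph-backed implementations: graphs are plain symmetric logical
# adjacency matrices, distances come from a hand-rolled BFS, and shortest
# paths are enumerated explicitly.

adj_matrix <- function(n, edges) {
  # edges: 2-column integer matrix
  adj <- matrix(FALSE, n, n)
  ids <- sprintf("n%02d", seq_len(n))
  dimnames(adj) <- list(ids, ids)
  if (length(edges)) {
    for (r in seq_len(nrow(edges))) {
      adj[edges[r, 1], edges[r, 2]] <- TRUE
      adj[edges[r, 2], edges[r, 1]] <- TRUE
    }
  }
  adj
}

rand_adj <- function(n, p) {
  pairs <- t(utils::combn(n, 2))
  adj_matrix(n, pairs[stats::runif(nrow(pairs)) < p, , drop = FALSE])
}

net_from_adj <- function(adj) {
  ids <- rownames(adj)
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  edges <- data.frame(from = ids[idx[, 1]], to = ids[idx[, 2]],
                      kind = rep("ppi", nrow(idx)))
  pharm_network(data.frame(id = ids, role = "target"), edges)
}

oracle_all_dists <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n, dimnames = dimnames(adj))
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) {
        nb <- which(adj[v, ])
        new <- nb[!is.finite(dist[nb])]
        dist[new] <- dist[v] + 1
        nxt <- c(nxt, new)
      }
      frontier <- unique(nxt)
    }
    D[s, ] <- dist
  }
  D
}

# All shortest s-t paths by DFS guided by the BFS distance matrix.
oracle_shortest_paths <- function(adj, D, s, t) {
  paths <- list()
  rec <- function(path) {
    cur <- path[length(path)]
    if (cur == t) {
      paths[[length(paths) + 1]] <<- path
      return(invisible(NULL))
    }
    for (v in which(adj[cur, ]))
      if (is.finite(D[v, t]) && D[v, t] == D[cur, t] - 1) rec(c(path, v))
  }
  rec(s)
  paths
}

oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  D <- oracle_all_dists(adj)
  bc <- stats::setNames(numeric(n), rownames(adj))
  if (n < 3) return(bc)
  for (s in seq_len(n - 1)) for (t in seq(s + 1, n)) {
    if (!is.finite(D[s, t])) next
    paths <- oracle_shortest_paths(adj, D, s, t)
    sigma <- length(paths)
    interior <- unlist(lapply(paths, function(p) p[-c(1, length(p))]))
    if (length(interior)) {
      tab <- table(interior)
      idx <- as.integer(names(tab))
      bc[idx] <- bc[idx] + as.numeric(tab) / sigma
    }
  }
  bc
}

oracle_closeness <- function(adj) {
  n <- nrow(adj)
  D <- oracle_all_dists(adj)
  vapply(seq_len(n), function(v) {
    d <- D[v, -v]
    d <- d[is.finite(d)]
    r <- length(d) + 1
    if (r == 1 || n == 1) return(0)
    ((r - 1) / sum(d)) * ((r - 1) / (n - 1))
  }, numeric(1)) |> stats::setNames(rownames(adj))
}

# Tree oracle: betweenness of v in a tree = number of node pairs whose
# unique path crosses v = sum over component-size products after removing v.
oracle_tree_betweenness <- function(adj) {
  n <- nrow(adj)
  vapply(seq_len(n), function(v) {
    sub <- adj[-v, -v, drop = FALSE]
    D <- oracle_all_dists(sub)
    seen <- rep(FALSE, n - 1)
    sizes <- integer(0)
    for (s in seq_len(n - 1)) {
      if (seen[s]) next
      comp <- which(is.finite(D[s, ]))
      seen[comp] <- TRUE
      sizes <- c(sizes, length(comp))
    }
    sum(utils::combn(c(sizes, 0), 2, function(x) x[1] * x[2]))
  }, numeric(1)) |> stats::setNames(rownames(adj))
}

# Exhaustive hypergeometric upper tail: pathway = first K universe elements,
# enumerate every size-n draw and count overlaps >= k.
oracle_hyper_tail <- function(N, K, n, k) {
  if (n == 0) return(as.numeric(k <= 0))
  draws <- utils::combn(N, n)
  overlap <- colSums(draws <= K)
  mean(overlap >= k)
}

# Every labeled connected graph on n nodes (bitmask over the n(n-1)/2 pairs).
all_connected_adj <- function(n) {
  pairs <- t(utils::combn(n, 2))
  m <- nrow(pairs)
  out <- list()
  for (mask in 0:(2^m - 1)) {
    sel <- bitwAnd(mask, 2^(seq_len(m) - 1)) > 0
    adj <- adj_matrix(n, pairs[sel, , drop = FALSE])
    if (all(is.finite(oracle_all_dists(adj)))) out[[length(out) + 1]] <- adj
  }
  out
}

expect_centrality_matches_oracle <- function(adj) {
  net <- net_from_adj(adj)
  expect_equal(as.numeric(betweenness_centrality(net)[rownames(adj)]),
               as.numeric(oracle_betweenness(adj)), tolerance = 1e-10)
  expect_equal(as.numeric(closeness_centrality(net)[rownames(adj)]),
               as.numeric(oracle_closeness(adj)), tolerance = 1e-10)
}
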