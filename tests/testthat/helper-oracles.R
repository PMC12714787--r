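# Independent brute-force oracles, deliberately written with the simplest
# possible loops so they share no code path with the package implementation.

# Gini by the O(n^2) pairwise-difference definition.
brute_gini <- function(x) {
  n <- length(x)
  if (mean(x) == 0) return(0)
  total <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) total <- total + abs(x[i] - x[j])
  total / (2 * n^2 * mean(x))
}

# Edge set by an explicit double loop over all pairs.
brute_edges <- function(placements, space, distance_mode = "euclidean_real") {
  n <- nrow(placements)
  out <- NULL
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- torus_distance(placements$x[i], placements$y[i],
                          placements$x[j], placements$y[j], space,
                          distance_mode = distance_mode)
      if (min(placements$sr[i], placements$sr[j]) >= d) {
        out <- rbind(out, c(placements$agent_id[i], placements$agent_id[j]))
      }
    }
  }
  if (is.null(out)) matrix(integer(0), ncol = 2) else out
}

# Canonical sorted representation of an edge matrix for set comparison.
edge_key <- function(edges) {
  if (nrow(edges) == 0L) return(character(0))
  lo <- pmin(edges[, 1], edges[, 2]); hi <- pmax(edges[, 1], edges[, 2])
  sort(paste(lo, hi, sep = "-"))
}

# Hand-rolled BFS distances from every node over an adjacency list
# (1-based vertex indices); returns the full distance matrix.
bfs_all_distances <- function(adj) {
  n <- length(adj)
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    frontier <- s
    depth <- 0
    while (length(frontier) > 0) {
      depth <- depth + 1
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[d[s, nxt] == Inf]
      d[s, nxt] <- depth
      frontier <- nxt
    }
  }
  d
}

# Normalized shortest-path betweenness by direct dependency accumulation over
# BFS shortest-path counts (dense dynamic programming over distances).
brute_betweenness <- function(adj) {
  n <- length(adj)
  d <- bfs_all_distances(adj)
  # sigma[s, t]: number of shortest s-t paths
  sigma <- matrix(0, n, n)
  diag(sigma) <- 1
  for (s in seq_len(n)) {
    for (dep in sort(unique(d[s, d[s, ] > 0 & is.finite(d[s, ])]))) {
      for (t in which(d[s, ] == dep)) {
        preds <- adj[[t]][d[s, adj[[t]]] == dep - 1]
        sigma[s, t] <- sum(sigma[s, preds])
      }
    }
  }
  bc <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n - 1)) {
      for (t in (s + 1):n) {
        if (s == v || t == v || !is.finite(d[s, t])) next
        if (d[s, v] + d[v, t] == d[s, t]) {
          bc[v] <- bc[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
        }
      }
    }
  }
  bc / ((n - 1) * (n - 2) / 2)
}

# Build an sc_network purely from topology (ids 0-based); coordinates unknown.
net_from_edges <- function(n, edges) {
  placements <- data.frame(agent_id = 0:(n - 1L), x = NA_integer_,
                           y = NA_integer_, sr = NA_real_)
  sc_network(placements, edges)
}

# igraph adjacency list (1-based) from an sc_network for the BFS oracles.
adj_list <- function(net) {
  g <- as_igraph(net)
  lapply(igraph::adjacent_vertices(g, igraph::V(g)), as.integer)
}

# Small named graphs used across test files (0-based ids).
star_net <- function(leaves = 3L) {
  net_from_edges(leaves + 1L, cbind(0L, seq_len(leaves)))
}
path_net <- function(n) net_from_edges(n, cbind(0:(n - 2L), 1:(n - 1L)))
ring_net <- function(n) net_from_edges(n, rbind(cbind(0:(n - 2L), 1:(n - 1L)), c(0L, n - 1L)))
complete_net <- function(n) {
  e <- t(utils::combn(0:(n - 1L), 2))
  net_from_edges(n, e)
}

# Random connected-ish graph for oracle comparisons: G(n, p) plus a spanning
# path so BFS oracles see a single component.
random_test_net <- function(n, p, seed) {
  set.seed(seed)
  pairs <- t(utils::combn(0:(n - 1L), 2))
  keep <- stats::runif(nrow(pairs)) < p
  e <- rbind(pairs[keep, , drop = FALSE], cbind(0:(n - 2L), 1:(n - 1L)))
  net_from_edges(n, e)
}
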