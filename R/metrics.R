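#' @importFrom stats cor sd
NULL

# Accept either an sc_network or an igraph graph; metrics operate on igraph.
metric_graph <- function(network) {
  if (inherits(network, "sc_network")) return(as_igraph(network))
  if (inherits(network, "igraph")) return(network)
  stop("expected an sc_network or igraph object", call. = FALSE)
}

require_connected <- function(g, what) {
  if (igraph::vcount(g) > 0L && !igraph::is_connected(g)) {
    stop(sprintf("%s requires a connected network; extract the giant component first (see giant_component())",
                 what), call. = FALSE)
  }
}

#' Extract the giant component
#'
#' Returns the induced subnetwork on the largest connected component,
#' preserving original agent ids, coordinates and reaches. When two or more
#' components tie for the largest size, the one containing the smallest agent
#' id wins. All structural properties reported by [network_properties()] are
#' measured on this subnetwork.
#'
#' @param network An `sc_network`.
#' @return An `sc_network` restricted to the giant component.
#' @export
giant_component <- function(network) {
  stopifnot(inherits(network, "sc_network"))
  if (nrow(network$placements) == 0L) {
    stop("giant_component: network has no agents", call. = FALSE)
  }
  g <- as_igraph(network)
  comp <- igraph::components(g)
  best <- which(comp$csize == max(comp$csize))
  if (length(best) > 1L) {
    # tie-break: the component holding the smallest agent id
    min_id <- vapply(best, function(k) {
      min(as.integer(igraph::V(g)$name[comp$membership == k]))
    }, numeric(1))
    best <- best[which.min(min_id)]
  }
  keep_ids <- as.integer(igraph::V(g)$name[comp$membership == best])
  keep <- network$placements$agent_id %in% keep_ids
  edges <- network$edges
  edges <- edges[edges[, 1] %in% keep_ids & edges[, 2] %in% keep_ids, , drop = FALSE]
  sc_network(network$placements[keep, , drop = FALSE], edges,
             network$space, network$distance_mode)
}

#' Gini coefficient
#'
#' Normalized mean absolute pairwise difference,
#' `G = sum_ij |x_i - x_j| / (2 n^2 mean(x))`, computed via the equivalent
#' sorted-vector form in O(n log n). Zero means perfect equality; values
#' approach (n-1)/n < 1 as a distribution concentrates on one observation.
#' Used here as the dispersion measure for every centrality distribution,
#' being scale-invariant and robust to the heavy right tails these
#' distributions show. An all-zero vector returns 0 by convention.
#'
#' @param values Nonnegative numeric vector.
#' @return A number in `[0, 1)`.
#' @examples
#' gini(c(5, 5, 5, 5))  # 0
#' gini(c(0, 1))        # 0.5
#' @export
gini <- function(values) {
  if (length(values) == 0L) stop("gini: empty input", call. = FALSE)
  if (any(is.na(values))) stop("gini: NA input", call. = FALSE)
  if (any(values < 0)) stop("gini: negative values are not supported", call. = FALSE)
  n <- length(values)
  m <- mean(values)
  if (m == 0) return(0)
  x <- sort(values)
  sum((2 * seq_len(n) - n - 1) * x) / (n^2 * m)
}

#' Degree mean and dispersion
#'
#' Mean and Gini coefficient of the degree sequence. Intended for
#' giant-component input (so `degree_mean = 2 * edges / n`), though it is
#' defined for any network.
#'
#' @param network An `sc_network` or igraph graph.
#' @return Named numeric vector `c(degree_mean, degree_gini)`.
#' @export
degree_stats <- function(network) {
  g <- metric_graph(network)
  deg <- igraph::degree(g)
  c(degree_mean = mean(deg), degree_gini = gini(deg))
}

#' Edge-end degree assortativity (Newman)
#'
#' Pearson correlation between the degrees of the nodes at the two ends of
#' each edge, computed over the `2E` ordered edge-end pairs so that each edge
#' contributes both orientations and the correlation is symmetric. Positive
#' values mean high-degree nodes preferentially attach to other high-degree
#' nodes. When every edge end has the same degree (e.g. a cycle) the
#' correlation is undefined and `NA` is returned, never a silent 0.
#'
#' @param network An `sc_network` or igraph graph with at least 2 edges.
#' @return A number in `[-1, 1]`, or `NA_real_` when undefined.
#' @export
assortativity_edge <- function(network) {
  g <- metric_graph(network)
  if (igraph::gsize(g) < 2L) {
    stop("assortativity_edge: need at least 2 edges", call. = FALSE)
  }
  deg <- igraph::degree(g)
  e <- igraph::as_edgelist(g, names = FALSE)
  a <- deg[e[, 1]]; b <- deg[e[, 2]]
  x <- c(a, b); y <- c(b, a)
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)
}

#' Degree vs mean-neighbour-degree assortativity
#'
#' The node-level assortativity variant: Pearson correlation, over nodes,
#' between a node's degree and the mean degree of its neighbours. Requires
#' every node to have at least one neighbour (use the giant component) and at
#' least two distinct degree values; otherwise `NA` is returned.
#'
#' @param network An `sc_network` or igraph graph.
#' @return A number in `[-1, 1]`, or `NA_real_` when undefined.
#' @export
assortativity_neighbour_mean <- function(network) {
  g <- metric_graph(network)
  deg <- igraph::degree(g)
  if (any(deg == 0)) {
    stop("assortativity_neighbour_mean: every node needs degree >= 1; extract the giant component first",
         call. = FALSE)
  }
  nb_mean <- vapply(igraph::adjacent_vertices(g, igraph::V(g)),
                    function(vs) mean(deg[as.integer(vs)]), numeric(1))
  if (sd(deg) == 0 || sd(nb_mean) == 0) return(NA_real_)
  cor(deg, nb_mean)
}

#' Closeness centrality values
#'
#' For each node v of a connected network, `(n - 1) / sum_u d(v, u)` — the
#' reciprocal of v's mean geodesic to all other nodes, so a node with short
#' average distances scores near 1.
#'
#' @param network A connected `sc_network` or igraph graph.
#' @return Numeric vector of per-node closeness values, in vertex order.
#' @export
closeness_values <- function(network) {
  g <- metric_graph(network)
  require_connected(g, "closeness_values")
  if (igraph::vcount(g) == 1L) return(0)
  unname(igraph::closeness(g, normalized = TRUE))
}

#' Betweenness centrality values
#'
#' Shortest-path betweenness with even split over equally short paths
#' (Brandes' algorithm), normalized by `(n-1)(n-2)/2` so values lie in
#' `[0, 1]`. Networks with fewer than 3 nodes have no intermediaries and
#' return all zeros.
#'
#' @param network A connected `sc_network` or igraph graph.
#' @return Numeric vector of per-node normalized betweenness values.
#' @export
betweenness_values <- function(network) {
  g <- metric_graph(network)
  require_connected(g, "betweenness_values")
  if (igraph::vcount(g) < 3L) return(rep(0, igraph::vcount(g)))
  unname(igraph::betweenness(g, normalized = TRUE))
}

#' Eigenvector centrality values
#'
#' Entries of the principal eigenvector of the adjacency matrix, nonnegative
#' and scaled to unit Euclidean norm. A node is central when its neighbours
#' are central. The Gini coefficient of these values is scale-invariant, so
#' dispersion summaries do not depend on the normalization convention.
#'
#' @param network A connected `sc_network` or igraph graph.
#' @return Numeric per-node vector with `sum(x^2) = 1`.
#' @export
eigenvector_values <- function(network) {
  g <- metric_graph(network)
  require_connected(g, "eigenvector_values")
  v <- igraph::eigen_centrality(g)$vector
  v <- abs(v)             # principal eigenvector of a connected graph is sign-definite
  unname(v / sqrt(sum(v^2)))
}

#' Local clustering coefficient values
#'
#' Per-node fraction of neighbour pairs that are themselves connected:
#' triangles through v divided by `deg(v) * (deg(v) - 1) / 2`. Nodes with
#' fewer than 2 neighbours have no neighbour pairs; by default they
#' contribute 0 (and are included in the mean), matching the convention that
#' an unclustered periphery lowers average cohesion. Set
#' `low_degree_as_zero = FALSE` to drop them (`NA`) instead.
#'
#' @param network An `sc_network` or igraph graph.
#' @param low_degree_as_zero Treat degree-<2 nodes as 0 (default) or `NA`.
#' @return Numeric per-node vector in `[0, 1]` (possibly with `NA`s).
#' @export
clustering_values <- function(network, low_degree_as_zero = TRUE) {
  g <- metric_graph(network)
  v <- igraph::transitivity(g, type = "localundirected", isolates = "NaN")
  if (low_degree_as_zero) v[is.nan(v)] <- 0 else v[is.nan(v)] <- NA_real_
  unname(v)
}

#' Global transitivity
#'
#' Three times the triangle count divided by the number of connected triples
#' (paths of length two). Returns `NA` when the network has no connected
#' triple.
#'
#' @param network An `sc_network` or igraph graph.
#' @return A number in `[0, 1]`, or `NA_real_` with no triples.
#' @export
global_transitivity <- function(network) {
  g <- metric_graph(network)
  v <- igraph::transitivity(g, type = "global")
  if (is.nan(v)) NA_real_ else v
}

#' Geodesic statistics
#'
#' Mean, Gini coefficient and maximum (the diameter) of the shortest-path
#' lengths over all n(n-1)/2 unordered node pairs of a connected network.
#'
#' @param network A connected `sc_network` or igraph graph with >= 2 nodes.
#' @return Named numeric vector `c(geodesic_mean, geodesic_gini, diameter)`.
#' @export
geodesic_stats <- function(network) {
  g <- metric_graph(network)
  require_connected(g, "geodesic_stats")
  if (igraph::vcount(g) < 2L) stop("geodesic_stats: need at least 2 nodes", call. = FALSE)
  d <- igraph::distances(g)
  pairs <- d[upper.tri(d)]
  c(geodesic_mean = mean(pairs), geodesic_gini = gini(pairs),
    diameter = max(pairs))
}

#' Full structural property summary
#'
#' Extracts the giant component and computes every structural property in the
#' measurement battery on it: size, edges, density, degree mean and Gini, both
#' assortativity definitions, closeness / betweenness / eigenvector /
#' clustering means and Ginis, global transitivity, geodesic mean, Gini and
#' diameter. `edges` counts giant-component edges; `edges_total` additionally
#' records the whole-network edge count (the two coincide whenever the network
#' is connected).
#'
#' @param network An `sc_network`.
#' @param low_degree_as_zero Passed to [clustering_values()].
#' @return A one-row `data.frame` of class `property_summary`.
#' @examples
#' cfg <- generator_config(200, torus_space(140, 140),
#'                         reach_discrete(c(15, 30), c(0.75, 0.25)), seed = 7)
#' network_properties(generate_network(cfg))
#' @export
network_properties <- function(network, low_degree_as_zero = TRUE) {
  stopifnot(inherits(network, "sc_network"))
  edges_total <- nrow(network$edges)
  gc <- giant_component(network)
  g <- as_igraph(gc)
  n <- igraph::vcount(g)
  m <- igraph::gsize(g)
  deg <- degree_stats(g)
  geo <- if (n >= 2L) geodesic_stats(g) else
    c(geodesic_mean = NA_real_, geodesic_gini = NA_real_, diameter = NA_real_)
  cl <- clustering_values(g, low_degree_as_zero)
  clo <- if (n >= 2L) closeness_values(g) else NA_real_
  bet <- betweenness_values(g)
  eig <- if (n >= 2L) eigenvector_values(g) else NA_real_
  out <- data.frame(
    n_giant = n,
    edges = m,
    density = if (n >= 2L) 2 * m / (n * (n - 1)) else NA_real_,
    degree_mean = deg[["degree_mean"]],
    degree_gini = deg[["degree_gini"]],
    assortativity_edge = if (m >= 2L) assortativity_edge(g) else NA_real_,
    assortativity_neighbour_mean =
      if (n >= 2L && m >= 1L) assortativity_neighbour_mean(g) else NA_real_,
    closeness_mean = mean(clo),
    closeness_gini = if (all(is.na(clo))) NA_real_ else gini(clo),
    betweenness_mean = mean(bet),
    betweenness_gini = gini(bet),
    eigenvector_mean = mean(eig),
    eigenvector_gini = if (all(is.na(eig))) NA_real_ else gini(eig),
    clustering_mean = mean(cl, na.rm = !low_degree_as_zero),
    clustering_gini = gini(cl[!is.na(cl)]),
    transitivity = global_transitivity(g),
    geodesic_mean = geo[["geodesic_mean"]],
    geodesic_gini = geo[["geodesic_gini"]],
    diameter = geo[["diameter"]],
    edges_total = edges_total
  )
  class(out) <- c("property_summary", "data.frame")
  out
}

#' Column order of a property summary
#'
#' The stable, documented column order used by [network_properties()] and the
#' delimited-text writers.
#'
#' @return Character vector of column names.
#' @export
property_columns <- function() {
  c("n_giant", "edges", "density", "degree_mean", "degree_gini",
    "assortativity_edge", "assortativity_neighbour_mean",
    "closeness_mean", "closeness_gini", "betweenness_mean", "betweenness_gini",
    "eigenvector_mean", "eigenvector_gini", "clustering_mean", "clustering_gini",
    "transitivity", "geodesic_mean", "geodesic_gini", "diameter", "edges_total")
}
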