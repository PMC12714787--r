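#' Generator configuration
#'
#' Bundles everything needed to generate one Social Circles network: the agent
#' count, the toroidal space, the social-reach distribution, the RNG seed and
#' the distance arithmetic. The canonical setup places 1,000 agents on a
#' 315 x 315 torus (about 1% occupancy of the 99,225 positions).
#'
#' @param n Positive integer agent count; must not exceed the cell count of
#'   `space` (agents occupy distinct cells).
#' @param space A [torus_space()]; default 315 x 315.
#' @param reach_spec A [reach_spec] describing the social-reach distribution.
#' @param seed Integer RNG seed; the generated network is fully reproducible
#'   from the configuration.
#' @param distance_mode `"euclidean_real"` (exact real distances, the default)
#'   or `"euclidean_truncated"` (distances floored to integers before the edge
#'   test, provided for replicating integer-distance implementations).
#' @return An object of class `generator_config`.
#' @examples
#' cfg <- generator_config(1000, torus_space(315, 315),
#'                         reach_discrete(c(15, 30), c(0.75, 0.25)), seed = 1)
#' @export
generator_config <- function(n, space = torus_space(315L, 315L), reach_spec,
                             seed = 1L,
                             distance_mode = c("euclidean_real", "euclidean_truncated")) {
  distance_mode <- match.arg(distance_mode)
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("generator_config: n must be a positive integer", call. = FALSE)
  if (!inherits(space, "torus_space")) stop("generator_config: space must be a torus_space", call. = FALSE)
  if (!inherits(reach_spec, "reach_spec")) stop("generator_config: reach_spec must be a reach_spec", call. = FALSE)
  cells <- space$width * space$height
  if (n > cells) {
    stop(sprintf("generator_config: n = %d exceeds the %d grid cells of the %dx%d space",
                 n, cells, space$width, space$height), call. = FALSE)
  }
  structure(list(n = n, space = space, reach_spec = reach_spec,
                 seed = as.integer(seed), distance_mode = distance_mode),
            class = "generator_config")
}

#' Place agents uniformly on the torus
#'
#' Samples `n` distinct grid cells uniformly at random without replacement
#' (two agents never share a cell) and assigns agent ids `0..n-1`. Social
#' reaches are left unset (0) until [assign_reaches()] runs. Uses the current
#' R random stream; call `set.seed()` first for reproducibility (or use
#' [generate_network()], which seeds from its configuration).
#'
#' @param n Positive integer agent count.
#' @param space A [torus_space()].
#' @return A `data.frame` with columns `agent_id` (0-based integer), `x`, `y`
#'   (integer grid coordinates) and `sr` (0 until reaches are assigned).
#' @export
place_agents <- function(n, space) {
  n <- as.integer(n)
  cells <- space$width * space$height
  if (n > cells) {
    stop(sprintf("place_agents: cannot place %d agents on %d distinct cells (%dx%d torus)",
                 n, cells, space$width, space$height), call. = FALSE)
  }
  cell <- sample.int(cells, n) - 1L   # without replacement: distinct positions
  data.frame(agent_id = 0:(n - 1L),
             x = cell %% space$width,
             y = cell %/% space$width,
             sr = 0)
}

#' Assign social reaches to placed agents
#'
#' For a discrete mixture, allocates exact per-value counts by
#' largest-remainder rounding (see [mixture_counts()]) and hands the values to
#' agents in uniformly random order, so the population composition is exact in
#' every replicate and only the assignment is random. Poisson and uniform
#' variants draw i.i.d. reaches per agent.
#'
#' @param placements Output of [place_agents()].
#' @param reach_spec A [reach_spec].
#' @return The placements with the `sr` column filled in.
#' @export
assign_reaches <- function(placements, reach_spec) {
  if (nrow(placements) == 0L) stop("assign_reaches: placements are empty", call. = FALSE)
  if (!inherits(reach_spec, "reach_spec")) {
    stop("assign_reaches: reach_spec must be a reach_spec", call. = FALSE)
  }
  n <- nrow(placements)
  placements$sr <- switch(reach_spec$variant,
    discrete_mixture = {
      counts <- mixture_counts(reach_spec$proportions, n)
      rep(reach_spec$values, counts)[sample.int(n)]
    },
    poisson = stats::rpois(n, reach_spec$mean),
    uniform = stats::runif(n, reach_spec$low, reach_spec$high))
  placements
}

#' Form edges by the reciprocal shorter-reach rule
#'
#' An unordered pair of agents \{i, j\} is an edge exactly when
#' `min(sr_i, sr_j) >= d(i, j)`, i.e. each agent lies within the other's
#' social reach (the shorter reach binds). The test is exhaustive over all
#' n(n-1)/2 pairs, evaluated as vectorized wrapped-distance matrices; the
#' comparison is non-strict, so a pair at distance exactly equal to the
#' shorter reach is connected.
#'
#' @param placements Placements with `sr` assigned.
#' @param space A [torus_space()].
#' @param distance_mode See [generator_config()].
#' @return A two-column integer matrix of agent-id pairs (columns `from`,
#'   `to`, `from < to`), one row per edge; zero rows when no pair qualifies.
#' @export
build_edges <- function(placements, space,
                        distance_mode = c("euclidean_real", "euclidean_truncated")) {
  distance_mode <- match.arg(distance_mode)
  if (any(is.na(placements$sr))) stop("build_edges: social reaches are unset", call. = FALSE)
  n <- nrow(placements)
  empty <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("from", "to")))
  if (n < 2L) return(empty)
  dx <- wrap_diff(outer(placements$x, placements$x, "-"), space$width)
  dy <- wrap_diff(outer(placements$y, placements$y, "-"), space$height)
  d <- sqrt(dx^2 + dy^2)
  if (distance_mode == "euclidean_truncated") d <- floor(d)
  shorter <- pmin(matrix(placements$sr, n, n), matrix(placements$sr, n, n, byrow = TRUE))
  adj <- shorter >= d
  adj[lower.tri(adj, diag = TRUE)] <- FALSE   # keep each unordered pair once, no self-loops
  idx <- which(adj, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(empty)
  m <- cbind(from = placements$agent_id[idx[, "row"]],
             to   = placements$agent_id[idx[, "col"]])
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

#' Generate a Social Circles network
#'
#' Runs the three generator steps — uniform placement on the torus, reach
#' assignment, reciprocal shorter-reach edge formation — under the
#' configuration's seed. The result is fully reproducible from the
#' configuration alone.
#'
#' @param config A [generator_config()].
#' @return An object of class `sc_network`: a list with `placements` (the
#'   agent table), `edges` (two-column id matrix), `space`, and the
#'   `distance_mode` used.
#' @examples
#' cfg <- generator_config(200, torus_space(140, 140),
#'                         reach_discrete(c(15, 30), c(0.75, 0.25)), seed = 7)
#' net <- generate_network(cfg)
#' net
#' @export
generate_network <- function(config) {
  if (!inherits(config, "generator_config")) {
    stop("generate_network: config must be a generator_config", call. = FALSE)
  }
  set.seed(config$seed)
  pl <- place_agents(config$n, config$space)
  pl <- assign_reaches(pl, config$reach_spec)
  sc_network(pl, build_edges(pl, config$space, config$distance_mode),
             config$space, config$distance_mode)
}

#' Construct an sc_network
#'
#' Container for a generated (or re-read) network: the placement table and the
#' undirected edge set stored once as unordered pairs. Validates that no edge
#' is a self-loop and that every endpoint id exists among the placements.
#'
#' @param placements Agent table with columns `agent_id`, `x`, `y`, `sr`.
#' @param edges Two-column integer matrix of agent-id pairs.
#' @param space A [torus_space()] (optional for networks read from edge lists).
#' @param distance_mode Distance arithmetic used to build the edges, if known.
#' @return An object of class `sc_network`.
#' @export
sc_network <- function(placements, edges, space = NULL,
                       distance_mode = "euclidean_real") {
  edges <- matrix(as.integer(edges), ncol = 2,
                  dimnames = list(NULL, c("from", "to")))
  if (nrow(edges) > 0L) {
    if (any(edges[, 1] == edges[, 2])) stop("sc_network: self-loop edge", call. = FALSE)
    swap <- edges[, 1] > edges[, 2]   # canonical unordered form, stored once
    edges[swap, ] <- edges[swap, 2:1]
    edges <- unique(edges)
    if (!all(edges %in% placements$agent_id)) {
      stop("sc_network: edge endpoint id not present in placements", call. = FALSE)
    }
  }
  structure(list(placements = placements, edges = edges, space = space,
                 distance_mode = distance_mode),
            class = "sc_network")
}

#' @export
print.sc_network <- function(x, ...) {
  sp <- if (is.null(x$space)) "unknown space" else
    sprintf("%dx%d torus", x$space$width, x$space$height)
  cat(sprintf("<sc_network: %d agents on %s, %d edges>\n",
              nrow(x$placements), sp, nrow(x$edges)))
  invisible(x)
}

#' Convert an sc_network to an igraph graph
#'
#' Vertices are named by their 0-based agent ids and carry `x`, `y`, `sr`
#' attributes when available; isolated agents are kept as isolated vertices.
#'
#' @param network An `sc_network`.
#' @return An undirected `igraph` graph.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "sc_network"))
  ids <- as.character(network$placements$agent_id)
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  if (nrow(network$edges) > 0L) {
    ends <- rbind(as.character(network$edges[, 1]), as.character(network$edges[, 2]))
    g <- igraph::add_edges(g, as.vector(ends))
  }
  g <- igraph::set_vertex_attr(g, "x", value = network$placements$x)
  g <- igraph::set_vertex_attr(g, "y", value = network$placements$y)
  g <- igraph::set_vertex_attr(g, "sr", value = network$placements$sr)
  g
}
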