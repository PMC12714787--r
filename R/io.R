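#' Read and write networks as delimited text and GraphML
#'
#' The edge-list dialect is fixed: two integer columns with header
#' `source,target`, comma-delimited, LF line endings, 0-based agent ids, each
#' undirected edge stored once. The node table is `agent_id,x,y,sr`. GraphML
#' files carry `x`, `y` and `sr` as node attributes. These cover both
#' directions: emitting generated networks for downstream simulation tools,
#' and re-reading previously emitted files for re-measurement.
#'
#' @param network An `sc_network`.
#' @param path File path.
#' @return Writers return `path` invisibly; readers return an `sc_network`
#'   (edge lists, having no coordinates, yield placements with `NA` `x`, `y`,
#'   `sr` — sufficient for all topological measurements).
#' @name network_io
NULL

#' @rdname network_io
#' @export
write_edge_list <- function(network, path) {
  stopifnot(inherits(network, "sc_network"))
  df <- data.frame(source = network$edges[, 1], target = network$edges[, 2])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

#' @rdname network_io
#' @export
read_edge_list <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("source", "target") %in% names(df))) {
    stop(sprintf("read_edge_list: '%s' must have columns 'source' and 'target' (got: %s)",
                 path, paste(names(df), collapse = ", ")), call. = FALSE)
  }
  if (nrow(df) == 0L) {
    stop(sprintf("read_edge_list: '%s' contains no edges", path), call. = FALSE)
  }
  bad <- which(is.na(df$source) | is.na(df$target))
  if (length(bad) > 0L) {
    stop(sprintf("read_edge_list: '%s' line %d is not a pair of integer ids",
                 path, bad[1] + 1L), call. = FALSE)
  }
  ids <- sort(unique(c(df$source, df$target)))
  placements <- data.frame(agent_id = as.integer(ids),
                           x = NA_integer_, y = NA_integer_, sr = NA_real_)
  sc_network(placements, cbind(df$source, df$target))
}

#' @rdname network_io
#' @export
write_node_table <- function(network, path) {
  stopifnot(inherits(network, "sc_network"))
  utils::write.csv(network$placements, path, row.names = FALSE, quote = FALSE,
                   eol = "\n")
  invisible(path)
}

#' @rdname network_io
#' @export
read_node_table <- function(path) {
  df <- utils::read.csv(path)
  need <- c("agent_id", "x", "y", "sr")
  if (!all(need %in% names(df))) {
    stop(sprintf("read_node_table: '%s' must have columns %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  df[need]
}

#' @rdname network_io
#' @export
write_graphml <- function(network, path) {
  stopifnot(inherits(network, "sc_network"))
  igraph::write_graph(as_igraph(network), path, format = "graphml")
  invisible(path)
}

#' @rdname network_io
#' @export
read_graphml <- function(path) {
  g <- tryCatch(igraph::read_graph(path, format = "graphml"),
                error = function(e) {
                  stop(sprintf("read_graphml: cannot parse '%s': %s",
                               path, conditionMessage(e)), call. = FALSE)
                })
  attrs <- igraph::vertex_attr_names(g)
  ids <- if ("name" %in% attrs) as.integer(igraph::V(g)$name)
         else seq_len(igraph::vcount(g)) - 1L
  placements <- data.frame(
    agent_id = ids,
    x = if ("x" %in% attrs) as.integer(round(igraph::V(g)$x)) else NA_integer_,
    y = if ("y" %in% attrs) as.integer(round(igraph::V(g)$y)) else NA_integer_,
    sr = if ("sr" %in% attrs) as.numeric(igraph::V(g)$sr) else NA_real_)
  e <- igraph::as_edgelist(g, names = FALSE)
  edges <- cbind(ids[e[, 1]], ids[e[, 2]])
  net <- sc_network(placements[order(placements$agent_id), , drop = FALSE], edges)
  net
}

#' Read a network, dispatching on format
#'
#' @param path Input file.
#' @param format `"auto"` (by extension: `.graphml` vs anything else as edge
#'   list), `"edgelist"` or `"graphml"`.
#' @return An `sc_network`.
#' @export
read_network <- function(path, format = c("auto", "edgelist", "graphml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("read_network: no such file '%s'", path), call. = FALSE)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) == "graphml") "graphml" else "edgelist"
  }
  switch(format, graphml = read_graphml(path), edgelist = read_edge_list(path))
}

#' Write a run manifest
#'
#' Records, as JSON, everything needed to regenerate a run bit-identically:
#' the configuration echo, the base seed and per-replicate seeds, the package
#' version, a timestamp, and the paths of every file the run produced.
#'
#' @param path Output JSON path.
#' @param config_echo Named list echoing the configuration.
#' @param base_seed Integer base seed.
#' @param seeds Integer vector of per-replicate (or single-run) seeds.
#' @param outputs Character vector of produced file paths.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config_echo, base_seed, seeds, outputs) {
  manifest <- list(
    config = config_echo,
    base_seed = base_seed,
    seeds = as.integer(seeds),
    software = list(package = "socialcircles",
                    version = as.character(utils::packageVersion("socialcircles"))),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = outputs)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
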