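#' Experiment configuration
#'
#' One replicated design: a discrete reach mixture plus run parameters.
#' Replicate `r` (1-based) uses seed `base_seed + r`, so any individual
#' replicate can be regenerated in isolation.
#'
#' @param label Short design name.
#' @param reach_values Strictly increasing positive reach values.
#' @param proportions Population proportions, same length, summing to ~1.
#' @param n Agent count (default 1000; 2000 is also a studied setting).
#' @param space A [torus_space()] (default 315 x 315).
#' @param replicates Number of networks to generate (default 30).
#' @param base_seed Integer base seed.
#' @param distance_mode See [generator_config()].
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(label, reach_values, proportions, n = 1000L,
                              space = torus_space(315L, 315L), replicates = 30L,
                              base_seed = 0L,
                              distance_mode = c("euclidean_real", "euclidean_truncated")) {
  distance_mode <- match.arg(distance_mode)
  replicates <- as.integer(replicates)
  if (is.na(replicates) || replicates < 1L) {
    stop("experiment_config: replicates must be >= 1", call. = FALSE)
  }
  spec <- reach_discrete(reach_values, proportions)   # validates lengths/sums
  structure(list(label = label, reach_spec = spec, n = as.integer(n),
                 space = space, replicates = replicates,
                 base_seed = as.integer(base_seed), distance_mode = distance_mode),
            class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf("<experiment_config '%s': reaches [%s] props [%s], n=%d, %d replicates, base_seed=%d>\n",
              x$label, paste(x$reach_spec$values, collapse = ","),
              paste(x$reach_spec$proportions, collapse = ","),
              x$n, x$replicates, x$base_seed))
  invisible(x)
}

#' The eight standard reach designs
#'
#' The canonical experimental grid: five two-reach designs (three varying the
#' reach values at fixed 75/25 proportions, three varying the proportions at
#' fixed values 20/40, with the [20,40] 75/25 design shared between the two
#' sets and materialized once) and three three-reach designs varying the
#' proportions over values 30/40/50.
#'
#' @param n Agent count; 1000 (canonical) or 2000; other values are accepted
#'   with a warning.
#' @param replicates Replicates per design (default 30).
#' @param base_seed Base seed for the first design; successive designs offset
#'   by 1000 so their replicate seed ranges never overlap.
#' @param space A [torus_space()].
#' @return Named list of 8 [experiment_config()] objects.
#' @export
standard_designs <- function(n = 1000L, replicates = 30L, base_seed = 0L,
                             space = torus_space(315L, 315L)) {
  n <- as.integer(n)
  if (!n %in% c(1000L, 2000L)) {
    warning(sprintf("standard_designs: n = %d is outside the canonical {1000, 2000}", n))
  }
  rows <- list(
    two_circles_15_30       = list(c(15, 30),     c(0.75, 0.25)),
    two_circles_20_40       = list(c(20, 40),     c(0.75, 0.25)),
    two_circles_30_50       = list(c(30, 50),     c(0.75, 0.25)),
    two_circles_20_40_90_10 = list(c(20, 40),     c(0.90, 0.10)),
    two_circles_20_40_25_75 = list(c(20, 40),     c(0.25, 0.75)),
    three_circles_10_20_70  = list(c(30, 40, 50), c(0.10, 0.20, 0.70)),
    three_circles_34_33_33  = list(c(30, 40, 50), c(0.34, 0.33, 0.33)),
    three_circles_70_20_10  = list(c(30, 40, 50), c(0.70, 0.20, 0.10))
  )
  out <- vector("list", length(rows))
  names(out) <- names(rows)
  for (i in seq_along(rows)) {
    out[[i]] <- experiment_config(names(rows)[i], rows[[i]][[1]], rows[[i]][[2]],
                                  n = n, space = space, replicates = replicates,
                                  base_seed = base_seed + (i - 1L) * 1000L)
  }
  out
}

#' Run one replicated experiment
#'
#' Generates `replicates` networks (replicate `r` seeded with
#' `base_seed + r`), measures the full property battery on each giant
#' component, and aggregates by the field-wise arithmetic mean. Properties
#' that come back flagged-undefined (`NA`, e.g. zero-variance assortativity)
#' are skipped in the mean and counted in `skipped_fields`. A replicate whose
#' giant component has fewer than 3 nodes is excluded with a warning.
#'
#' @param config An [experiment_config()].
#' @param verbose Print one progress line per replicate.
#' @return An object of class `experiment_result`: list with `config`,
#'   `per_replicate` (data.frame, one row per replicate, with `replicate` and
#'   `seed` columns), `aggregate` (named numeric means), `sd` (named numeric
#'   standard deviations) and `skipped_fields`.
#' @export
run_experiment <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  rows <- vector("list", config$replicates)
  for (r in seq_len(config$replicates)) {
    seed <- config$base_seed + r
    gcfg <- generator_config(config$n, config$space, config$reach_spec,
                             seed = seed, distance_mode = config$distance_mode)
    net <- generate_network(gcfg)
    props <- network_properties(net)
    if (props$n_giant < 3L) {
      warning(sprintf("run_experiment('%s'): replicate %d (seed %d) has a giant component of %d nodes; excluded",
                      config$label, r, seed, props$n_giant))
      next
    }
    if (verbose) {
      message(sprintf("%s replicate %d: seed=%d giant=%d edges=%d",
                      config$label, r, seed, props$n_giant, props$edges))
    }
    rows[[r]] <- cbind(data.frame(replicate = r, seed = seed), props)
  }
  per <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(per) || nrow(per) == 0L) {
    stop(sprintf("run_experiment('%s'): no replicate produced a usable giant component",
                 config$label), call. = FALSE)
  }
  vals <- per[, property_columns(), drop = FALSE]
  aggregate <- vapply(vals, function(v) mean(v, na.rm = TRUE), numeric(1))
  sds <- vapply(vals, function(v) if (sum(!is.na(v)) > 1L) sd(v, na.rm = TRUE) else NA_real_,
                numeric(1))
  skipped <- vapply(vals, function(v) sum(is.na(v)), integer(1))
  structure(list(config = config, per_replicate = per, aggregate = aggregate,
                 sd = sds, skipped_fields = skipped[skipped > 0L]),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result '%s': %d replicates>\n",
              x$config$label, nrow(x$per_replicate)))
  agg <- x$aggregate
  cat(sprintf("  edges %.0f | degree mean %.1f (gini %.3f) | assortativity %.3f\n",
              agg[["edges"]], agg[["degree_mean"]], agg[["degree_gini"]],
              agg[["assortativity_edge"]]))
  cat(sprintf("  clustering %.3f | transitivity %.3f | geodesic %.3f | diameter %.0f\n",
              agg[["clustering_mean"]], agg[["transitivity"]],
              agg[["geodesic_mean"]], agg[["diameter"]]))
  invisible(x)
}

#' Giant-component degrees stratified by social reach
#'
#' Groups the degree of every giant-component node by its social reach value,
#' supporting comparisons of the degree distributions of short- versus
#' long-reach agents within the same network. Each giant-component node
#' contributes its degree exactly once.
#'
#' @param network An `sc_network` with reaches assigned.
#' @return Named list, one element per distinct reach value (ascending),
#'   holding the integer degrees of that reach group.
#' @export
degrees_by_reach <- function(network) {
  stopifnot(inherits(network, "sc_network"))
  gc <- giant_component(network)
  g <- as_igraph(gc)
  deg <- igraph::degree(g)
  sr <- gc$placements$sr
  split(unname(deg), sr)
}

#' Tabulate experiment aggregates
#'
#' Renders a set of experiment results as one row per design with a chosen,
#' ordered subset of property columns, values formatted to the conventional
#' precision: integers for `edges`, `edges_total`, `n_giant` and `diameter`
#' (diameter being the rounded mean of per-replicate diameters), one decimal
#' for `degree_mean` above 10, three decimals otherwise.
#'
#' @param results List of `experiment_result` objects (or a single one).
#' @param columns Character vector of property names, in the desired order.
#' @return A `data.frame` with a `design` column followed by the requested
#'   columns (formatted as character).
#' @export
results_table <- function(results, columns) {
  if (inherits(results, "experiment_result")) results <- list(results)
  if (length(results) == 0L) stop("results_table: no results supplied", call. = FALSE)
  if (length(columns) == 0L) stop("results_table: no columns requested", call. = FALSE)
  valid <- property_columns()
  bad <- setdiff(columns, valid)
  if (length(bad) > 0L) {
    stop(sprintf("results_table: unknown property name(s) %s; valid names are: %s",
                 paste(sQuote(bad), collapse = ", "),
                 paste(valid, collapse = ", ")), call. = FALSE)
  }
  fmt_cell <- function(name, value) {
    if (name %in% c("edges", "edges_total", "n_giant", "diameter")) {
      sprintf("%d", as.integer(round(value)))
    } else if (name == "degree_mean" && !is.na(value) && value >= 10) {
      sprintf("%.1f", value)
    } else {
      sprintf("%.3f", value)
    }
  }
  rows <- lapply(results, function(res) {
    cells <- vapply(columns, function(cn) fmt_cell(cn, res$aggregate[[cn]]),
                    character(1))
    c(design = res$config$label, cells)
  })
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
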