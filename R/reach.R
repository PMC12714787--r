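#' Social-reach distributions
#'
#' A reach specification describes how social reaches are assigned across the
#' agent population. Three variants are supported, mirroring the generator's
#' published configurations:
#'
#' * `reach_discrete(values, proportions)` — a discrete mixture: each agent
#'   receives one of a small set of reach values (the One/Two/Three Circles
#'   variants), with population composition fixed exactly by largest-remainder
#'   rounding of the proportions.
#' * `reach_poisson(mean)` — i.i.d. Poisson draws (the published continuous
#'   variant uses mean 30).
#' * `reach_uniform(low, high)` — i.i.d. continuous uniform draws (published
#'   range 10 to 50).
#'
#' @param values Strictly increasing vector of positive reach values.
#' @param proportions Fractions in (0, 1], same length as `values`, summing to
#'   1 within +/- 0.01 (slack needed for compositions such as 34/33/33).
#' @param mean Positive Poisson mean.
#' @param low,high Positive bounds with `low <= high`.
#' @return An object of class `reach_spec` with a `variant` field
#'   (`"discrete_mixture"`, `"poisson"` or `"uniform"`).
#' @examples
#' reach_discrete(c(15, 30), c(0.75, 0.25))
#' reach_poisson(30)
#' reach_uniform(10, 50)
#' @name reach_spec
NULL

#' @rdname reach_spec
#' @export
reach_discrete <- function(values, proportions) {
  values <- as.numeric(values)
  proportions <- as.numeric(proportions)
  if (length(values) == 0L || length(values) != length(proportions)) {
    stop("reach_discrete: values and proportions must be nonempty and the same length",
         call. = FALSE)
  }
  if (any(values <= 0)) stop("reach_discrete: all reach values must be > 0", call. = FALSE)
  if (is.unsorted(values, strictly = TRUE)) {
    stop("reach_discrete: values must be strictly increasing", call. = FALSE)
  }
  if (any(proportions <= 0) || any(proportions > 1)) {
    stop("reach_discrete: proportions must lie in (0, 1]", call. = FALSE)
  }
  if (abs(sum(proportions) - 1) > 0.01) {
    stop(sprintf("reach_discrete: proportions sum to %.4f; must be 1 within +/- 0.01",
                 sum(proportions)), call. = FALSE)
  }
  structure(list(variant = "discrete_mixture", values = values,
                 proportions = proportions),
            class = "reach_spec")
}

#' @rdname reach_spec
#' @export
reach_poisson <- function(mean) {
  mean <- as.numeric(mean)
  if (length(mean) != 1L || is.na(mean) || mean <= 0) {
    stop("reach_poisson: mean must be a single positive number", call. = FALSE)
  }
  structure(list(variant = "poisson", mean = mean), class = "reach_spec")
}

#' @rdname reach_spec
#' @export
reach_uniform <- function(low, high) {
  low <- as.numeric(low); high <- as.numeric(high)
  if (length(low) != 1L || length(high) != 1L || is.na(low) || is.na(high) ||
      low <= 0 || high < low) {
    stop("reach_uniform: need positive bounds with low <= high", call. = FALSE)
  }
  structure(list(variant = "uniform", low = low, high = high), class = "reach_spec")
}

#' @export
print.reach_spec <- function(x, ...) {
  desc <- switch(x$variant,
    discrete_mixture = sprintf("discrete mixture: values [%s], proportions [%s]",
                               paste(x$values, collapse = ", "),
                               paste(x$proportions, collapse = ", ")),
    poisson = sprintf("Poisson(mean = %g)", x$mean),
    uniform = sprintf("Uniform(%g, %g)", x$low, x$high))
  cat("<reach_spec ", desc, ">\n", sep = "")
  invisible(x)
}

#' Largest-remainder allocation of mixture counts
#'
#' Converts mixture proportions into exact integer counts summing to `n`:
#' each class gets `floor(p_k * n)`, and the leftover units go to the classes
#' with the largest fractional remainders. Ties in remainder are broken in
#' favour of earlier (shorter-reach) classes, which is immaterial for the
#' standard designs where remainders differ.
#'
#' @param proportions Mixture proportions (summing to ~1).
#' @param n Total count to allocate.
#' @return Integer vector of counts, same length as `proportions`, summing to
#'   `n`.
#' @examples
#' mixture_counts(c(0.34, 0.33, 0.33), 1000)  # 340 330 330
#' @export
mixture_counts <- function(proportions, n) {
  raw <- proportions * n
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short < 0 || short > length(proportions)) {
    stop(sprintf(
      "mixture_counts: proportions (sum %.4f) cannot be reconciled to n = %d",
      sum(proportions), n), call. = FALSE)
  }
  if (short > 0) {
    take <- order(raw - counts, decreasing = TRUE)[seq_len(short)]
    counts[take] <- counts[take] + 1
  }
  as.integer(counts)
}
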