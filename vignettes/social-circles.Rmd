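---
title: "The Social Circles generator: model, measurement conventions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Social Circles generator: model, measurement conventions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(socialcircles)
```

## The model

The Social Circles generator produces synthetic social-contact networks from a
simple spatial mechanism. Each of `n` agents occupies a cell of a wrapped
integer grid (a torus, so there are no edge effects), and each carries a
*social reach* `sr` — the radius within which it can perceive other agents.
An undirected edge forms between agents `i` and `j` exactly when the contact
is mutual:

    min(sr_i, sr_j) >= d(i, j),

where `d` is the Euclidean distance with per-axis wrap-around,
`min(|dx|, W - |dx|)`. The shorter reach binds: a far-seeing agent cannot
connect to a near-sighted one that cannot see it back. This reciprocity is
what gives the generated networks their social-network signature — high
clustering (two agents inside the same circle are usually inside each
other's), positive degree assortativity (long-reach agents link mostly to
other long-reach agents), heavy-tailed but bounded degrees, and short paths
once the reach mixture is dense enough to percolate.

The canonical configuration places 1,000 agents on a 315 x 315 torus
(99,225 cells, about 1% occupancy). The farthest any two cells can be is
`sqrt(2 * 157^2)` (about 222), which sets the natural scale for reach values:
the studied designs use reaches between 15 and 50.

```{r model}
cfg <- generator_config(n = 1000, space = torus_space(315, 315),
                        reach_spec = reach_discrete(c(15, 30), c(0.75, 0.25)),
                        seed = 1)
net <- generate_network(cfg)
net
```

## Parameters that matter

* **Reach values** (grid-distance units). Doubling the reaches roughly
  quadruples the circle area, so edge counts grow much faster than the
  reaches themselves; mean degree more than triples between the `[15,30]`
  and `[30,50]` designs.
* **Reach proportions.** With values fixed at `[20,40]`, moving the
  population from 90/10 to 25/75 short/long more than doubles the edge
  count: a long reach only converts to edges when the reached agent can
  reciprocate, so long-reach agents benefit from each other. This is also
  why increasing the long-reach share *raises* degree inequality (the
  short-reach agents gain nothing) while raising the values lowers it.
* **Node count / density.** 1,000 agents is the canonical setting; 2,000 is
  supported and behaves like a uniform reach increase (more agents inside
  the same circle).
* **Distribution variants.** Besides the discrete mixtures (the One/Two/
  Three Circles designs) the generator offers i.i.d. Poisson reaches
  (`reach_poisson(30)`) and continuous uniform reaches
  (`reach_uniform(10, 50)`).

## Measurement conventions

All structural properties are measured on the **giant component** (ties
broken toward the component holding the smallest agent id). Dispersion is
summarized by the **Gini coefficient** `sum |x_i - x_j| / (2 n^2 mean(x))`
throughout, because centrality distributions here are far from normal;
Gini is scale-invariant, so it is unaffected by centrality normalization
conventions. Specific conventions, chosen where several are in circulation:

* **Closeness** is `(n-1) / sum_u d(v,u)` — the reciprocal of a node's mean
  geodesic. This is the convention consistent with the reference summary
  values (e.g. closeness mean around 0.13 for the sparsest design).
* **Betweenness** is shortest-path betweenness with even splitting over
  equally short paths, normalized by `(n-1)(n-2)/2`, consistent with the
  reported means of 0.002–0.007.
* **Eigenvector centrality** is scaled to unit Euclidean norm. The mean is
  therefore convention-dependent and only its Gini (invariant) should be
  compared across implementations.
* **Two assortativity definitions** are provided because both are in use:
  the edge-end Pearson correlation over the `2E` ordered endpoint pairs
  (Newman's definition; the one reported by `network_properties`' main
  column) and the node-level correlation between degree and mean neighbour
  degree. They are *not* interchangeable — on these networks the node-level
  variant runs noticeably higher.
* **Local clustering** of a degree-<2 node is taken as 0 and included in
  the mean (set `low_degree_as_zero = FALSE` to exclude such nodes
  instead).
* **Geodesics** are summarized over unordered pairs; the mean and Gini are
  identical under the ordered-pair reading, so the choice is cosmetic.
* **Undefined correlations** (zero variance, e.g. any regular graph) yield
  `NA_real_`, never a silent 0; experiment aggregation skips them and
  reports a per-field skip count.

## Numerical and design choices

* **Distinct cells.** Whether the original NetLogo implementation allowed
  co-located agents is not documented; this package samples cells without
  replacement, matching the "1% of positions occupied" reading. At 1%
  occupancy the practical difference is negligible.
* **Distance arithmetic.** Distances are exact reals by default
  (`euclidean_real`). A replication mode `euclidean_truncated` floors
  distances to integers, since early implementations appear to have worked
  with integer distances (their uniform-reach networks ran short of edges,
  consistent with truncation). Neither mode is asserted to be what the
  original code did; the default is validated directly against the
  published summary tables.
* **Tie handling.** The edge test is non-strict (`>=`): with integer
  coordinates, pairs at distance exactly equal to the binding reach occur,
  and they are kept as edges.
* **Mixture rounding.** Discrete mixtures are allocated by largest-remainder
  rounding, so a 34/33/33 split of 1,000 agents gives exactly 340/330/330 in
  every replicate; randomness decides only *which* agents get which reach,
  never the composition.
* **Seeding.** Replicate `r` of an experiment uses `base_seed + r`, so any
  single replicate is reproducible in isolation; `standard_designs()`
  offsets successive designs by 1,000 so their seed ranges never overlap.
* **Edge construction.** The reference implementation is the exhaustive
  all-pairs test, evaluated as vectorized wrapped-distance matrices
  (5 x 10^5 pair tests at n = 1,000 — well under a second). The test suite
  proves it identical to an independent double-loop scan; any future
  spatial index must pass the same equivalence check.
* **Aggregation.** Experiment aggregates are plain arithmetic means over
  replicates (no trimming); per-field standard deviations are stored
  alongside to make tolerance reasoning possible. The aggregate diameter is
  the mean of per-replicate integer diameters and is rounded for display.
* **Eigenvector computation** uses an ARPACK-based principal eigenvector
  with the sign fixed nonnegative (valid for connected graphs by
  Perron–Frobenius).

## What the generator does and does not emulate

The generator reproduces the *structural* signature of social contact
networks — clustering in the 0.5–0.6 band, positive assortativity, short
paths, right-skewed degrees — from purely spatial homophily. It does not
model anything temporal (tie formation or decay), attribute homophily
beyond position, directed or weighted relations, or group/affiliation
structure. Communities emerge around spatial concentrations of long-reach
agents but are not targeted or measured here. Consequently, a passing test
suite shows that the implementation reproduces the published structural
summaries of the *model*, not that the model matches any particular
empirical network.

## Problem sizes used by the tests

The unit tests exercise the algorithms at small scale (networks of 10–400
agents, where brute-force oracles — pairwise Gini sums, double-loop edge
scans, BFS distance matrices, path-count betweenness — are exact and fast).
The reproduction checks run the full canonical study, eight designs times
30 replicates of 1,000 agents, and compare the aggregates with the published
summary tables at the sampling tolerances appropriate for 30-replicate
means; the same computation backs `scripts/acceptance.R`.

## Known limitations

* The all-pairs edge scan is O(n^2) in memory and time; it is instant at the
  canonical sizes but a cell-binned neighbourhood search would be needed far
  beyond ~10^4 agents.
* Whole-network edge counts and giant-component counts are both recorded
  (`edges_total` vs `edges`) because the published tables do not say which
  they print; for the studied designs the giant component captures nearly
  every node, so the two differ by well under 1%.
* The node-level (degree vs mean neighbour degree) assortativity values
  published for the original NetLogo implementation come from a different
  codebase and are reported here for comparison only, not asserted as
  reproduction targets.
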