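# Thresholded term-association networks and their case-study statistics:
# threshold sweep, degree distribution, hubs, giant component with a
# random-network (G(n, m)) significance test, and a descriptive power-law
# fit of the degree distribution.

#' Edge counts across a threshold grid
#'
#' For each threshold the number of pairs scoring at or above it; the
#' counts are non-increasing in the threshold.
#'
#' @param score_table A `pair_scores` table.
#' @param thresholds Sorted numeric grid.
#' @return data.table with columns `threshold`, `n_edges`.
#' @export
threshold_sweep <- function(score_table, thresholds) {
  stopifnot(inherits(score_table, "pair_scores"), nrow(score_table) > 0,
            !is.unsorted(thresholds))
  s <- score_table$score
  data.table(threshold = thresholds,
             n_edges = vapply(thresholds, function(th) sum(s >= th), 0L))
}

#' Build a thresholded association network
#'
#' Nodes are the terms incident to at least one edge; two terms are linked
#' when their relationship score is equal to or larger than the threshold.
#' No self-loops or duplicate edges can arise from a canonical pair table.
#'
#' @param score_table A `pair_scores` table.
#' @param threshold Score cutoff (edges kept at `score >= threshold`).
#' @return An object of class `assoc_network`: list with `graph` (igraph),
#'   `edges` (data.table `t1`, `t2`, `score`), `threshold`.
#' @export
build_network <- function(score_table, threshold) {
  stopifnot(inherits(score_table, "pair_scores"))
  edges <- as.data.table(score_table)[score >= threshold]
  edges <- edges[t1 != t2]
  setorderv(edges, c("t1", "t2"))
  if (!nrow(edges)) warning("no edges at threshold ", threshold)
  g <- igraph::graph_from_data_frame(
    edges[, .(t1, t2, weight = score)], directed = FALSE)
  structure(list(graph = g, edges = edges[], threshold = threshold),
            class = "assoc_network")
}

#' @export
print.assoc_network <- function(x, ...) {
  cat(sprintf("<assoc_network> threshold=%s: %d nodes, %d edges\n",
              format(x$threshold), igraph::vcount(x$graph), nrow(x$edges)))
  invisible(x)
}

#' Degree statistics of an association network
#'
#' @param network An `assoc_network`.
#' @return List with `n_nodes`, `n_edges`, `degree_histogram` (data.table
#'   `degree`, `count`), `fraction_degree1`, `fraction_degree3plus`, and
#'   `hubs` (all nodes attaining the maximum degree, with that degree as
#'   `hub_degree`).
#' @export
degree_stats <- function(network) {
  stopifnot(inherits(network, "assoc_network"), nrow(network$edges) > 0)
  deg <- igraph::degree(network$graph)
  hist <- as.data.table(table(degree = deg))
  hist[, degree := as.integer(as.character(degree))]
  setnames(hist, "N", "count")
  setorderv(hist, "degree")
  list(
    n_nodes = length(deg),
    n_edges = nrow(network$edges),
    degree_histogram = hist[],
    fraction_degree1 = mean(deg == 1L),
    fraction_degree3plus = mean(deg >= 3L),
    hubs = names(deg)[deg == max(deg)],
    hub_degree = unname(max(deg))
  )
}

#' Size of the giant (largest connected) component
#'
#' @param network An `assoc_network` or an igraph object.
#' @return Integer node count of the largest component.
#' @export
giant_component <- function(network) {
  g <- if (inherits(network, "assoc_network")) network$graph else network
  stopifnot(igraph::vcount(g) > 0)
  max(igraph::components(g)$csize)
}

#' Empirical significance of the giant-component size
#'
#' Compares the observed giant-component size with `n_replicates` uniform
#' random graphs G(n, m) matched on node and edge counts. With
#' `side = "smaller"` (the association-clustering direction: modular
#' networks have smaller giant components than random ones), `r` counts
#' replicates whose giant component is `<=` the observed size and the
#' add-one estimator `p = (r + 1) / (n_replicates + 1)` is returned, whose
#' floor for an observation below every replicate is `1 / (n_replicates + 1)`.
#'
#' @param network An `assoc_network`.
#' @param n_replicates Number of random networks (>= 1).
#' @param side `"smaller"` or `"larger"`.
#' @param seed Integer seed for the replicate generator.
#' @param null_model `"gnm"` (uniform random graph, default) or `"rewire"`
#'   (degree-preserving rewiring) for sensitivity analysis.
#' @return List with `observed`, `p_value`, `replicate_sizes`.
#' @export
gc_significance <- function(network, n_replicates = 10000L,
                            side = c("smaller", "larger"), seed = 1L,
                            null_model = c("gnm", "rewire")) {
  side <- match.arg(side)
  null_model <- match.arg(null_model)
  stopifnot(inherits(network, "assoc_network"), n_replicates >= 1L)
  n <- igraph::vcount(network$graph)
  m <- igraph::ecount(network$graph)
  obs <- giant_component(network)
  sizes <- with_seed(seed, vapply(seq_len(n_replicates), function(i) {
    g <- if (null_model == "gnm") igraph::sample_gnm(n, m)
         else igraph::rewire(network$graph,
                             igraph::keeping_degseq(niter = 10 * m))
    max(igraph::components(g)$csize)
  }, 0))
  r <- if (side == "smaller") sum(sizes <= obs) else sum(sizes >= obs)
  list(observed = obs,
       p_value = (r + 1) / (n_replicates + 1),
       replicate_sizes = sizes)
}

#' Descriptive power-law fit of a degree distribution
#'
#' Ordinary least squares of `log10 P(k)` on `log10 k` over degrees with
#' nonzero counts, where `P(k)` is the fraction of nodes with degree `k`.
#' This is the conventional descriptive scale-free diagnostic (an R-squared
#' on the log-log histogram), not a maximum-likelihood exponent estimate.
#'
#' @param degree_histogram data.table/data.frame with columns `degree`,
#'   `count` (as from [degree_stats()]), or a named vector
#'   (names = degrees).
#' @return List with `slope`, `r2`, `n_points`.
#' @export
powerlaw_fit <- function(degree_histogram) {
  if (!is.data.frame(degree_histogram))
    degree_histogram <- data.table(
      degree = as.integer(names(degree_histogram)),
      count = as.numeric(degree_histogram))
  h <- as.data.table(degree_histogram)[count > 0 & degree > 0]
  if (nrow(h) < 3L)
    stop("insufficient data: need >= 3 distinct degrees with nonzero counts")
  p <- h$count / sum(degree_histogram$count)
  fit <- lm(log10(p) ~ log10(h$degree))
  # summary.lm warns on exact log-linear data; the R^2 itself is well defined
  list(slope = unname(stats::coef(fit)[2]),
       r2 = suppressWarnings(summary(fit)$r.squared),
       n_points = nrow(h))
}

#' Full network report for the case study
#'
#' Convenience wrapper assembling [degree_stats()], [giant_component()],
#' [gc_significance()] and [powerlaw_fit()] into one list suitable for JSON
#' export.
#'
#' @inheritParams gc_significance
#' @return Named list of statistics.
#' @export
network_report <- function(network, n_replicates = 1000L, seed = 1L,
                           side = "smaller") {
  ds <- degree_stats(network)
  gc <- gc_significance(network, n_replicates, side = side, seed = seed)
  pl <- tryCatch(powerlaw_fit(ds$degree_histogram),
                 error = function(e) list(slope = NA, r2 = NA, n_points = 0L))
  list(
    threshold = network$threshold,
    n_nodes = ds$n_nodes, n_edges = ds$n_edges,
    fraction_degree1 = ds$fraction_degree1,
    fraction_degree3plus = ds$fraction_degree3plus,
    hubs = ds$hubs, hub_degree = ds$hub_degree,
    giant_component_size = gc$observed,
    gc_p_value = gc$p_value,
    powerlaw_slope = pl$slope, powerlaw_r2 = pl$r2
  )
}
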