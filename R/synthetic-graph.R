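#' Generate a ground-truth connectivity graph
#'
#' Draws an undirected, unweighted graph on `n_nodes` nodes with a target
#' edge density, used as the planted connectivity structure behind
#' synthetic hemoglobin recordings.
#'
#' Two models are available. `"gnm"` picks exactly
#' `round(density * n(n-1)/2)` edges uniformly at random (the rounding is
#' base R's round-half-even, so the edge count is deterministic given the
#' density). `"cliques"` partitions a random subset of nodes into disjoint
#' cliques whose sizes are chosen greedily so the total edge count comes
#' as close as possible to the target; clique-union graphs admit an exact
#' positive-definite correlation representation, which makes them the
#' preferred planting model for cohort simulations (see the package
#' vignette).
#'
#' @param n_nodes number of nodes (default 44, one per measurement channel).
#' @param density target fraction of the `n(n-1)/2` possible edges, in
#'   `[0, 1]`.
#' @param seed optional integer seed for reproducibility.
#' @param model `"gnm"` (uniform random, default) or `"cliques"`.
#' @return An object of class `gt_graph`: list with `n_nodes`, logical
#'   `adjacency` (symmetric, zero diagonal), realized `density`, and the
#'   `model` used.
#' @examples
#' g <- generate_graph(10, 0.5, seed = 1)
#' sum(g$adjacency) / 2  # edge count
#' @export
generate_graph <- function(n_nodes = 44L, density, seed = NULL,
                           model = c("gnm", "cliques")) {
  model <- match.arg(model)
  if (!is.numeric(density) || length(density) != 1L || is.na(density) ||
      density < 0 || density > 1)
    stop("density must be a single value in [0, 1]")
  n_nodes <- as.integer(n_nodes)
  if (n_nodes < 1L) stop("n_nodes must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  n_pairs <- n_nodes * (n_nodes - 1L) / 2
  adjacency <- matrix(FALSE, n_nodes, n_nodes)
  if (model == "gnm") {
    m <- round(density * n_pairs)
    if (m > 0) {
      pairs <- which(upper.tri(adjacency))
      sel <- if (m >= length(pairs)) pairs else sample(pairs, m)
      adjacency[sel] <- TRUE
      adjacency <- adjacency | t(adjacency)
    }
  } else {
    sizes <- clique_sizes(n_nodes, round(density * n_pairs))
    perm <- sample.int(n_nodes)
    offset <- 0L
    for (m in sizes) {
      idx <- perm[(offset + 1L):(offset + m)]
      adjacency[idx, idx] <- TRUE
      offset <- offset + m
    }
    diag(adjacency) <- FALSE
  }
  structure(
    list(n_nodes = n_nodes, adjacency = adjacency,
         density = if (n_pairs > 0) sum(adjacency) / 2 / n_pairs else 0,
         model = model),
    class = "gt_graph")
}

# Greedy clique-size partition: largest clique whose edge count fits the
# remaining target, repeated. Exact except near density 1 where disjoint
# cliques cannot realize every edge count.
clique_sizes <- function(n_nodes, target_edges) {
  sizes <- integer(0)
  remaining_nodes <- n_nodes
  remaining_edges <- target_edges
  while (remaining_edges >= 1 && remaining_nodes >= 2) {
    m <- min(remaining_nodes, floor((1 + sqrt(1 + 8 * remaining_edges)) / 2))
    if (m * (m - 1) / 2 > remaining_edges) m <- m - 1L
    if (m < 2) break
    sizes <- c(sizes, as.integer(m))
    remaining_nodes <- remaining_nodes - m
    remaining_edges <- remaining_edges - m * (m - 1) / 2
  }
  sizes
}

#' @export
print.gt_graph <- function(x, ...) {
  cat(sprintf("<gt_graph> %d nodes, %d edges (density %.3f, model %s)\n",
              x$n_nodes, sum(x$adjacency) / 2, x$density, x$model))
  invisible(x)
}
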