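#' Pearson correlation matrix of a recording
#'
#' Computes the pairwise Pearson correlation between all channels of one
#' chromophore's (preprocessed) time series: the functional connectivity
#' matrix whose nodes are measurement channels. Zero-variance channels
#' have undefined correlations; their rows/columns are set to 0 (never an
#' edge) with a warning rather than aborting.
#'
#' @param rec an `hb_recording` with at least 3 samples and 2 channels.
#' @param chromophore `"oxy"`, `"deoxy"` or `"total"`.
#' @return symmetric numeric matrix with unit diagonal, class
#'   `fc_matrix`, with attributes `chromophore` and channel dimnames.
#' @export
correlation_matrix <- function(rec, chromophore = c("oxy", "deoxy", "total")) {
  stopifnot(inherits(rec, "hb_recording"))
  chromophore <- match.arg(chromophore)
  mat <- rec[[chromophore]]
  if (ncol(mat) < 3) stop("at least 3 samples are required")
  if (nrow(mat) < 2) stop("at least 2 channels are required")
  sds <- apply(mat, 1, stats::sd)
  r <- suppressWarnings(stats::cor(t(mat)))
  if (any(sds == 0)) {
    warning(sprintf("%d zero-variance channel(s); correlations set to 0",
                    sum(sds == 0)))
    r[sds == 0, ] <- 0
    r[, sds == 0] <- 0
  }
  r[!is.finite(r)] <- 0
  r <- pmin(pmax(r, -1), 1)
  diag(r) <- 1
  dimnames(r) <- list(rec$channel_labels, rec$channel_labels)
  attr(r, "chromophore") <- chromophore
  class(r) <- c("fc_matrix", class(r))
  r
}

#' Binarize a correlation matrix at a threshold
#'
#' Declares an undirected edge between two distinct channels when the
#' absolute Pearson correlation is strictly larger than the threshold
#' `delta` (so `|r|` exactly equal to `delta` gives no edge, and negative
#' correlations create edges through their magnitude).
#'
#' @param cm symmetric correlation matrix (e.g. from
#'   [correlation_matrix()]).
#' @param delta threshold in `[0, 1)`.
#' @return logical adjacency matrix (symmetric, zero diagonal) of class
#'   `binary_graph` with attribute `threshold`.
#' @export
binarize <- function(cm, delta) {
  if (!is.numeric(delta) || length(delta) != 1L || delta < 0 || delta >= 1)
    stop("delta must be a single value in [0, 1)")
  m <- unclass(cm)
  adjacency <- abs(m) > delta
  diag(adjacency) <- FALSE
  attributes(adjacency) <- list(dim = dim(m), dimnames = dimnames(m),
                                threshold = delta,
                                chromophore = attr(cm, "chromophore"))
  class(adjacency) <- c("binary_graph", "matrix")
  adjacency
}

as_adjacency <- function(g) {
  if (inherits(g, "gt_graph")) g <- g$adjacency
  m <- unclass(g)
  attr(m, "threshold") <- NULL
  attr(m, "chromophore") <- NULL
  class(m) <- "matrix"
  storage.mode(m) <- "double"
  m
}

#' Unweighted shortest path lengths
#'
#' All-pairs shortest hop counts of a binary graph, by level-synchronous
#' breadth-first search run from every node at once (the frontier of all
#' sources is advanced with one adjacency multiplication per level).
#' Unreachable pairs are `Inf`; the diagonal is 0.
#'
#' @param g a `binary_graph`, `gt_graph`, or logical/0-1 adjacency matrix.
#' @return numeric matrix of hop counts.
#' @export
shortest_paths <- function(g) {
  A <- as_adjacency(g)
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  frontier <- diag(n) > 0
  visited <- frontier
  d <- 0
  while (any(frontier)) {
    d <- d + 1
    nxt <- (A %*% frontier > 0) & !visited
    if (!any(nxt)) break
    D[nxt] <- d
    visited <- visited | nxt
    frontier <- nxt
  }
  dimnames(D) <- dimnames(A)
  D
}

#' Global efficiency of a binary graph
#'
#' The average inverse shortest path length over all ordered pairs of
#' distinct nodes, `E_glob = 1/(N(N-1)) * sum_{i != j} 1/L_ij`, with
#' `1/L = 0` for unreachable pairs (the Latora-Marchiori convention,
#' keeping the result in `[0, 1]`: 1 for a complete graph, 0 for an
#' edgeless one).
#'
#' @param g a `binary_graph`, `gt_graph`, or adjacency matrix with
#'   `n >= 2` nodes.
#' @return efficiency in `[0, 1]`.
#' @export
global_efficiency <- function(g) {
  A <- as_adjacency(g)
  n <- nrow(A)
  if (n < 2) stop("global efficiency requires at least 2 nodes")
  D <- shortest_paths(A)
  inv <- 1 / D
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Local efficiency of a binary graph
#'
#' For each node, the global efficiency of the subgraph induced on its
#' immediate neighbors (the node itself excluded); nodes with fewer than
#' two neighbors contribute 0. The local efficiency is the average over
#' all `N` nodes, `E_loc = 1/N * sum_i E(G_i)`, and measures the fault
#' tolerance of local information exchange.
#'
#' @param g a `binary_graph`, `gt_graph`, or adjacency matrix.
#' @return efficiency in `[0, 1]`.
#' @export
local_efficiency <- function(g) {
  A <- as_adjacency(g)
  n <- nrow(A)
  if (n < 1) stop("local efficiency requires at least 1 node")
  contrib <- vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] > 0)
    if (length(nb) < 2) return(0)
    global_efficiency(A[nb, nb, drop = FALSE])
  }, numeric(1))
  mean(contrib)
}

#' Efficiency across a threshold grid
#'
#' Binarizes a correlation matrix at each threshold of the grid and
#' computes global and local efficiency of each resulting graph: one
#' (E_glob, E_loc) pair per threshold.
#'
#' @param cm a correlation matrix (see [correlation_matrix()]).
#' @param deltas threshold grid, each in `[0, 1)`; default
#'   `seq(0.2, 0.6, by = 0.1)`.
#' @return data.frame with columns `chromophore`, `delta`, `e_glob`,
#'   `e_loc`.
#' @export
efficiency_sweep <- function(cm, deltas = seq(0.2, 0.6, by = 0.1)) {
  if (length(deltas) == 0) stop("deltas must be non-empty")
  rows <- lapply(deltas, function(d) {
    g <- binarize(cm, d)
    data.frame(chromophore = attr(cm, "chromophore") %||% NA_character_,
               delta = d,
               e_glob = global_efficiency(g),
               e_loc = local_efficiency(g))
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
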