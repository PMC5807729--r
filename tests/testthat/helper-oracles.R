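# Independent reference implementations used to cross-check the package's
# graph metrics, plus small fixture builders. These deliberately use
# different algorithms from the package (Floyd-Warshall instead of BFS,
# explicit double loops instead of vectorized frontiers).

floyd_warshall <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A > 0] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) {
    D <- pmin(D, outer(D[, k], D[k, ], "+"))
  }
  D
}

global_eff_oracle <- function(A) {
  n <- nrow(A)
  D <- floyd_warshall(A)
  total <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && is.finite(D[i, j])) total <- total + 1 / D[i, j]
  }
  total / (n * (n - 1))
}

local_eff_oracle <- function(A) {
  n <- nrow(A)
  vals <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] > 0)
    vals[i] <- if (length(nb) < 2) 0 else global_eff_oracle(A[nb, nb, drop = FALSE])
  }
  mean(vals)
}

rand_adj <- function(n, p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(0, n, n)
  A[upper.tri(A)] <- as.numeric(stats::runif(n * (n - 1) / 2) < p)
  A + t(A)
}

adj_from_edges <- function(n, edges) {
  A <- matrix(0, n, n)
  for (e in edges) {
    A[e[1], e[2]] <- 1
    A[e[2], e[1]] <- 1
  }
  A
}

# quick white-noise recording, channels x samples
noise_recording <- function(n_ch = 4, n_s = 500, dt = 0.027, sd = 1,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  hb_recording(oxy = matrix(stats::rnorm(n_ch * n_s, sd = sd), n_ch),
               deoxy = matrix(stats::rnorm(n_ch * n_s, sd = sd), n_ch),
               sampling_interval = dt)
}

# residual-regression oracle for first-order partial correlation
partial_corr_oracle <- function(x, y, z) {
  rx <- stats::residuals(stats::lm(x ~ z))
  ry <- stats::residuals(stats::lm(y ~ z))
  stats::cor(rx, ry)
}
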