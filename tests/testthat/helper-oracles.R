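# Independent brute-force oracles and small fixtures used across tests.

# Onnela-style weighted clustering by explicit triple loop over nodes
oracle_node_clustering <- function(w) {
  n <- nrow(w)
  wh <- w / max(w)
  sapply(seq_len(n), function(u) {
    nb <- which(w[u, ] > 0)
    d <- length(nb)
    if (d < 2) return(0)
    s <- 0
    for (v in nb) for (x in nb) if (v != x)
      s <- s + (wh[u, v] * wh[u, x] * wh[v, x])^(1 / 3)
    s / (d * (d - 1))
  })
}

# all-pairs shortest paths by Floyd-Warshall on lengths 1/w
oracle_path_length <- function(w) {
  n <- nrow(w)
  d <- matrix(Inf, n, n)
  d[w > 0] <- 1 / w[w > 0]
  diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  off <- d[row(d) != col(d)]
  mean(off[is.finite(off)])
}

# random symmetric nonnegative weight matrix with connected support
random_weight_matrix <- function(n, p_edge = 0.7) {
  repeat {
    w <- matrix(0, n, n)
    iu <- which(upper.tri(w))
    on <- stats::runif(length(iu)) < p_edge
    w[iu[on]] <- stats::runif(sum(on), 0.05, 1)
    w <- w + t(w)
    g <- igraph::graph_from_adjacency_matrix(w > 0, mode = "undirected")
    if (igraph::is_connected(g) && any(w > 0)) return(w)
  }
}

# tiny study design for fast tests that do not need long recordings
tiny_design <- function(n_per_cell = 1, duration = 40, seed = 1, ...) {
  study_design(n_per_cell = n_per_cell, duration = duration, seed = seed, ...)
}

# amplitude of the central half of a filtered sinusoid
central_amplitude <- function(y) {
  n <- length(y)
  max(abs(y[floor(n / 4):floor(3 * n / 4)]))
}
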