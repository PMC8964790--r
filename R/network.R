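#' Pearson functional-connectivity network over ROIs
#'
#' Correlates every pair of ROI time series. The signed correlation matrix
#' `r` is kept for feature extraction; graph analysis uses the nonnegative
#' weight matrix `w = |r|` with a zero diagonal.
#'
#' @param series A [band_roi_series()].
#' @return A `connectivity_network` object: list with `r`, `w`,
#'   `roi_order`, `species`, `band`.
#' @export
fc_matrix <- function(series) {
  stopifnot(inherits(series, "band_roi_series"))
  y <- series$y
  if (nrow(y) < 3) stop("need at least 3 time points for correlation")
  sds <- apply(y, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance ROI column(s): ",
         paste(colnames(y)[sds == 0], collapse = ", "))
  r <- stats::cor(y)
  w <- abs(r)
  diag(w) <- 0
  structure(list(r = r, w = w, roi_order = colnames(y),
                 species = series$species, band = series$band),
            class = "connectivity_network")
}

#' @export
print.connectivity_network <- function(x, ...) {
  cat(sprintf("connectivity network (%s, band %s): %d ROIs, mean |r| %.3f\n",
              x$species, x$band$name, nrow(x$r),
              mean(x$w[upper.tri(x$w)])))
  invisible(x)
}

check_weight_matrix <- function(w) {
  w <- as.matrix(w)
  if (nrow(w) != ncol(w)) stop("weight matrix must be square")
  if (any(w < 0)) stop("weights must be nonnegative")
  if (any(abs(w - t(w)) > 1e-12)) stop("weight matrix must be symmetric")
  if (any(diag(w) != 0)) stop("weight-matrix diagonal must be zero")
  w
}

#' Weighted node clustering coefficient
#'
#' Geometric-mean triangle intensity around a node: with edge weights
#' normalized by the network maximum, `C_u` averages
#' `(w_uv w_uw w_vw)^(1/3)` over ordered neighbour pairs, divided by
#' `deg(u) (deg(u) - 1)`. Nodes with fewer than two neighbours get 0.
#'
#' @param w Symmetric nonnegative weight matrix with zero diagonal.
#' @param u Node index (1-based), or `NULL` for all nodes.
#' @return Clustering coefficient(s) in `[0, 1]`.
#' @export
node_clustering <- function(w, u = NULL) {
  w <- check_weight_matrix(w)
  if (max(w) == 0) stop("all-zero weight matrix: maximum weight undefined")
  wh <- (w / max(w))^(1 / 3)
  deg <- colSums(w > 0)
  num <- diag(wh %*% wh %*% wh)   # sum over ordered neighbour pairs
  cu <- ifelse(deg < 2, 0, num / (deg * pmax(deg - 1, 1)))
  names(cu) <- rownames(w)
  if (is.null(u)) cu else cu[[u]]
}

#' Network clustering coefficient
#'
#' Mean of [node_clustering()] over all nodes.
#' @inheritParams node_clustering
#' @return Scalar in `[0, 1]`.
#' @export
clustering_coefficient <- function(w) {
  mean(node_clustering(w))
}

#' Characteristic path length
#'
#' Mean shortest-path length over all ordered node pairs, with each edge's
#' length the reciprocal of its weight (Dijkstra via igraph). If the
#' positive-weight graph is disconnected, the mean is taken over reachable
#' pairs and the result carries attribute `disconnected = TRUE`.
#'
#' @inheritParams node_clustering
#' @return Scalar path length (attribute `disconnected` flags partial
#'   coverage).
#' @export
characteristic_path_length <- function(w) {
  w <- check_weight_matrix(w)
  lengths <- ifelse(w > 0, 1 / w, 0)
  g <- igraph::graph_from_adjacency_matrix(lengths, mode = "undirected",
                                           weighted = TRUE)
  d <- igraph::distances(g, algorithm = "dijkstra")
  off <- d[row(d) != col(d)]
  reachable <- is.finite(off)
  if (!any(reachable)) stop("graph has no edges")
  L <- mean(off[reachable])
  attr(L, "disconnected") <- !all(reachable)
  L
}

#' Binarize a weighted network at fixed sparsity
#'
#' Keeps the `k = round(sparsity * n(n-1)/2)` strongest edges (round half
#' up) so that every binarized network in a study has the same edge count.
#' Ties at the cutoff are broken by lexicographic `(u, v)` order for
#' determinism.
#'
#' @inheritParams node_clustering
#' @param sparsity Fraction of possible edges to keep, in `(0, 1]`.
#' @return Symmetric 0/1 adjacency matrix with exactly `k` edges.
#' @examples
#' w <- abs(stats::cor(matrix(stats::rnorm(80), 10)))
#' diag(w) <- 0
#' sum(binarize_by_sparsity(w, 0.45)) / 2  # 13 edges for n = 8
#' @export
binarize_by_sparsity <- function(w, sparsity) {
  w <- check_weight_matrix(w)
  if (sparsity <= 0 || sparsity > 1) stop("sparsity must be in (0, 1]")
  n <- nrow(w)
  npairs <- n * (n - 1) / 2
  k <- floor(sparsity * npairs + 0.5)   # round half up
  if (k == 0) stop("sparsity ", sparsity, " keeps zero edges for n = ", n)
  iu <- which(upper.tri(w), arr.ind = TRUE)
  ord <- order(-w[iu], iu[, 1], iu[, 2])
  keep <- iu[ord[seq_len(k)], , drop = FALSE]
  a <- matrix(0, n, n, dimnames = dimnames(w))
  a[keep] <- 1
  a[keep[, c(2, 1), drop = FALSE]] <- 1
  a
}

# attempt Maslov-Sneppen double-edge swaps on an edge list (rows u < v);
# returns list(edges, n_success)
double_edge_swaps <- function(edges, n, attempts) {
  adj <- matrix(FALSE, n, n)
  adj[edges] <- TRUE
  adj[edges[, c(2, 1), drop = FALSE]] <- TRUE
  m <- nrow(edges)
  success <- 0L
  for (it in seq_len(attempts)) {
    ij <- sample.int(m, 2)
    e1 <- edges[ij[1], ]
    e2 <- edges[ij[2], ]
    if (stats::runif(1) < 0.5) e2 <- rev(e2)
    a <- e1[1]; b <- e1[2]; c <- e2[1]; d <- e2[2]
    # propose (a,d), (c,b); must be simple and new
    if (length(unique(c(a, b, c, d))) < 4) next
    if (adj[a, d] || adj[c, b]) next
    adj[a, b] <- adj[b, a] <- FALSE
    adj[c, d] <- adj[d, c] <- FALSE
    adj[a, d] <- adj[d, a] <- TRUE
    adj[c, b] <- adj[b, c] <- TRUE
    edges[ij[1], ] <- sort(c(a, d))
    edges[ij[2], ] <- sort(c(c, b))
    success <- success + 1L
  }
  list(edges = edges, n_success = success)
}

#' Matched random networks
#'
#' Generates degree-matched null networks by Maslov-Sneppen
#' degree-preserving rewiring (10 x E attempted double-edge swaps per
#' replicate). In weighted mode the original weight multiset is randomly
#' permuted over the rewired edges, so node count, edge count, degree
#' sequence and weight multiset are all preserved exactly. For graphs too
#' dense or small for any swap to succeed (e.g. a complete graph) the
#' nulls reduce to weight permutation on the original topology; the result
#' then carries attribute `swap_fallback = TRUE`.
#'
#' @inheritParams node_clustering
#' @param n_random Number of replicates.
#' @param seed Integer RNG seed.
#' @param mode `"weighted"` (permute weights) or `"unweighted"` (0/1).
#' @param swap_multiplier Attempted swaps per edge. Default 10.
#' @return List of weight matrices.
#' @export
matched_random_networks <- function(w, n_random = 100, seed = 1,
                                    mode = c("weighted", "unweighted"),
                                    swap_multiplier = 10) {
  mode <- match.arg(mode)
  w <- check_weight_matrix(w)
  if (n_random < 1) stop("n_random must be >= 1")
  n <- nrow(w)
  iu <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  if (nrow(iu) == 0) stop("graph has no edges")
  wt <- w[iu]
  m <- nrow(iu)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  any_swap <- FALSE
  out <- vector("list", n_random)
  for (rep in seq_len(n_random)) {
    sw <- double_edge_swaps(iu, n, attempts = swap_multiplier * m)
    if (sw$n_success > 0) any_swap <- TRUE
    wr <- matrix(0, n, n, dimnames = dimnames(w))
    vals <- if (mode == "weighted") sample(wt) else rep(1, m)
    wr[sw$edges] <- vals
    wr[sw$edges[, c(2, 1), drop = FALSE]] <- vals
    out[[rep]] <- wr
  }
  attr(out, "swap_fallback") <- !any_swap
  out
}

#' Small-worldness against matched random networks
#'
#' Computes clustering coefficient `C` and characteristic path length `L`
#' of the network, the means `C_random`, `L_random` over `n_random`
#' matched random replicates, and the normalized ratios
#' `gamma = C / C_random`, `lambda = L / L_random`,
#' `sigma = gamma / lambda`. `sigma > 1` indicates small-world
#' organization.
#'
#' Both modes first threshold the network at the given sparsity so that
#' every analysed network has the same edge count: unweighted mode keeps a
#' 0/1 adjacency, weighted mode keeps the surviving edges' weights. The
#' thresholding matters for the null model: on the full (complete)
#' correlation graph degree-preserving rewiring cannot alter the topology
#' and weight permutation leaves both the triangle structure and the
#' path fabric statistically unchanged, so sigma degenerates to about 1
#' or below for any coupling structure; on the thresholded support the
#' matched nulls are meaningful. Pass `sparsity = NULL` in weighted mode
#' to analyse the full matrix anyway.
#'
#' @inheritParams matched_random_networks
#' @param sparsity Fraction of edges retained before analysis
#'   (default 0.45); `NULL` for no thresholding (weighted mode only).
#' @return A `network_metrics` object: list with `C`, `L`, `gamma`,
#'   `lambda`, `sigma`, `C_random`, `L_random`, `mode`, `n_random`,
#'   `seed`, `disconnected`.
#' @export
small_worldness <- function(w, n_random = 100, seed = 1,
                            mode = c("weighted", "unweighted"),
                            sparsity = 0.45, swap_multiplier = 10) {
  mode <- match.arg(mode)
  if (inherits(w, "connectivity_network")) w <- w$w
  w <- check_weight_matrix(w)
  if (mode == "unweighted") {
    if (is.null(sparsity)) stop("unweighted mode requires a sparsity")
    w <- binarize_by_sparsity(w, sparsity)
  } else if (!is.null(sparsity)) {
    w <- w * binarize_by_sparsity(w, sparsity)
  }
  C_real <- clustering_coefficient(w)
  L_real <- characteristic_path_length(w)
  nulls <- matched_random_networks(w, n_random, seed, mode, swap_multiplier)
  Cr <- vapply(nulls, clustering_coefficient, 0)
  Lr <- vapply(nulls, function(x) as.numeric(characteristic_path_length(x)), 0)
  C_random <- mean(Cr)
  L_random <- mean(Lr)
  if (C_random == 0) stop("degenerate null model: C_random = 0")
  gamma <- C_real / C_random
  lambda <- as.numeric(L_real) / L_random
  structure(list(C = C_real, L = as.numeric(L_real), gamma = gamma,
                 lambda = lambda, sigma = gamma / lambda,
                 C_random = C_random, L_random = L_random,
                 mode = mode, n_random = n_random, seed = seed,
                 disconnected = isTRUE(attr(L_real, "disconnected")),
                 swap_fallback = isTRUE(attr(nulls, "swap_fallback"))),
            class = "network_metrics")
}

#' @export
print.network_metrics <- function(x, ...) {
  cat(sprintf("%s network metrics: C %.4f  L %.4f  gamma %.3f  lambda %.3f  sigma %.3f (%d nulls)\n",
              x$mode, x$C, x$L, x$gamma, x$lambda, x$sigma, x$n_random))
  invisible(x)
}

#' Mean within-hemisphere connectivity strength
#'
#' Averages edge weights over unordered ROI pairs lying entirely in the
#' left and in the right hemisphere; medial ROIs are excluded.
#'
#' @param net A `connectivity_network` (or weight matrix with ROI
#'   dimnames).
#' @param montage A [montage()] with a hemisphere map.
#' @return Named numeric vector `c(left = ..., right = ...)`.
#' @export
hemisphere_means <- function(net, montage = default_montage()) {
  w <- if (inherits(net, "connectivity_network")) net$w else check_weight_matrix(net)
  rois <- rownames(w)
  if (is.null(rois)) rois <- montage$roi_order
  res <- vapply(c("left", "right"), function(h) {
    members <- rois[montage$hemisphere[rois] == h]
    if (length(members) < 2)
      stop("hemisphere '", h, "' has fewer than 2 ROIs")
    idx <- match(members, rois)
    sub <- w[idx, idx, drop = FALSE]
    mean(sub[upper.tri(sub)])
  }, 0)
  names(res) <- c("left", "right")
  res
}
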