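mk_series <- function(y) {
  band_roi_series(y, "HbO", default_bands()$III, 16)
}

test_that("connectivity matrices hold signed r and absolute weights", {
  t <- 1:100
  y <- cbind(a = t + rnorm(100), b = 0, c = 0)
  y[, "b"] <- 2 * y[, "a"]        # perfect positive
  y[, "c"] <- -y[, "a"]           # perfect negative
  net <- fc_matrix(mk_series(y))
  expect_equal(net$r["a", "b"], 1)
  expect_equal(net$r["a", "c"], -1)
  expect_equal(net$w["a", "c"], 1)         # |r| mapping
  expect_equal(diag(net$w), c(a = 0, b = 0, c = 0))

  y2 <- cbind(x = c(1, 2, 3), y = c(1, 3, 2))
  expect_equal(fc_matrix(mk_series(y2))$r["x", "y"], 0.5)

  expect_error(fc_matrix(mk_series(cbind(u = c(1, 2, 3), v = c(5, 5, 5)))),
               "zero-variance.*v")
})

test_that("node clustering matches hand-evaluated triangles", {
  tri <- matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3, 3)
  expect_equal(node_clustering(tri), c(1, 1, 1), ignore_attr = TRUE)

  tri2 <- matrix(c(0, 1, 1, 1, 0, 0.5, 1, 0.5, 0), 3, 3)
  expect_equal(node_clustering(tri2, 1), 0.5^(1 / 3), tolerance = 1e-12)

  star <- matrix(0, 4, 4)
  star[1, 2:4] <- star[2:4, 1] <- 1
  expect_equal(node_clustering(star, 1), 0)
  expect_error(node_clustering(matrix(0, 3, 3)), "all-zero")
})

test_that("clustering and path length match brute-force oracles", {
  set.seed(99)
  for (i in 1:200) {
    n <- sample(5:8, 1)
    w <- random_weight_matrix(n)
    expect_equal(clustering_coefficient(w), mean(oracle_node_clustering(w)),
                 tolerance = 1e-12)
    expect_equal(as.numeric(characteristic_path_length(w)),
                 oracle_path_length(w), tolerance = 1e-12)
  }
})

test_that("path length handles hand-checked and disconnected graphs", {
  w <- matrix(0.5, 4, 4); diag(w) <- 0
  expect_equal(as.numeric(characteristic_path_length(w)), 2)

  chain <- matrix(0, 3, 3)
  chain[1, 2] <- chain[2, 1] <- chain[2, 3] <- chain[3, 2] <- 1
  expect_equal(as.numeric(characteristic_path_length(chain)), 4 / 3)

  disc <- matrix(0, 4, 4)
  disc[1, 2] <- disc[2, 1] <- disc[3, 4] <- disc[4, 3] <- 1
  L <- characteristic_path_length(disc)
  expect_true(attr(L, "disconnected"))
  expect_equal(as.numeric(L), 1)
})

test_that("scaling weights leaves C fixed and scales L reciprocally", {
  set.seed(5)
  w <- random_weight_matrix(8)
  c0 <- clustering_coefficient(w)
  L0 <- as.numeric(characteristic_path_length(w))
  for (cc in c(0.2, 3)) {
    expect_equal(clustering_coefficient(cc * w), c0, tolerance = 1e-12)
    expect_equal(as.numeric(characteristic_path_length(cc * w)), L0 / cc,
                 tolerance = 1e-12)
  }
  # sigma in weighted mode is invariant to the scale too
  s1 <- small_worldness(w, n_random = 20, seed = 3)$sigma
  s2 <- small_worldness(2.5 * w, n_random = 20, seed = 3)$sigma
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("sparsity binarization keeps exactly k strongest edges", {
  set.seed(6)
  w <- random_weight_matrix(8, p_edge = 1)
  a <- binarize_by_sparsity(w, 0.45)
  expect_equal(sum(a) / 2, 13)           # round(0.45 * 28)
  expect_true(isSymmetric(a))
  expect_equal(binarize_by_sparsity(w, 1), (w > 0) * 1, ignore_attr = TRUE)
  expect_equal(sum(binarize_by_sparsity(w, 1)) / 2, 28)
  # determinism under ties
  wt <- matrix(0.5, 6, 6); diag(wt) <- 0
  a1 <- binarize_by_sparsity(wt, 0.4)
  a2 <- binarize_by_sparsity(wt, 0.4)
  expect_identical(a1, a2)
  expect_equal(sum(a1) / 2, round(0.4 * 15))
  expect_error(binarize_by_sparsity(w, 0), "sparsity")
  expect_error(binarize_by_sparsity(matrix(0.1, 3, 3) - diag(0.1, 3), 0.05),
               "zero edges")
})

test_that("matched random networks preserve degrees and weight multiset", {
  set.seed(8)
  w <- random_weight_matrix(8, p_edge = 0.5)
  nulls <- matched_random_networks(w, n_random = 25, seed = 4)
  deg0 <- colSums(w > 0)
  wt0 <- sort(w[upper.tri(w) & w > 0])
  for (r in nulls) {
    expect_equal(colSums(r > 0), deg0)
    expect_equal(sort(r[upper.tri(r) & r > 0]), wt0, tolerance = 1e-15)
    expect_true(isSymmetric(r))
  }
  # a complete graph cannot be rewired: fallback to weight permutation
  wc <- random_weight_matrix(6, p_edge = 1)
  nc <- matched_random_networks(wc, n_random = 5, seed = 1)
  expect_true(attr(nc, "swap_fallback"))
  expect_equal(colSums(nc[[1]] > 0), colSums(wc > 0))
})

test_that("rewiring nulls break the clustering of a modular network", {
  # two dense modules joined by one bridge: strongly clustered
  w <- matrix(0, 8, 8)
  w[1:4, 1:4] <- 0.9
  w[5:8, 5:8] <- 0.9
  w[4, 5] <- w[5, 4] <- 0.3
  diag(w) <- 0
  c_real <- clustering_coefficient(w)
  drops <- sapply(1:10, function(s) {
    nulls <- matched_random_networks(w, n_random = 10, seed = s)
    mean(sapply(nulls, clustering_coefficient))
  })
  expect_true(all(drops < c_real))
})

test_that("small-worldness satisfies its definitional identity and flags", {
  set.seed(10)
  w <- abs(stats::cor(matrix(rnorm(60 * 8), 60, 8)))
  diag(w) <- 0
  m <- small_worldness(w, n_random = 30, seed = 2)
  expect_equal(m$sigma, m$gamma / m$lambda, tolerance = 1e-12)
  expect_equal(m$C / m$C_random, m$gamma, tolerance = 1e-12)
  expect_equal(m$n_random, 30)
  mu <- small_worldness(w, n_random = 30, seed = 2, mode = "unweighted")
  expect_equal(mu$sigma, mu$gamma / mu$lambda, tolerance = 1e-12)
  expect_error(small_worldness(w, mode = "unweighted", sparsity = NULL),
               "requires a sparsity")
})

test_that("a clustered ring beats its rewired nulls, a random graph does not", {
  # ring of 8 + two crossing chords, analysed as-is (no thresholding)
  ring <- matrix(0, 8, 8)
  for (i in 1:8) {
    j <- i %% 8 + 1; k <- (i + 1) %% 8 + 1
    ring[i, j] <- ring[j, i] <- 1     # ring
    ring[i, k] <- ring[k, i] <- 1     # next-nearest neighbour (clustered)
  }
  ring[1, 5] <- ring[5, 1] <- 1
  ring[3, 7] <- ring[7, 3] <- 1
  sig <- sapply(1:10, function(s)
    small_worldness(ring, n_random = 50, seed = s, sparsity = NULL)$sigma)
  expect_true(all(sig > 1))

  # an unstructured random weighted graph hovers around sigma = 1
  # (dense enough that every draw carries triangles; very sparse 8-node
  # draws can be triangle-free, where sigma is legitimately far from 1)
  set.seed(20)
  sig0 <- sapply(1:10, function(s) {
    w <- random_weight_matrix(8, p_edge = 0.7)
    small_worldness(w, n_random = 50, seed = s, sparsity = NULL)$sigma
  })
  expect_true(all(sig0 > 0.8 & sig0 < 1.2))
  expect_lt(abs(mean(sig0) - 1), 0.1)
})

test_that("hemisphere means average the three within-hemisphere pairs", {
  m <- default_montage()
  w <- matrix(0.4, 8, 8, dimnames = list(m$roi_order, m$roi_order))
  diag(w) <- 0
  expect_equal(hemisphere_means(w, m), c(left = 0.4, right = 0.4))

  set.seed(12)
  w2 <- abs(stats::cor(matrix(rnorm(50 * 8), 50, 8)))
  dimnames(w2) <- list(m$roi_order, m$roi_order)
  diag(w2) <- 0
  hm <- hemisphere_means(w2, m)
  left <- c(w2["L-PFC", "L-FEF"], w2["L-PFC", "L-PMC"], w2["L-FEF", "L-PMC"])
  right <- c(w2["R-PFC", "R-FEF"], w2["R-PFC", "R-PMC"], w2["R-FEF", "R-PMC"])
  expect_equal(hm[["left"]], mean(left))
  expect_equal(hm[["right"]], mean(right))
})
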