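test_that("hand-computed characteristic values are reproduced", {
  labs <- letters[1:4]
  Z <- matrix(0, 4, 4, dimnames = list(labs, labs))
  A <- Z; A["a", "b"] <- A["b", "a"] <- 0.5
  B <- Z
  # one edge of weight 0.5 vs empty, double-sum convention
  expect_equal(global_strength_diff(A, B), 1.0)
  # single symmetric pair differing by 0.3
  A2 <- Z; A2["a", "b"] <- A2["b", "a"] <- 0.3
  expect_equal(frobenius_distance(A2, B), sqrt(2 * 0.3^2))
  expect_equal(max_metric_distance(A2, B), 0.3)
  # N = 2 closed form for the spectral distance: spectra are +/- w
  C1 <- matrix(c(0, .7, .7, 0), 2, dimnames = list(c("x", "y"), c("x", "y")))
  C2 <- matrix(c(0, .2, .2, 0), 2, dimnames = list(c("x", "y"), c("x", "y")))
  expect_equal(spectral_distance(C1, C2), sqrt(2) * abs(0.7 - 0.2))
  # Jaccard: E_A = {ab, bc}, E_B = {ab, cd}
  A3 <- Z; A3["a", "b"] <- A3["b", "a"] <- 1; A3["b", "c"] <- A3["c", "b"] <- 1
  B3 <- Z; B3["a", "b"] <- B3["b", "a"] <- 1; B3["c", "d"] <- B3["d", "c"] <- 1
  expect_equal(jaccard_distance(A3, B3), 2 / 3)
  expect_equal(jaccard_distance(B, B), 0) # both empty: defined as 0
  expect_equal(edge_count_diff(A3, A2), 1)
  expect_equal(isolated_count_diff(B, A2), 2)
  expect_equal(degree_diff(A3, A2, "b"), 1)
  expect_equal(edge_strength_diff(A, B, "a", "b"), 0.5)
  expect_equal(edge_strength_diff(A, B, "b", "a"), 0.5)
})

test_that("every characteristic vanishes on identical networks and is symmetric", {
  set.seed(61)
  for (r in 1:20) {
    n <- sample(3:6, 1)
    A <- random_weights(n)
    B <- random_weights(n)
    expect_equal(global_strength_diff(A, A), 0)
    expect_equal(frobenius_distance(A, A), 0)
    expect_equal(max_metric_distance(A, A), 0)
    expect_equal(spectral_distance(A, A), 0)
    expect_equal(jaccard_distance(A, A), 0)
    expect_equal(edge_count_diff(A, A), 0)
    expect_equal(cluster_count_diff(A, A), 0)
    expect_equal(isolated_count_diff(A, A), 0)
    expect_equal(degree_diff(A, A, "V1"), 0)
    expect_equal(edge_strength_diff(A, A, "V1", "V2"), 0)
    # symmetry in the pair
    expect_equal(global_strength_diff(A, B), global_strength_diff(B, A))
    expect_equal(frobenius_distance(A, B), frobenius_distance(B, A))
    expect_equal(spectral_distance(A, B), spectral_distance(B, A))
    expect_equal(jaccard_distance(A, B), jaccard_distance(B, A))
    expect_equal(cluster_count_diff(A, B), cluster_count_diff(B, A))
  }
})

test_that("metric inequalities hold on random triples", {
  set.seed(71)
  for (r in 1:30) {
    n <- sample(3:6, 1)
    A <- random_weights(n)
    B <- random_weights(n)
    C <- random_weights(n)
    expect_lte(frobenius_distance(A, C),
               frobenius_distance(A, B) + frobenius_distance(B, C) + 1e-12)
    expect_lte(max_metric_distance(A, C),
               max_metric_distance(A, B) + max_metric_distance(B, C) + 1e-12)
    expect_lte(spectral_distance(A, C),
               spectral_distance(A, B) + spectral_distance(B, C) + 1e-12)
    expect_lte(max_metric_distance(A, B), frobenius_distance(A, B) + 1e-12)
  }
})

test_that("spectral distance is invariant to simultaneous node relabeling", {
  set.seed(81)
  for (r in 1:10) {
    n <- sample(4:6, 1)
    A <- random_weights(n)
    p <- sample(n)
    Ap <- A[p, p]
    dimnames(Ap) <- dimnames(A)
    expect_equal(spectral_distance(A, Ap), 0, tolerance = 1e-10)
  }
})

test_that("scaling both networks scales global strength linearly", {
  set.seed(91)
  A <- random_weights(5)
  B <- random_weights(5)
  for (c in c(0, 0.5, 2)) {
    expect_equal(global_strength_diff(c * A, c * B),
                 c * global_strength_diff(A, B), tolerance = 1e-12)
  }
})

test_that("degrees satisfy the handshake identity", {
  set.seed(92)
  for (r in 1:10) {
    A <- random_weights(6)
    degs <- vapply(colnames(A), function(v) sum(A[v, ] != 0), numeric(1))
    expect_equal(sum(degs), 2 * length(oracle_edge_set(A)))
  }
})

test_that("Girvan-Newman counts match named small graphs", {
  labs <- paste0("V", 1:6)
  two_tri <- matrix(0, 6, 6, dimnames = list(labs, labs))
  for (e in list(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6))) {
    two_tri[e[1], e[2]] <- two_tri[e[2], e[1]] <- 1
  }
  expect_equal(girvan_newman_clusters(two_tri), 2)
  k5 <- matrix(1, 5, 5) - diag(5)
  dimnames(k5) <- list(paste0("V", 1:5), paste0("V", 1:5))
  expect_equal(girvan_newman_clusters(k5), 1)
  empty <- matrix(0, 7, 7, dimnames = list(paste0("V", 1:7), paste0("V", 1:7)))
  expect_equal(girvan_newman_clusters(empty), 7)
  # two triangles vs K6: |2 - 1| = 1
  k6 <- matrix(1, 6, 6) - diag(6)
  dimnames(k6) <- list(labs, labs)
  expect_equal(cluster_count_diff(two_tri, k6), 1)
  # relabeling invariance
  p <- c(3, 1, 2, 6, 4, 5)
  perm <- two_tri[p, p]
  dimnames(perm) <- list(labs, labs)
  expect_equal(girvan_newman_clusters(perm), 2)
})

test_that("node arguments are validated", {
  A <- random_weights(4)
  expect_error(degree_diff(A, A, "nope"), "Unknown node")
  expect_error(edge_strength_diff(A, A, "V1", "V9"), "Unknown node")
  expect_error(edge_strength_diff(A, A, "V1", "V1"), "must differ")
  B <- random_weights(5)
  expect_error(frobenius_distance(A, B), "same variable labels")
})

test_that("network_difference returns the full labelled table", {
  set.seed(93)
  A <- random_weights(5)
  B <- random_weights(5)
  tab <- network_difference(A, B)
  expect_equal(nrow(tab), 8 + 5 + choose(5, 2))
  expect_equal(tab$value[tab$characteristic == "frobenius"],
               frobenius_distance(A, B))
  expect_equal(tab$value[tab$characteristic == "degree" & tab$node_i == "V2"],
               degree_diff(A, B, "V2"))
  expect_true(all(tab$value >= 0))
})
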