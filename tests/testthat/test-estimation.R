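test_that("Spearman association handles perfect monotone relations and ties", {
  set.seed(101)
  x <- rnorm(30)
  d <- tibble::tibble(a = x, b = x, c = exp(-x), d = rnorm(30))
  a <- spearman_assoc(d)
  expect_equal(a$assoc["a", "b"], 1)
  expect_equal(a$assoc["a", "c"], -1)
  expect_equal(a$pvals["a", "b"], 0)
  expect_equal(a$assoc, t(a$assoc))
  expect_equal(diag(a$assoc), rep(1, 4), ignore_attr = TRUE)
  # average ranks under ties: still symmetric and in [-1, 1]
  dt <- tibble::tibble(a = rep(1:5, each = 2), b = rnorm(10))
  at <- spearman_assoc(dt)
  expect_true(abs(at$assoc["a", "b"]) <= 1)
})

test_that("Spearman p-values are approximately uniform under independence", {
  set.seed(202)
  reps <- 400
  p <- replicate(reps, {
    d <- tibble::tibble(x = rnorm(500), y = rnorm(500))
    spearman_assoc(d)$pvals[1, 2]
  })
  ks <- stats::ks.test(p, "punif")
  expect_gt(ks$p.value, 1e-3)
})

test_that("constant variables are an error naming the variable", {
  d <- tibble::tibble(a = rnorm(10), flatline = rep(2, 10))
  expect_error(spearman_assoc(d), "flatline")
  expect_error(dcor_assoc(d), "flatline")
  expect_error(ebicglasso_network(d), "flatline")
})

test_that("p-value adjustment follows Bonferroni and BH step-up rules", {
  expect_equal(adjust_pvalues(c(0.01, 0.02), "bonferroni"), c(0.02, 0.04))
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03), "bh"), rep(0.03, 3))
  p <- runif(20)
  expect_identical(adjust_pvalues(p, "none"), p)
  expect_error(adjust_pvalues(c(0.5, 1.2), "bh"), "\\[0, 1\\]")
  # dominance: bonferroni >= bh everywhere
  set.seed(1)
  for (r in 1:20) {
    p <- runif(15)
    expect_true(all(adjust_pvalues(p, "bonferroni") >=
                      adjust_pvalues(p, "bh") - 1e-12))
  }
})

test_that("thresholding zeroes non-significant edges and keeps structure", {
  assoc <- matrix(c(1, .8, .1, .8, 1, -.5, .1, -.5, 1), 3,
                  dimnames = list(letters[1:3], letters[1:3]))
  pv <- matrix(c(NA, .001, .9, .001, NA, .2, .9, .2, NA), 3,
               dimnames = dimnames(assoc))
  net <- threshold_network(assoc, pv, alpha = 0.05, adjust = "none")
  expect_equal(net$weights["a", "b"], 0.8)
  expect_equal(net$weights["b", "c"], 0)
  expect_equal(diag(net$weights), rep(0, 3), ignore_attr = TRUE)
  # all p above alpha: empty network, every node isolated
  pv2 <- pv
  pv2[] <- 0.5
  diag(pv2) <- NA
  empty <- threshold_network(assoc, pv2, alpha = 0.05, adjust = "none")
  expect_true(all(empty$weights == 0))
  expect_equal(glance(empty)$n_isolated, 3)
})

test_that("Bonferroni edge sets are nested inside BH edge sets", {
  set.seed(77)
  for (r in 1:25) {
    d <- tibble::as_tibble(as.data.frame(matrix(rnorm(40 * 5), 40)))
    a <- spearman_assoc(d)
    bon <- threshold_network(a$assoc, a$pvals, alpha = 0.3, adjust = "bonferroni")
    bh <- threshold_network(a$assoc, a$pvals, alpha = 0.3, adjust = "bh")
    expect_true(all(bh$weights[bon$weights != 0] != 0))
  }
})

test_that("Spearman networks are invariant to monotone transforms and row order", {
  set.seed(5)
  d <- tibble::as_tibble(as.data.frame(matrix(rnorm(60 * 4), 60)))
  n1 <- estimate_network(d, adjust = "bh")
  d2 <- d
  d2$V2 <- exp(d2$V2)        # strictly increasing
  d2$V3 <- -1 / (1 + exp(d2$V3)) # strictly increasing
  n2 <- estimate_network(d2, adjust = "bh")
  expect_equal(n1$weights, n2$weights)
  d3 <- d[sample(nrow(d)), ]
  n3 <- estimate_network(d3, adjust = "bh")
  expect_equal(n1$weights, n3$weights)
})

test_that("all three estimators return symmetric zero-diagonal weights", {
  set.seed(9)
  d <- tibble::as_tibble(as.data.frame(matrix(rnorm(50 * 4), 50)))
  for (m in c("spearman", "dcor", "ebicglasso")) {
    net <- estimate_network(d, method = m, dcor_n_perm = 50, n_lambda = 25,
                            seed = 3)
    expect_identical(net$weights, t(net$weights))
    expect_equal(diag(net$weights), rep(0, 4), ignore_attr = TRUE)
    expect_identical(net$method, m)
  }
  expect_error(estimate_network(d, method = "mystery"))
})

test_that("distance correlation detects exact affine and quadratic dependence", {
  set.seed(11)
  x <- rnorm(100)
  expect_equal(dcor(x, 2 * x + 1), 1, tolerance = 1e-12)
  # y = x^2 with symmetric x: Spearman blind, dCor substantial
  x <- rnorm(200)
  y <- x^2
  d <- tibble::tibble(x = x, y = y)
  sp <- spearman_assoc(d)
  dc <- dcor_assoc(d, n_perm = 200, seed = 4)
  expect_lt(abs(sp$assoc["x", "y"]), 0.25)
  expect_gt(dc$assoc["x", "y"], 0.3)
  expect_lte(dc$pvals["x", "y"], 0.05)
})

test_that("dCor weights live in [0, 1] and the estimator is seed-stable", {
  set.seed(21)
  d <- tibble::as_tibble(as.data.frame(matrix(rnorm(40 * 3), 40)))
  n1 <- estimate_network(d, method = "dcor", dcor_n_perm = 50, seed = 8)
  n2 <- estimate_network(d, method = "dcor", dcor_n_perm = 50, seed = 8)
  expect_identical(n1$weights, n2$weights)
  expect_true(all(n1$assoc >= 0 & n1$assoc <= 1))
})

test_that("EBIC glasso recovers chain structure and prunes independence", {
  # chain-structured true precision, partial correlations 0.4
  N <- 6
  K <- diag(1, N)
  for (i in 1:(N - 1)) K[i, i + 1] <- K[i + 1, i] <- -0.4
  ev <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 0.05) diag(K) <- diag(K) + (0.05 - ev)
  Sig <- solve(K)
  Dm <- diag(1 / sqrt(diag(Sig)))
  ch <- chol(Dm %*% Sig %*% Dm)
  set.seed(31)
  hits <- 0
  for (r in 1:10) {
    X <- as.data.frame(matrix(rnorm(500 * N), 500) %*% ch)
    net <- ebicglasso_network(X, gamma = 0.5, n_lambda = 50)
    W <- net$weights
    hits <- hits + all(vapply(1:(N - 1), function(i) W[i, i + 1] != 0,
                              logical(1)))
  }
  expect_gte(hits, 9)
  # independent variables: empty or near-empty at gamma = 0.5
  near_empty <- 0
  for (r in 1:10) {
    X <- as.data.frame(matrix(rnorm(500 * 6), 500))
    W <- ebicglasso_network(X, gamma = 0.5, n_lambda = 50)$weights
    near_empty <- near_empty + (sum(W[upper.tri(W)] != 0) <= 1)
  }
  expect_gte(near_empty, 9)
})

test_that("EBIC-selected edge count is non-increasing in gamma", {
  set.seed(41)
  for (r in 1:5) {
    X <- as.data.frame(matrix(rnorm(120 * 5), 120))
    e0 <- sum(ebicglasso_network(X, gamma = 0, n_lambda = 40)$weights != 0)
    e5 <- sum(ebicglasso_network(X, gamma = 0.5, n_lambda = 40)$weights != 0)
    expect_lte(e5, e0)
  }
})

test_that("network tidiers expose edges, summaries and plots", {
  set.seed(51)
  d <- simulate_planted(edges = tibble::tibble(var_i = "Bil", var_j = "CRP"),
                        delta = 0.6, n = 150, seed = 2)
  net <- estimate_network(dplyr::filter(d, group == "B"))
  ed <- tidy(net)
  expect_named(ed, c("var_i", "var_j", "weight", "p", "p_adj"))
  expect_equal(nrow(ed), choose(9, 2))
  g <- glance(net)
  expect_equal(g$n_edges, sum(ed$weight != 0))
  expect_s3_class(autoplot(net), "ggplot")
})
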