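# Fixtures and independent brute-force oracles used across the suite.

# Random symmetric zero-diagonal weight matrix.
random_weights <- function(n, p_edge = 0.4, labels = paste0("V", seq_len(n))) {
  W <- matrix(0, n, n)
  ut <- upper.tri(W)
  w <- ifelse(stats::runif(sum(ut)) < p_edge,
              round(stats::runif(sum(ut), -1, 1), 3), 0)
  W[ut] <- w
  W <- W + t(W)
  dimnames(W) <- list(labels, labels)
  W
}

# Two-group sample tibble from iid normals.
random_two_group <- function(n_a, n_b, n_vars) {
  va <- paste0("V", seq_len(n_vars))
  a <- as.data.frame(matrix(stats::rnorm(n_a * n_vars), n_a))
  b <- as.data.frame(matrix(stats::rnorm(n_b * n_vars), n_b))
  names(a) <- va
  names(b) <- va
  dplyr::bind_rows(
    dplyr::bind_cols(tibble::tibble(group = "A"), a),
    dplyr::bind_cols(tibble::tibble(group = "B"), b)
  )
}

# Paired two-condition tibble (same subjects under two conditions).
random_paired <- function(n_pairs, n_vars) {
  va <- paste0("V", seq_len(n_vars))
  mk <- function(g) {
    x <- as.data.frame(matrix(stats::rnorm(n_pairs * n_vars), n_pairs))
    names(x) <- va
    dplyr::bind_cols(tibble::tibble(group = g,
                                    pair_key = as.character(seq_len(n_pairs))),
                     x)
  }
  dplyr::bind_rows(mk("A"), mk("B"))
}

# ---- brute-force characteristic oracles (explicit loops / enumerations) --

oracle_global_strength <- function(A, B) {
  s <- 0
  for (i in seq_len(nrow(A))) for (j in seq_len(ncol(A))) {
    s <- s + abs(A[i, j]) - abs(B[i, j])
  }
  abs(s)
}

oracle_frobenius <- function(A, B) {
  s <- 0
  for (i in seq_len(nrow(A))) for (j in seq_len(ncol(A))) {
    s <- s + abs(A[i, j] - B[i, j])^2
  }
  sqrt(s)
}

oracle_max_metric <- function(A, B) {
  m <- 0
  for (i in seq_len(nrow(A))) for (j in seq_len(ncol(A))) {
    m <- max(m, abs(A[i, j] - B[i, j]))
  }
  m
}

oracle_edge_set <- function(W) {
  out <- character()
  n <- ncol(W)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (W[i, j] != 0) out <- c(out, paste(i, j))
  }
  out
}

oracle_jaccard <- function(A, B) {
  ea <- oracle_edge_set(A)
  eb <- oracle_edge_set(B)
  uni <- union(ea, eb)
  if (!length(uni)) return(0)
  1 - length(intersect(ea, eb)) / length(uni)
}

oracle_edge_count <- function(A, B) {
  abs(length(oracle_edge_set(A)) - length(oracle_edge_set(B)))
}

oracle_isolated <- function(A, B) {
  iso <- function(W) {
    sum(vapply(seq_len(ncol(W)), function(i) all(W[i, ] == 0), logical(1)))
  }
  abs(iso(A) - iso(B))
}

oracle_degree <- function(A, B, i) {
  deg <- function(W) sum(W[i, ] != 0)
  abs(deg(A) - deg(B))
}

# Spectral distance via the general (non-symmetric-path) eigen solver.
oracle_spectral <- function(A, B) {
  la <- sort(Re(eigen(A, only.values = TRUE)$values), decreasing = TRUE)
  lb <- sort(Re(eigen(B, only.values = TRUE)$values), decreasing = TRUE)
  sqrt(sum((la - lb)^2))
}

# Divisive Girvan-Newman hierarchy explored step by step: returns the
# maximal modularity over the hierarchy and every community count that
# attains it (ties are genuine when several cuts share the maximum).
oracle_gn <- function(W) {
  n <- ncol(W)
  idx <- which(W != 0 & upper.tri(W), arr.ind = TRUE)
  if (nrow(idx) == 0) return(list(best_mod = 0, best_ks = n))
  g0 <- igraph::graph_from_edgelist(idx, directed = FALSE)
  if (igraph::vcount(g0) < n) {
    g0 <- igraph::add_vertices(g0, n - igraph::vcount(g0))
  }
  g <- g0
  mods <- numeric()
  ks <- integer()
  repeat {
    memb <- igraph::components(g)$membership
    mods <- c(mods, igraph::modularity(g0, memb))
    ks <- c(ks, max(memb))
    if (igraph::ecount(g) == 0) break
    g <- igraph::delete_edges(g, which.max(igraph::edge_betweenness(g)))
  }
  best <- max(mods)
  list(best_mod = best, best_ks = unique(ks[mods >= best - 1e-12]))
}

# Modularity of the partition the package's community count corresponds to
# is recovered by re-running the package's own clustering; used to check
# that the chosen cut attains the hierarchy maximum.
pkg_gn_modularity <- function(W) {
  n <- ncol(W)
  idx <- which(W != 0 & upper.tri(W), arr.ind = TRUE)
  if (nrow(idx) == 0) return(0)
  g <- igraph::graph_from_edgelist(idx, directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  cl <- igraph::cluster_edge_betweenness(g, weights = NULL)
  igraph::modularity(g, igraph::membership(cl))
}
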