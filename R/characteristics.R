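# The ten network difference characteristics.  Sums over the adjacency
# matrix run over the full N x N matrix, so each unordered pair is counted
# twice; permutation p-values are invariant to this factor but the statistic
# values follow the printed formulas.

#' Overall characteristic identifiers
#' @format Character vector of the eight overall characteristic ids, in the
#'   canonical reporting order.
#' @export
overall_characteristics <- c("global_strength", "frobenius", "max_metric",
                             "spectral", "jaccard", "n_edges", "n_clusters",
                             "n_isolated")

#' Difference in global strength between two networks
#'
#' `G(A, B) = | sum_{i,j} (|a_ij| - |b_ij|) |` over the full matrix.
#'
#' @param A,B Networks ([new_network()] objects or symmetric matrices) on
#'   the same node set.
#' @return A non-negative scalar.
#' @export
global_strength_diff <- function(A, B) {
  A <- as_weights(A, "A"); B <- as_weights(B, "B")
  check_same_nodes(A, B)
  abs(sum(abs(A)) - sum(abs(B)))
}

#' Frobenius distance between two networks
#'
#' `F(A, B) = sqrt(sum_{i,j} |a_ij - b_ij|^2)` over the full matrix.
#'
#' @inheritParams global_strength_diff
#' @return A non-negative scalar.
#' @export
frobenius_distance <- function(A, B) {
  A <- as_weights(A, "A"); B <- as_weights(B, "B")
  check_same_nodes(A, B)
  sqrt(sum((A - B)^2))
}

#' Maximum-metric distance between two networks
#'
#' `M(A, B) = max_{i,j} |a_ij - b_ij|`.
#'
#' @inheritParams global_strength_diff
#' @return A non-negative scalar.
#' @export
max_metric_distance <- function(A, B) {
  A <- as_weights(A, "A"); B <- as_weights(B, "B")
  check_same_nodes(A, B)
  max(abs(A - B))
}

#' Spectral distance between two networks
#'
#' Euclidean distance between the descending-sorted eigenvalue vectors of
#' the two weighted adjacency matrices.
#'
#' @inheritParams global_strength_diff
#' @return A non-negative scalar.
#' @export
spectral_distance <- function(A, B) {
  A <- as_weights(A, "A"); B <- as_weights(B, "B")
  check_same_nodes(A, B)
  la <- sort(eigen(A, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  lb <- sort(eigen(B, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  sqrt(sum((la - lb)^2))
}

#' Jaccard distance between the edge sets of two networks
#'
#' `J(A, B) = 1 - |E_A intersect E_B| / |E_A union E_B|`, where an edge is
#' present iff its weight is nonzero.  When both networks are empty the
#' printed formula is 0/0; the two networks are then identical and `J` is
#' defined as 0.
#'
#' @inheritParams global_strength_diff
#' @return A scalar in `[0, 1]`.
#' @export
jaccard_distance <- function(A, B) {
  A <- as_weights(A, "A"); B <- as_weights(B, "B")
  check_same_nodes(A, B)
  ut <- upper.tri(A)
  ea <- A[ut] != 0
  eb <- B[ut] != 0
  uni <- sum(ea | eb)
  if (uni == 0) return(0)
  1 - sum(ea & eb) / uni
}

#' Difference in the number of edges between two networks
#'
#' Edges are unordered node pairs with nonzero weight.
#'
#' @inheritParams global_strength_diff
#' @return A non-negative integer.
#' @export
edge_count_diff <- function(A, B) {
  A <- as_weights(A, "A"); B <- as_weights(B, "B")
  check_same_nodes(A, B)
  abs(sum(A[upper.tri(A)] != 0) - sum(B[upper.tri(B)] != 0))
}

#' Number of Girvan-Newman communities of one network
#'
#' Runs divisive edge-betweenness community detection on the binarized
#' topology (edge present/absent) and cuts the divisive hierarchy at the
#' maximum-modularity partition.  Isolated nodes count as singleton
#' communities, so the empty graph on `N` nodes has `N` communities.
#'
#' @param A A network ([new_network()] object or symmetric matrix).
#' @return A positive integer.
#' @export
girvan_newman_clusters <- function(A) {
  W <- as_weights(A, "A")
  gn_count_mat(W)
}

gn_count_mat <- function(W) {
  idx <- which(W != 0 & upper.tri(W), arr.ind = TRUE)
  n <- ncol(W)
  if (nrow(idx) == 0) return(n)
  g <- igraph::graph_from_edgelist(idx, directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  cl <- igraph::cluster_edge_betweenness(g, weights = NULL)
  length(unique(igraph::membership(cl)))
}

#' Difference in the number of Girvan-Newman communities
#'
#' @inheritParams global_strength_diff
#' @return A non-negative integer.
#' @export
cluster_count_diff <- function(A, B) {
  A <- as_weights(A, "A"); B <- as_weights(B, "B")
  check_same_nodes(A, B)
  abs(gn_count_mat(A) - gn_count_mat(B))
}

#' Difference in the number of isolated nodes
#'
#' An isolated node has no incident edges (all weights zero).
#'
#' @inheritParams global_strength_diff
#' @return A non-negative integer.
#' @export
isolated_count_diff <- function(A, B) {
  A <- as_weights(A, "A"); B <- as_weights(B, "B")
  check_same_nodes(A, B)
  abs(sum(rowSums(A != 0) == 0) - sum(rowSums(B != 0) == 0))
}

#' Difference in the degree of one node
#'
#' Degree is the unweighted number of edges incident to the node.
#'
#' @inheritParams global_strength_diff
#' @param node Variable label of the node.
#' @return A non-negative integer.
#' @export
degree_diff <- function(A, B, node) {
  A <- as_weights(A, "A"); B <- as_weights(B, "B")
  check_same_nodes(A, B)
  i <- match(node, colnames(A))
  if (is.na(i)) abort(paste0("Unknown node: ", node))
  abs(sum(A[i, ] != 0) - sum(B[i, ] != 0))
}

#' Difference in the edge strength between two specific nodes
#'
#' `E_ij(A, B) = |a_ij - b_ij|`; symmetric in the order of `node_i`, `node_j`.
#'
#' @inheritParams global_strength_diff
#' @param node_i,node_j Variable labels of the two nodes.
#' @return A non-negative scalar.
#' @export
edge_strength_diff <- function(A, B, node_i, node_j) {
  A <- as_weights(A, "A"); B <- as_weights(B, "B")
  check_same_nodes(A, B)
  i <- match(node_i, colnames(A))
  j <- match(node_j, colnames(A))
  if (is.na(i) || is.na(j)) {
    abort(paste0("Unknown node(s): ",
                 paste(c(node_i, node_j)[is.na(c(i, j))], collapse = ", ")))
  }
  if (i == j) abort("`node_i` and `node_j` must differ.")
  abs(A[i, j] - B[i, j])
}

#' All difference characteristics of a network pair, as a tibble
#'
#' Computes the eight overall characteristics plus the per-node degree
#' differences and per-pair edge-strength differences.
#'
#' @inheritParams global_strength_diff
#' @param characteristics Characteristic ids to include; `"all"` expands to
#'   the eight overall ids plus `"degree"` (all nodes) and
#'   `"edge_strength"` (all pairs).
#' @return A tibble with columns `characteristic`, `node_i`, `node_j`,
#'   `value`.
#' @export
network_difference <- function(A, B, characteristics = "all") {
  A <- as_weights(A, "A"); B <- as_weights(B, "B")
  check_same_nodes(A, B)
  plan <- characteristic_plan(characteristics, colnames(A))
  vals <- make_stat_fun(plan, colnames(A))(A, B)
  tibble(characteristic = plan$characteristic,
         node_i = plan$node_i, node_j = plan$node_j,
         value = as.numeric(vals))
}

# Expand a characteristic request into one row per reported statistic.
characteristic_plan <- function(characteristics, var_labels) {
  valid <- c(overall_characteristics, "degree", "edge_strength")
  if (identical(characteristics, "all")) characteristics <- valid
  bad <- setdiff(characteristics, valid)
  if (length(bad)) {
    abort(paste0("Unknown characteristic(s): ", paste(bad, collapse = ", ")))
  }
  rows <- list()
  for (ch in characteristics) {
    if (ch == "degree") {
      rows[[ch]] <- tibble(characteristic = "degree", node_i = var_labels,
                           node_j = NA_character_)
    } else if (ch == "edge_strength") {
      pr <- t(combn(var_labels, 2))
      rows[[ch]] <- tibble(characteristic = "edge_strength",
                           node_i = pr[, 1], node_j = pr[, 2])
    } else {
      rows[[ch]] <- tibble(characteristic = ch, node_i = NA_character_,
                           node_j = NA_character_)
    }
  }
  dplyr::bind_rows(rows)
}

# Build a fast evaluator for a fixed characteristic plan.  `cache` memoizes
# Girvan-Newman community counts by binary edge pattern, which repeat often
# across permutations.
make_stat_fun <- function(plan, var_labels, cache = NULL) {
  n <- length(var_labels)
  ut <- upper.tri(matrix(0, n, n))
  need <- unique(plan$characteristic)
  deg_idx <- match(plan$node_i[plan$characteristic == "degree"], var_labels)
  ei <- match(plan$node_i[plan$characteristic == "edge_strength"], var_labels)
  ej <- match(plan$node_j[plan$characteristic == "edge_strength"], var_labels)
  edge_lin <- (ej - 1) * n + ei
  if (is.null(cache) && "n_clusters" %in% need) cache <- new.env(parent = emptyenv())
  gn_cached <- function(W) {
    key <- paste0("e", paste(which(W[ut] != 0), collapse = ","))
    hit <- cache[[key]]
    if (is.null(hit)) {
      hit <- gn_count_mat(W)
      cache[[key]] <- hit
    }
    hit
  }
  function(A, B) {
    out <- numeric(nrow(plan))
    pos <- 1L
    D <- A - B
    ea <- A[ut] != 0
    eb <- B[ut] != 0
    for (ch in need) {
      k <- sum(plan$characteristic == ch)
      val <- switch(
        ch,
        global_strength = abs(sum(abs(A)) - sum(abs(B))),
        frobenius = sqrt(sum(D^2)),
        max_metric = max(abs(D)),
        spectral = {
          la <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
          lb <- eigen(B, symmetric = TRUE, only.values = TRUE)$values
          sqrt(sum((la - lb)^2))
        },
        jaccard = {
          uni <- sum(ea | eb)
          if (uni == 0) 0 else 1 - sum(ea & eb) / uni
        },
        n_edges = abs(sum(ea) - sum(eb)),
        n_clusters = abs(gn_cached(A) - gn_cached(B)),
        n_isolated = abs(sum(rowSums(A != 0) == 0) - sum(rowSums(B != 0) == 0)),
        degree = abs(rowSums(A != 0)[deg_idx] - rowSums(B != 0)[deg_idx]),
        edge_strength = abs(D[edge_lin])
      )
      out[pos:(pos + k - 1)] <- val
      pos <- pos + k
    }
    out
  }
}
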