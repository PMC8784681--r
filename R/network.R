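#' Construct a weighted network object
#'
#' A `dnet_network` wraps a symmetric, zero-diagonal weighted adjacency
#' matrix together with the estimation metadata.  A weight of exactly zero
#' encodes "no edge".
#'
#' @param weights Symmetric numeric matrix with zero diagonal.
#' @param var_labels Node labels (defaults to the matrix dimnames).
#' @param method Estimator tag, e.g. `"spearman"`.
#' @param params List of estimator settings used.
#' @param assoc,pvals,pvals_adj Optional matrices of raw associations,
#'   p-values and adjusted p-values retained for reporting.
#' @param n_samples Number of samples the network was estimated from.
#' @return An object of class `dnet_network`.
#' @export
new_network <- function(weights, var_labels = NULL, method = "manual",
                        params = list(), assoc = NULL, pvals = NULL,
                        pvals_adj = NULL, n_samples = NULL) {
  weights <- as.matrix(weights)
  n <- ncol(weights)
  if (nrow(weights) != n) abort("`weights` must be square.")
  if (max(abs(weights - t(weights))) > 1e-8) {
    abort("`weights` must be symmetric.")
  }
  weights <- (weights + t(weights)) / 2
  if (any(diag(weights) != 0)) abort("`weights` must have a zero diagonal.")
  var_labels <- var_labels %||% colnames(weights) %||% paste0("V", seq_len(n))
  if (length(var_labels) != n || anyDuplicated(var_labels)) {
    abort("`var_labels` must be unique and match the matrix dimension.")
  }
  dimnames(weights) <- list(var_labels, var_labels)
  structure(
    list(weights = weights, var_labels = var_labels, method = method,
         params = params, assoc = assoc, pvals = pvals,
         pvals_adj = pvals_adj, n_samples = n_samples),
    class = "dnet_network"
  )
}

# Accept a dnet_network or a bare symmetric matrix.
as_weights <- function(x, arg = "network") {
  if (inherits(x, "dnet_network")) return(x$weights)
  if (is.matrix(x) && is.numeric(x)) {
    if (nrow(x) != ncol(x) || max(abs(x - t(x))) > 1e-8) {
      abort(paste0("`", arg, "` must be a symmetric square matrix."))
    }
    w <- (x + t(x)) / 2
    diag(w) <- 0
    if (is.null(colnames(w))) {
      dimnames(w) <- list(paste0("V", seq_len(ncol(w))),
                          paste0("V", seq_len(ncol(w))))
    }
    return(w)
  }
  abort(paste0("`", arg, "` must be a dnet_network or a numeric matrix."))
}

# Check two networks live on the same node set, in the same order.
check_same_nodes <- function(A, B) {
  if (ncol(A) != ncol(B) || !identical(colnames(A), colnames(B))) {
    abort("Networks must share the same variable labels in the same order.")
  }
  invisible(NULL)
}

#' @export
print.dnet_network <- function(x, ...) {
  ne <- sum(x$weights[upper.tri(x$weights)] != 0)
  cat("<dnet_network> ", length(x$var_labels), " nodes, ", ne, " edges (",
      x$method, ")\n", sep = "")
  if (ne > 0) {
    ed <- tidy(x)
    ed <- ed[ed$weight != 0, ]
    print(as.data.frame(head(ed, 10)), row.names = FALSE)
    if (ne > 10) cat("... and", ne - 10, "more edges\n")
  }
  invisible(x)
}

#' Tidy a weighted network into a long edge table
#'
#' One row per unordered node pair, with the edge weight (zero where the
#' edge was pruned) and, when available, the raw and adjusted p-values of
#' the underlying association test.
#'
#' @param x A `dnet_network`.
#' @param ... Unused.
#' @return A tibble with columns `var_i`, `var_j`, `weight`, `p`, `p_adj`.
#' @export
tidy.dnet_network <- function(x, ...) {
  n <- length(x$var_labels)
  ut <- which(upper.tri(x$weights), arr.ind = TRUE)
  tibble(
    var_i = x$var_labels[ut[, 1]],
    var_j = x$var_labels[ut[, 2]],
    weight = x$weights[ut],
    p = if (is.null(x$pvals)) NA_real_ else x$pvals[ut],
    p_adj = if (is.null(x$pvals_adj)) NA_real_ else x$pvals_adj[ut]
  )
}

#' One-row summary of a weighted network
#'
#' @param x A `dnet_network`.
#' @param ... Unused.
#' @return A tibble with the node/edge counts, number of isolated nodes,
#'   number of Girvan-Newman communities and the global strength
#'   (sum of absolute weights over the full matrix).
#' @export
glance.dnet_network <- function(x, ...) {
  W <- x$weights
  tibble(
    method = x$method,
    n_nodes = ncol(W),
    n_edges = sum(W[upper.tri(W)] != 0),
    n_isolated = sum(rowSums(W != 0) == 0),
    n_clusters = girvan_newman_clusters(W),
    global_strength = sum(abs(W))
  )
}

#' Plot a weighted network
#'
#' Nodes are placed on a circle; edge width is proportional to the absolute
#' weight and colour encodes the sign of the association.
#'
#' @param object A `dnet_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dnet_network <- function(object, ...) {
  W <- object$weights
  n <- ncol(W)
  theta <- 2 * pi * (seq_len(n) - 1) / n
  nodes <- tibble(label = object$var_labels,
                  x = cos(theta), y = sin(theta))
  ed <- tidy(object)
  ed <- ed[ed$weight != 0, , drop = FALSE]
  p <- ggplot2::ggplot()
  if (nrow(ed) > 0) {
    ed$x <- nodes$x[match(ed$var_i, nodes$label)]
    ed$y <- nodes$y[match(ed$var_i, nodes$label)]
    ed$xend <- nodes$x[match(ed$var_j, nodes$label)]
    ed$yend <- nodes$y[match(ed$var_j, nodes$label)]
    ed$sign <- ifelse(ed$weight >= 0, "positive", "negative")
    p <- p + ggplot2::geom_segment(
      data = ed,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linewidth = abs(.data$weight),
                   colour = .data$sign)
    ) +
      ggplot2::scale_colour_manual(
        values = c(positive = "#2166ac", negative = "#b2182b"),
        name = "association") +
      ggplot2::scale_linewidth_continuous(range = c(0.3, 2), name = "|weight|")
  }
  p +
    ggplot2::geom_point(data = nodes, ggplot2::aes(.data$x, .data$y), size = 3) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(1.15 * .data$x, 1.15 * .data$y,
                                    label = .data$label)) +
    ggplot2::coord_equal(xlim = c(-1.3, 1.3), ylim = c(-1.3, 1.3)) +
    ggplot2::theme_void() +
    ggplot2::labs(title = paste0("Network (", object$method, ")"))
}
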