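#' Write a weighted network to GraphML
#'
#' Exports the network as a weighted undirected GraphML graph: vertices
#' carry the variable label as `name`, edges carry the `weight` attribute.
#' Pruned (zero-weight) pairs are not written as edges, so an empty network
#' round-trips to nodes only.
#'
#' @param network A [new_network()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(network, path) {
  if (!inherits(network, "dnet_network")) {
    abort("`network` must be a dnet_network.")
  }
  g <- igraph::graph_from_adjacency_matrix(network$weights, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read a weighted network back from GraphML
#'
#' @param path GraphML file as written by [write_network_graphml()].
#' @return A [new_network()] object with method `"graphml"`.
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  W <- as.matrix(igraph::as_adjacency_matrix(g, attr = if (igraph::ecount(g))
    "weight" else NULL, sparse = FALSE))
  labels <- igraph::vertex_attr(g, "name") %||% paste0("V", seq_len(ncol(W)))
  dimnames(W) <- list(labels, labels)
  new_network(W, var_labels = labels, method = "graphml")
}

#' Write a results table to TSV or JSON
#'
#' Writes the table with a stable column order and p-values at full double
#' precision.  When `meta` is given, a JSON sidecar `<path>.meta.json`
#' records the configuration and seed alongside the artifact.
#'
#' @param table A data frame (e.g. a tidied comparison table).
#' @param path Output file path.
#' @param format `"tsv"` or `"json"`.
#' @param meta Optional named list written to the sidecar file.
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path, format = c("tsv", "json"),
                          meta = NULL) {
  format <- match.arg(format)
  table <- as_tibble(table)
  if (format == "tsv") {
    readr::write_tsv(table, path)
  } else {
    jsonlite::write_json(table, path, dataframe = "rows", digits = NA,
                         na = "null", auto_unbox = TRUE, pretty = TRUE)
  }
  if (!is.null(meta)) {
    jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
  }
  invisible(path)
}

#' Read a results table written by [write_results()]
#'
#' @param path File path (`.tsv` or `.json`).
#' @return A tibble.
#' @export
read_results <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as_tibble(jsonlite::fromJSON(path))
  } else {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  }
}
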