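# Plain-text interchange: per-group CSV, undirected weighted edge lists,
# trait tables, and GraphML export for external network tools.

#' Write / read an undirected weighted edge list
#'
#' One row per dyad with positive weight, columns `node_i, node_j, weight`,
#' 0-based integer node ids, each undirected edge written once (`node_i <
#' node_j`). `read_edge_csv()` rebuilds the symmetric weight matrix; pass `n`
#' when isolated trailing nodes exist, otherwise the largest id defines it.
#'
#' @param w Symmetric weight matrix.
#' @param path File path.
#' @return `write_edge_csv()` returns `path` invisibly; `read_edge_csv()`
#'   returns a weight matrix.
#' @export
write_edge_csv <- function(w, path) {
  check_weight_matrix(w)
  idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  edges <- tibble(
    node_i = idx[, 1] - 1L,
    node_j = idx[, 2] - 1L,
    weight = w[idx]
  ) %>% dplyr::arrange(.data$node_i, .data$node_j)
  readr::write_csv(edges, path)
  invisible(path)
}

#' @rdname write_edge_csv
#' @param n Number of nodes; defaults to 1 + the largest id in the file.
#' @export
read_edge_csv <- function(path, n = NULL) {
  edges <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot(all(c("node_i", "node_j", "weight") %in% names(edges)))
  if (is.null(n)) n <- max(edges$node_i, edges$node_j) + 1L
  w <- matrix(0, n, n)
  i <- edges$node_i + 1L
  j <- edges$node_j + 1L
  w[cbind(i, j)] <- edges$weight
  w[cbind(j, i)] <- edges$weight
  diag(w) <- 0
  w
}

#' Read a trait table
#'
#' Columns `node_id` (0-based) and `trait`; returns the trait vector ordered
#' by node id, for use with [network_metrics()].
#'
#' @param path File path.
#' @return Numeric vector of traits.
#' @export
read_trait_csv <- function(path) {
  tr <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot(all(c("node_id", "trait") %in% names(tr)))
  tr$trait[order(tr$node_id)]
}

#' Serialize one group
#'
#' Writes the per-individual table (`node_id, x, y, a, e, eta, z, t`, 0-based
#' ids) and, when `edge_path` is given, the companion edge list.
#'
#' @param group An `ipn_group`.
#' @param path Destination CSV for the individual table.
#' @param edge_path Optional destination CSV for the edge list.
#' @return `path`, invisibly.
#' @export
write_group_csv <- function(group, path, edge_path = NULL) {
  stopifnot(inherits(group, "ipn_group"))
  ind <- group$individuals %>%
    dplyr::mutate(node_id = .data$id - 1L, .before = 1) %>%
    dplyr::select(-"id")
  readr::write_csv(ind, path)
  if (!is.null(edge_path)) write_edge_csv(group$w, edge_path)
  invisible(path)
}

#' Write a sweep table
#'
#' Long-format CSV, one row per simulated group, configuration columns first.
#' A fixed master seed makes the file byte-identical across runs.
#'
#' @param sweep An `ipn_sweep` tibble.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(sweep, path) {
  stopifnot(is.data.frame(sweep))
  readr::write_csv(sweep, path)
  invisible(path)
}

#' Export a group's network as GraphML
#'
#' Nodes carry the individual columns as attributes; edges carry the weight.
#' For inspection in external network tools.
#'
#' @param group An `ipn_group`.
#' @param path Destination `.graphml` file.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(group, path) {
  stopifnot(inherits(group, "ipn_group"))
  g <- igraph::graph_from_adjacency_matrix(group$w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  for (col in setdiff(names(group$individuals), "id")) {
    g <- igraph::set_vertex_attr(g, col, value = group$individuals[[col]])
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
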