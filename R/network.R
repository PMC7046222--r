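#' Contact network
#'
#' A symmetric, self-loop-free graph over `n_nodes` spheres or residues,
#' stored as an edge list. Node ids are 1-based inside R; the edge-list CSV
#' interface ([write_edges()], [read_edges()]) uses 0-based ids.
#'
#' @param n_nodes number of nodes.
#' @param edges two-column matrix (or data frame) of node pairs, 1-based.
#' @return An object of class `contact_network` with elements `n_nodes` and
#'   `edges` (a two-column integer matrix with `i < j`, duplicates removed).
#' @export
contact_network <- function(n_nodes, edges) {
  n_nodes <- as.integer(n_nodes)
  if (is.na(n_nodes) || n_nodes < 1L) stop("'n_nodes' must be >= 1")
  edges <- as.matrix(edges)
  if (length(edges) == 0L) {
    edges <- matrix(integer(0), 0L, 2L)
  }
  if (ncol(edges) != 2L) stop("'edges' must have two columns")
  storage.mode(edges) <- "integer"
  if (nrow(edges) > 0L) {
    if (any(is.na(edges)) || any(edges < 1L) || any(edges > n_nodes))
      stop("edge endpoints must be node ids in 1..n_nodes")
    if (any(edges[, 1] == edges[, 2])) stop("self-loops are not allowed")
    edges <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    edges <- unique(edges)
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  }
  dimnames(edges) <- NULL
  structure(list(n_nodes = n_nodes, edges = edges), class = "contact_network")
}

#' @export
print.contact_network <- function(x, ...) {
  cat("Contact network:", x$n_nodes, "nodes,", nrow(x$edges), "edges\n")
  cat("  mean degree:", format(average_degree(x), digits = 4), "\n")
  invisible(x)
}

#' Number of edges
#' @param net a [contact_network()].
#' @return Integer edge count.
#' @export
n_edges <- function(net) {
  stopifnot(inherits(net, "contact_network"))
  nrow(net$edges)
}

#' Adjacency matrix of a contact network
#' @param net a [contact_network()].
#' @return Dense symmetric 0/1 matrix with zero diagonal.
#' @export
adjacency_matrix <- function(net) {
  stopifnot(inherits(net, "contact_network"))
  A <- matrix(0, net$n_nodes, net$n_nodes)
  if (nrow(net$edges) > 0L) {
    A[net$edges] <- 1
    A[net$edges[, 2:1, drop = FALSE]] <- 1
  }
  A
}

#' @export
as_igraph <- function(net) UseMethod("as_igraph")

#' Convert to an igraph graph
#' @param net a [contact_network()].
#' @return An undirected [igraph::graph] on the same node set.
#' @export
as_igraph.contact_network <- function(net) {
  g <- igraph::make_empty_graph(net$n_nodes, directed = FALSE)
  if (nrow(net$edges) > 0L) g <- igraph::add_edges(g, t(net$edges))
  g
}

#' Node degrees
#' @param net a [contact_network()].
#' @return Integer vector of node degrees.
#' @export
node_degrees <- function(net) {
  stopifnot(inherits(net, "contact_network"))
  tabulate(net$edges, nbins = net$n_nodes)
}

#' Write / read a contact network as an edge-list CSV
#'
#' Two integer columns with header `i,j` and 0-based node ids. `read_edges`
#' needs `n_nodes` when isolated trailing nodes exist (defaults to the
#' largest id + 1).
#'
#' @param net a [contact_network()].
#' @param file path to a CSV file.
#' @param n_nodes number of nodes (for `read_edges`).
#' @return `write_edges` returns `file` invisibly; `read_edges` a
#'   [contact_network()].
#' @export
write_edges <- function(net, file) {
  stopifnot(inherits(net, "contact_network"))
  df <- data.frame(i = net$edges[, 1] - 1L, j = net$edges[, 2] - 1L)
  write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_edges
#' @export
read_edges <- function(file, n_nodes = NULL) {
  df <- read.csv(file)
  if (!all(c("i", "j") %in% names(df))) stop("edge CSV needs columns 'i' and 'j'")
  if (is.null(n_nodes)) n_nodes <- if (nrow(df)) max(df$i, df$j) + 1L else 1L
  contact_network(n_nodes, cbind(df$i + 1L, df$j + 1L))
}

# network from an explicit bond list of a folding run (keeps backbone edges)
network_from_bonds <- function(n_nodes, edges) contact_network(n_nodes, edges)
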