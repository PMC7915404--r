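#' @importFrom stats rnorm runif sd setNames
#' @importFrom utils read.table write.table head
NULL

#' Opinion interaction networks
#'
#' An `opinion_network` is a simple undirected graph (no self-loops, no
#' multi-edges) on nodes `1..n` that serves as the interaction substrate for
#' all simulators in the package. It caches the adjacency list and the degree
#' vector, which the simulation engine queries millions of times per run.
#'
#' @param graph An [igraph::igraph] object, or a two-column edge matrix /
#'   data frame of 1-based node indices.
#' @param n_nodes Number of nodes; required when `graph` is an edge list that
#'   may omit isolated nodes. Ignored for igraph input.
#' @return An object of class `opinion_network` with elements `n` (node
#'   count), `adj` (list of integer neighbor vectors), `deg` (integer degree
#'   vector) and `graph` (the underlying igraph object).
#' @export
as_opinion_network <- function(graph, n_nodes = NULL) {
  if (inherits(graph, "igraph")) {
    g <- igraph::simplify(igraph::as_undirected(graph, mode = "collapse"))
  } else {
    el <- as.matrix(graph)
    if (ncol(el) != 2) stop("edge list must have two columns", call. = FALSE)
    storage.mode(el) <- "integer"
    if (is.null(n_nodes)) n_nodes <- if (nrow(el)) max(el) else 0L
    if (nrow(el) && (min(el) < 1L || max(el) > n_nodes))
      stop("edge endpoints must lie in 1..n_nodes", call. = FALSE)
    g <- igraph::simplify(igraph::graph_from_edgelist(el, directed = FALSE))
    if (igraph::vcount(g) < n_nodes)
      g <- igraph::add_vertices(g, n_nodes - igraph::vcount(g))
  }
  n <- igraph::vcount(g)
  if (n == 0) stop("network must have at least one node", call. = FALSE)
  adj <- igraph::as_adj_list(g, mode = "all")
  adj <- lapply(adj, as.integer)
  structure(
    list(n = n, adj = adj, deg = lengths(adj), graph = g),
    class = "opinion_network"
  )
}

#' @export
print.opinion_network <- function(x, ...) {
  cat(sprintf(
    "<opinion_network> %d nodes, %d edges, mean degree %.2f\n",
    x$n, igraph::ecount(x$graph), average_degree(x)
  ))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Scale-free (Barabasi-Albert) network
#'
#' Grows a connected scale-free graph by preferential attachment: each new
#' node attaches to `m_attach` existing nodes with probability proportional
#' to their degree. The realized mean degree is slightly below `2 * m_attach`
#' because the first `m_attach` nodes cannot receive the full complement of
#' edges.
#'
#' @param n Number of nodes (must exceed `m_attach`).
#' @param m_attach Edges added per new node (>= 1).
#' @param seed Optional integer seed; a fixed seed reproduces the graph.
#' @return An [as_opinion_network()] object.
#' @export
make_ba_network <- function(n, m_attach, seed = NULL) {
  if (!is.numeric(n) || !is.numeric(m_attach) || m_attach < 1 || n <= m_attach)
    stop("require n > m_attach >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  as_opinion_network(igraph::sample_pa(n, m = m_attach, directed = FALSE))
}

#' Small-world (Watts-Strogatz) network
#'
#' Ring lattice on `n` nodes where each node is linked to its `k_ring`
#' nearest neighbors, with each edge rewired independently with probability
#' `p_rewire`. Rewiring preserves the edge count, so the mean degree is
#' exactly `k_ring` for any rewiring probability.
#'
#' @param n Number of nodes.
#' @param k_ring Even number of nearest neighbors in the initial lattice.
#' @param p_rewire Rewiring probability in \[0, 1\].
#' @param seed Optional integer seed.
#' @return An [as_opinion_network()] object.
#' @export
make_ws_network <- function(n, k_ring, p_rewire = 0.1, seed = NULL) {
  if (!is.numeric(k_ring) || k_ring %% 2 != 0)
    stop("k_ring must be even", call. = FALSE)
  if (k_ring >= n) stop("k_ring must be smaller than n", call. = FALSE)
  if (p_rewire < 0 || p_rewire > 1)
    stop("p_rewire must lie in [0, 1]", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  g <- igraph::sample_smallworld(1, n, k_ring / 2, p_rewire, loops = FALSE,
                                 multiple = FALSE)
  as_opinion_network(g)
}

#' Random (Erdos-Renyi) network
#'
#' Each unordered node pair is an edge independently with probability
#' `p_edge`. The graph may be disconnected; isolated nodes simply never
#' interact in the simulators.
#'
#' @param n Number of nodes.
#' @param p_edge Edge probability in \[0, 1\].
#' @param seed Optional integer seed.
#' @return An [as_opinion_network()] object.
#' @export
make_er_network <- function(n, p_edge, seed = NULL) {
  if (p_edge < 0 || p_edge > 1) stop("p_edge must lie in [0, 1]", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  as_opinion_network(igraph::sample_gnp(n, p_edge))
}

#' Embeddedness of an adjacent pair
#'
#' Normalized common-neighbor count used as a proxy for tie strength: for an
#' adjacent pair with degrees `k_i`, `k_j` and `n_ij` shared neighbors,
#' `E_ij = n_ij / ((k_i - 1) + (k_j - 1))`, the shared count over its maximum
#' possible value. When the two nodes are each other's only neighbors
#' (`k_i = k_j = 1`) the tie is maximal and `E_ij = 1`. The quantity is
#' symmetric and bounded in \[0, 1\].
#'
#' @param net An `opinion_network`.
#' @param i,j Adjacent node indices (1-based).
#' @return Embeddedness in \[0, 1\].
#' @export
embeddedness <- function(net, i, j) {
  stopifnot(inherits(net, "opinion_network"))
  if (!(j %in% net$adj[[i]]))
    stop("embeddedness is only defined for directly connected pairs",
         call. = FALSE)
  ki <- net$deg[i]; kj <- net$deg[j]
  if (ki == 1L && kj == 1L) return(1)
  sum(net$adj[[i]] %in% net$adj[[j]]) / ((ki - 1L) + (kj - 1L))
}

#' Global clustering and mean degree
#'
#' `network_clustering()` is the average of local clustering coefficients
#' (nodes with degree < 2 contribute 0); `average_degree()` is the mean
#' degree. These are the two scale statistics used to match the three network
#' families in the cross-network comparison.
#'
#' @param net An `opinion_network`.
#' @return A single number.
#' @export
network_clustering <- function(net) {
  stopifnot(inherits(net, "opinion_network"))
  igraph::transitivity(net$graph, type = "localaverage", isolates = "zero")
}

#' @rdname network_clustering
#' @export
average_degree <- function(net) {
  stopifnot(inherits(net, "opinion_network"))
  mean(net$deg)
}

#' Plain-text edge list input/output
#'
#' One edge per line as two whitespace-separated 0-based node ids; lines
#' starting with `#` are ignored. Node ids are converted to the package's
#' 1-based convention on read.
#'
#' @param path File path.
#' @param n_nodes Optional node count for graphs with trailing isolated
#'   nodes.
#' @return `read_edgelist()` returns an `opinion_network`;
#'   `write_edgelist()` invisibly returns `path`.
#' @export
read_edgelist <- function(path, n_nodes = NULL) {
  el <- read.table(path, comment.char = "#",
                   col.names = c("from", "to"),
                   colClasses = "integer")
  as_opinion_network(as.matrix(el) + 1L, n_nodes = n_nodes)
}

#' @rdname read_edgelist
#' @param net An `opinion_network` to serialize.
#' @export
write_edgelist <- function(net, path) {
  stopifnot(inherits(net, "opinion_network"))
  el <- igraph::as_edgelist(net$graph, names = FALSE) - 1L
  writeLines(
    c("# edge list: 0-based node ids, one edge per line",
      sprintf("%d %d", el[, 1], el[, 2])),
    path
  )
  invisible(path)
}
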