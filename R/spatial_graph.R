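#' Spatial graph
#'
#' An undirected, positively weighted graph whose nodes carry positions in a
#' Euclidean s-dimensional space. This is the basic container of the package:
#' filtering, crossing analysis and the growth model all operate on it.
#'
#' @param coords numeric matrix, one row per node, `s >= 1` columns of finite
#'   coordinates. Row names (if present) are used as node identifiers,
#'   otherwise nodes are named `"1", "2", ...`.
#' @param edges data frame (or matrix) with columns `from`, `to` and
#'   optionally `weight` (default 1). `from`/`to` may be node names or
#'   1-based indices. Self-loops are rejected; each unordered pair may appear
#'   at most once; weights must be strictly positive and finite.
#' @return An object of class `spatial_graph`: a list with elements
#'   `coords` (numeric matrix), `edges` (data frame with integer columns
#'   `from < to` and numeric `weight`), `node_ids` (character) and `s`
#'   (embedding dimension).
#' @examples
#' g <- spatial_graph(cbind(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1)),
#'                    data.frame(from = c(1, 2, 3), to = c(2, 3, 4)))
#' connection_density(g)
#' @export
spatial_graph <- function(coords, edges = NULL) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (nrow(coords) < 1L || ncol(coords) < 1L)
    stop("coords must have at least one node and one dimension")
  if (!all(is.finite(coords))) stop("all coordinates must be finite")
  ids <- rownames(coords)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(coords)))
  if (anyDuplicated(ids)) stop("duplicated node identifiers")
  rownames(coords) <- NULL

  if (is.null(edges)) {
    edges <- data.frame(from = integer(), to = integer(), weight = numeric())
  } else {
    edges <- as.data.frame(edges)
    if (!all(c("from", "to") %in% names(edges))) {
      if (ncol(edges) %in% 2:3)  # bare 2/3-column matrix or frame
        names(edges)[1:ncol(edges)] <- c("from", "to",
                                         "weight")[1:ncol(edges)]
      else stop("edges must have columns 'from' and 'to'")
    }
    from <- resolve_nodes(edges$from, ids)
    to <- resolve_nodes(edges$to, ids)
    w <- if ("weight" %in% names(edges)) as.numeric(edges$weight)
         else rep(1, length(from))
    if (any(!is.finite(w)) || any(w <= 0))
      stop("edge weights must be strictly positive and finite")
    if (any(from == to)) stop("self-loops are not allowed")
    lo <- pmin(from, to); hi <- pmax(from, to)
    if (anyDuplicated(cbind(lo, hi)))
      stop("duplicate edges: each unordered pair may appear at most once")
    o <- order(lo, hi)
    edges <- data.frame(from = lo[o], to = hi[o], weight = w[o])
  }
  structure(list(coords = coords, edges = edges, node_ids = ids,
                 s = ncol(coords)),
            class = "spatial_graph")
}

resolve_nodes <- function(ref, ids) {
  if (is.numeric(ref)) {
    idx <- as.integer(ref)
    if (any(is.na(idx)) || any(idx < 1L) || any(idx > length(ids)))
      stop("edge references out of range")
    return(idx)
  }
  idx <- match(as.character(ref), ids)
  if (anyNA(idx))
    stop("edges reference unknown nodes: ",
         paste(unique(ref[is.na(idx)]), collapse = ", "))
  idx
}

#' @export
print.spatial_graph <- function(x, ...) {
  cat(sprintf("<spatial_graph> N = %d nodes in %d-D, L = %d edges\n",
              n_nodes(x), x$s, n_edges(x)))
  invisible(x)
}

#' Node and edge counts
#' @param graph a [spatial_graph()]
#' @return integer count.
#' @export
n_nodes <- function(graph) nrow(graph$coords)

#' @rdname n_nodes
#' @export
n_edges <- function(graph) nrow(graph$edges)

#' Euclidean edge lengths
#'
#' @param graph a [spatial_graph()]
#' @param edges optional two-column matrix/data frame of node indices; default
#'   is the graph's own edge list.
#' @return numeric vector of Euclidean distances between edge endpoints.
#' @export
edge_lengths <- function(graph, edges = graph$edges) {
  e <- as.matrix(edges[, c("from", "to")])
  if (nrow(e) == 0) return(numeric())
  d2 <- (graph$coords[e[, 1], , drop = FALSE] -
         graph$coords[e[, 2], , drop = FALSE])^2
  sqrt(rowSums(d2))
}

#' All unordered node pairs
#'
#' The edge list of the complete graph on `n` nodes (`from < to`).
#'
#' @param n number of nodes, `>= 2`.
#' @return data frame with columns `from`, `to` (`n (n - 1) / 2` rows).
#' @export
all_pairs <- function(n) {
  if (n < 2) stop("at least 2 nodes required")
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  data.frame(from = idx[, "row"], to = idx[, "col"])
}

#' Connection density
#'
#' The fraction of realized edges, `rho = 2L / (N (N - 1))`.
#'
#' @param graph a [spatial_graph()] with at least 2 nodes.
#' @return numeric in `[0, 1]`.
#' @export
connection_density <- function(graph) {
  n <- n_nodes(graph)
  if (n < 2) stop("connection density needs at least 2 nodes")
  2 * n_edges(graph) / (n * (n - 1))
}

#' Spatial density
#'
#' Cumulative Euclidean length of a set of edges divided by the cumulative
#' length of all `N (N - 1) / 2` node pairs (the fully connected graph), so
#' the full edge set has spatial density 1. Scale-invariant.
#'
#' @param graph a [spatial_graph()] with at least 2 nodes.
#' @param edges edge subset (two-column `from`/`to`); defaults to the graph's
#'   edge list.
#' @return numeric in `[0, 1]`.
#' @export
spatial_density <- function(graph, edges = graph$edges) {
  n <- n_nodes(graph)
  if (n < 2) stop("spatial density needs at least 2 nodes")
  total <- sum(dist(graph$coords))
  if (total <= 0)
    stop("degenerate geometry: all nodes coincide, full-graph length is zero")
  sum(edge_lengths(graph, edges)) / total
}
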