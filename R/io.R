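#' Read a spatial graph from edge-list and coordinate files
#'
#' Accepts a CSV/TSV edge list (`source`, `target`, optional `weight`,
#' header required, '.' decimal) plus a coordinate table (`id`, then one
#' column per dimension, e.g. `x`, `y`, `z`), or a GraphML file whose nodes
#' carry coordinate attributes `x`, `y` (and optionally `z`). Directed or
#' duplicated pairs are symmetrized by summing weights (`A + A'`);
#' self-loops are dropped; isolated nodes (no surviving edge) are removed
#' with a message. A node referenced by an edge but missing from the
#' coordinate table, or a non-positive weight, is a hard error.
#'
#' @param edge_path path to the edge list (ignored when `graphml_path`
#'   given).
#' @param coord_path path to the coordinate table.
#' @param graphml_path path to a GraphML file (alternative input).
#' @param keep_isolated keep coordinate-table nodes without edges.
#' @return a [spatial_graph()].
#' @export
read_spatial_graph <- function(edge_path = NULL, coord_path = NULL,
                               graphml_path = NULL, keep_isolated = FALSE) {
  if (!is.null(graphml_path)) {
    ig <- igraph::read_graph(graphml_path, format = "graphml")
    va <- igraph::vertex_attr(ig)
    dims <- intersect(c("x", "y", "z"), names(va))
    if (length(dims) == 0)
      stop("GraphML nodes carry no coordinate attributes x/y/z")
    coords <- do.call(cbind, va[dims])
    ids <- if (!is.null(va$name)) as.character(va$name)
           else as.character(seq_len(nrow(coords)))
    el <- igraph::as_edgelist(ig, names = FALSE)
    w <- igraph::edge_attr(ig, "weight")
    if (is.null(w)) w <- rep(1, nrow(el))
    edges <- data.frame(source = ids[el[, 1]], target = ids[el[, 2]],
                        weight = w)
  } else {
    if (is.null(edge_path) || is.null(coord_path))
      stop("supply edge_path and coord_path, or graphml_path")
    edges <- read_table_auto(edge_path)
    names(edges)[1:2] <- c("source", "target")
    if (!"weight" %in% names(edges)) edges$weight <- 1
    ct <- read_table_auto(coord_path)
    ids <- as.character(ct[[1]])
    coords <- as.matrix(ct[, -1, drop = FALSE])
  }
  storage.mode(coords) <- "double"
  if (anyDuplicated(ids)) stop("duplicated node ids in coordinate table")
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  miss <- setdiff(unique(c(edges$source, edges$target)), ids)
  if (length(miss))
    stop("edges reference nodes without coordinates: ",
         paste(head(miss, 10), collapse = ", "))
  if (any(!is.finite(edges$weight)) || any(edges$weight <= 0))
    stop("non-positive or non-finite edge weight in input")
  from <- match(edges$source, ids); to <- match(edges$target, ids)
  loop <- from == to
  if (any(loop)) {
    message("dropping ", sum(loop), " self-loop(s)")
    from <- from[!loop]; to <- to[!loop]
    edges <- edges[!loop, , drop = FALSE]
  }
  lo <- pmin(from, to); hi <- pmax(from, to)
  agg <- aggregate(list(weight = edges$weight),
                   by = list(from = lo, to = hi), FUN = sum)
  used <- sort(unique(c(agg$from, agg$to)))
  if (!keep_isolated && length(used) < length(ids)) {
    message("removing ", length(ids) - length(used), " isolated node(s)")
    agg$from <- match(agg$from, used)
    agg$to <- match(agg$to, used)
    coords <- coords[used, , drop = FALSE]
    ids <- ids[used]
  }
  rownames(coords) <- ids
  spatial_graph(coords, agg)
}

read_table_auto <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  read.csv(path, sep = sep, stringsAsFactors = FALSE)
}

#' Write a spatial graph as edge-list and coordinate CSV files
#'
#' Round-trips with [read_spatial_graph()] (same dialect: comma separated,
#' header row, '.' decimal).
#'
#' @param graph a [spatial_graph()].
#' @param edge_path,coord_path output paths.
#' @return invisibly, the two paths.
#' @export
write_spatial_graph <- function(graph, edge_path, coord_path) {
  e <- graph$edges
  write.csv(data.frame(source = graph$node_ids[e$from],
                       target = graph$node_ids[e$to],
                       weight = e$weight),
            edge_path, row.names = FALSE, quote = FALSE)
  cn <- colnames(graph$coords)
  if (is.null(cn)) cn <- c("x", "y", "z")[seq_len(graph$s)]
  ct <- data.frame(id = graph$node_ids, graph$coords)
  names(ct) <- c("id", cn)
  write.csv(ct, coord_path, row.names = FALSE, quote = FALSE)
  invisible(c(edge_path, coord_path))
}

#' Collapse a synapse table to a backbone network
#'
#' Builds the unweighted backbone of a connectome: every chemical synapse
#' and gap junction between an unordered neuron pair collapses into a
#' single undirected edge; neuromuscular rows are excluded. Connection
#' types are matched case-insensitively; unknown types are skipped with a
#' warning or raise an error, per `unknown_type`.
#'
#' @param synapses data frame with columns `pre`, `post`, `type` (and
#'   optionally `count`, ignored: the backbone is unweighted).
#' @param synapse_types,gap_types,neuromuscular_types type labels.
#' @param unknown_type `"warn"` (skip) or `"error"`.
#' @return data frame with character columns `from`, `to` (one row per
#'   backbone edge, `from < to`).
#' @export
celegans_backbone <- function(synapses,
                              synapse_types = c("chemical", "synapse", "s",
                                                "sp"),
                              gap_types = c("gap", "gapjunction", "ej",
                                            "electrical"),
                              neuromuscular_types = c("nmj",
                                                      "neuromuscular"),
                              unknown_type = c("warn", "error")) {
  unknown_type <- match.arg(unknown_type)
  if (!all(c("pre", "post", "type") %in% names(synapses)))
    stop("synapse table needs columns pre, post, type")
  ty <- tolower(gsub("[ _-]", "", as.character(synapses$type)))
  keep <- ty %in% tolower(c(synapse_types, gap_types))
  nm <- ty %in% tolower(neuromuscular_types)
  unk <- !keep & !nm
  if (any(unk)) {
    msg <- paste("unknown connection type(s):",
                 paste(unique(synapses$type[unk]), collapse = ", "))
    if (unknown_type == "error") stop(msg) else warning(msg, "; skipped")
  }
  s <- synapses[keep, , drop = FALSE]
  a <- as.character(s$pre); b <- as.character(s$post)
  self <- a == b
  a <- a[!self]; b <- b[!self]
  lo <- pmin(a, b); hi <- pmax(a, b)
  u <- !duplicated(paste(lo, hi, sep = "\r"))
  data.frame(from = lo[u], to = hi[u], stringsAsFactors = FALSE)
}
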