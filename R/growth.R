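#' Benefit-cost attachment probability
#'
#' The local version of the benefit-cost functional: a newcomer links to an
#' existing node of normalized degree `k_hat` at normalized distance `d_hat`
#' with probability `pi = k_hat^alpha * (1 - d_hat)^beta` (convention
#' `0^0 = 1`). The first-order expansion `k_hat^alpha - k_hat^alpha beta
#' d_hat` shows the cost per length unit `c = k_hat^alpha * beta` grows with
#' the target's degree. `alpha = beta = 0` is uniform attachment;
#' `alpha = 1, beta = 0` is linear preferential attachment.
#'
#' @param k_hat normalized degree in `[0, 1]` (vectorized).
#' @param d_hat normalized distance in `[0, 1]` (vectorized).
#' @param alpha,beta non-negative exponents.
#' @return attachment probabilities in `[0, 1]`.
#' @export
attachment_probability <- function(k_hat, d_hat, alpha, beta) {
  check_unit(k_hat, "k_hat"); check_unit(d_hat, "d_hat")
  if (alpha < 0 || beta < 0) stop("alpha and beta must be non-negative")
  b <- if (alpha == 0) rep(1, length(k_hat)) else k_hat^alpha
  cc <- if (beta == 0) rep(1, length(d_hat)) else (1 - d_hat)^beta
  unname(b * cc)
}

#' Sample points uniformly from a supported spatial domain
#'
#' @param n number of points.
#' @param domain `"unit_disk"` (2-D disk of radius 1), `"unit_square"`,
#'   or `"unit_segment"` (1-D).
#' @return coordinate matrix with `n` rows.
#' @export
sample_points <- function(n, domain = c("unit_disk", "unit_square",
                                        "unit_segment")) {
  domain <- match.arg(domain)
  switch(domain,
    unit_disk = {
      th <- runif(n, 0, 2 * pi)
      r <- sqrt(runif(n))
      cbind(x = r * cos(th), y = r * sin(th))
    },
    unit_square = cbind(x = runif(n), y = runif(n)),
    unit_segment = cbind(x = runif(n)))
}

#' Grow a spatial network with fixed edges per arrival
#'
#' Iterative construction: an initial seed of `n0` fully connected nodes is
#' placed in the domain; each subsequent arrival is placed at a fresh
#' position and attached to `m` distinct existing nodes sampled without
#' replacement with probabilities proportional to
#' [attachment_probability()]. Degrees are normalized by the current maximum
#' degree and distances by the maximum pairwise distance among already
#' placed nodes (newcomer distances clipped to 1). If every candidate has
#' probability zero (e.g. `beta > 0` with all candidates at `d_hat = 1`),
#' targets are sampled uniformly so the process stays defined. The final
#' edge count is deterministic: `L = n0 (n0 - 1) / 2 + m (N - n0)`.
#'
#' @param N final number of nodes, `> n0`.
#' @param m edges attached per arrival, `<= n0`.
#' @param alpha,beta attachment exponents.
#' @param n0 seed size, `>= 2`.
#' @param domain passed to [sample_points()].
#' @param seed integer seed.
#' @return list of class `grown_network`: `graph` (a [spatial_graph()]),
#'   `arrival_index` (1-based construction order per node), `alpha`, `beta`,
#'   `m`, `n0`.
#' @export
grow_network <- function(N = 2000, m = 5, alpha = 0, beta = 0, n0 = 6,
                         domain = "unit_disk", seed = NULL) {
  if (n0 < 2) stop("seed size n0 must be at least 2")
  if (m > n0) stop("m cannot exceed the seed size n0")
  if (N <= n0) stop("N must exceed n0")
  if (!is.null(seed)) set.seed(seed)
  coords <- sample_points(N, domain)
  e <- cpp_grow_plain(coords, as.integer(n0), as.integer(m), alpha, beta)
  g <- graph_from_grown(coords, e)
  structure(list(graph = g, arrival_index = seq_len(N), alpha = alpha,
                 beta = beta, m = m, n0 = n0),
            class = "grown_network")
}

#' Accelerated hidden-variable growth
#'
#' Variant for networks whose mean degree grows during development (e.g. a
#' maturing connectome): nodes are added on a prescribed arrival schedule at
#' fixed positions, and each node's attachment attractiveness is its known
#' final ("adult-stage") degree, used as a hidden variable. When node `i`
#' arrives, every existing node `j` independently receives a link with
#' Bernoulli probability `pi_ij = k_hat_j^alpha (1 - d_hat_ij)^beta`, where
#' `k_hat_j` normalizes the hidden degree by the maximum hidden degree among
#' placed nodes and `d_hat_ij` the distance by the maximum pairwise distance
#' among placed nodes (clipped to 1). The realized edge count is a random
#' variable — the quantity targeted by the edge-count calibration stage.
#'
#' @param coords coordinate matrix, one row per node, in arrival order
#'   (reorder beforehand if the schedule differs).
#' @param hidden_degrees positive per-node hidden (final) degrees, same
#'   order.
#' @param alpha,beta attachment exponents.
#' @param seed integer seed.
#' @return a `grown_network` (see [grow_network()]); `m` and `n0` are `NA`.
#' @export
grow_accelerated <- function(coords, hidden_degrees, alpha, beta,
                             seed = NULL) {
  coords <- as.matrix(coords)
  N <- nrow(coords)
  if (length(hidden_degrees) != N)
    stop("hidden_degrees must match the number of nodes")
  if (any(!is.finite(hidden_degrees)) || any(hidden_degrees <= 0))
    stop("hidden degrees must be positive")
  if (!is.null(seed)) set.seed(seed)
  e <- cpp_grow_accelerated(coords, as.numeric(hidden_degrees), alpha, beta)
  g <- graph_from_grown(coords, e)
  structure(list(graph = g, arrival_index = seq_len(N), alpha = alpha,
                 beta = beta, m = NA, n0 = NA,
                 hidden_degrees = hidden_degrees),
            class = "grown_network")
}

#' @export
print.grown_network <- function(x, ...) {
  cat(sprintf("<grown_network> N = %d, L = %d (alpha = %.3g, beta = %.3g)\n",
              n_nodes(x$graph), n_edges(x$graph), x$alpha, x$beta))
  invisible(x)
}

# Fast internal constructor for edges produced by the growth cores: pairs
# are unique with from < to by construction, so validation is skipped.
graph_from_grown <- function(coords, e) {
  storage.mode(coords) <- "double"
  o <- order(e[, 1], e[, 2])
  edges <- data.frame(from = e[o, 1], to = e[o, 2],
                      weight = rep(1, nrow(e)))
  rownames(coords) <- NULL
  structure(list(coords = coords, edges = edges,
                 node_ids = as.character(seq_len(nrow(coords))),
                 s = ncol(coords)),
            class = "spatial_graph")
}

#' Degrees of a spatial graph
#' @param graph a [spatial_graph()]
#' @return integer degree per node.
#' @export
node_degrees <- function(graph) {
  tabulate(c(graph$edges$from, graph$edges$to), nbins = n_nodes(graph))
}

#' Pairwise-distance density for uniform points on the unit disk
#'
#' Closed-form density of the distance between two independent uniform
#' points in a disk of radius 1:
#' `f(d) = 2 d ( (2/pi) acos(d/2) - (d/pi) sqrt(1 - d^2/4) )` on `[0, 2]`.
#' Used as the theoretical reference for link-length distributions of
#' spatially unconstrained (`beta = 0`) grown networks.
#'
#' @param d distances (vectorized), in `[0, 2]`.
#' @param domain only `"unit_disk"` is supported.
#' @return density values.
#' @export
distance_density_reference <- function(d, domain = "unit_disk") {
  if (!identical(domain, "unit_disk"))
    stop("unsupported domain: ", domain)
  out <- numeric(length(d))
  ok <- d >= 0 & d <= 2
  x <- d[ok]
  out[ok] <- 2 * x * ((2 / pi) * acos(x / 2) -
                      (x / pi) * sqrt(pmax(1 - x^2 / 4, 0)))
  out[!ok] <- 0
  out
}
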