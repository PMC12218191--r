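#' Count edge crossings of a straight-line drawing
#'
#' Counts unordered pairs of edges whose open segments properly intersect in
#' a 2-D drawing with fixed node positions. Pairs sharing an endpoint never
#' count, and a vertex lying on another edge's interior (touching) is not a
#' crossing. Exactly collinear overlapping segments are degenerate and raise
#' an error — jitter the layout if that happens. Orientation tests use a
#' relative epsilon of 1e-12 to avoid misclassification near collinearity.
#'
#' Two interchangeable backends are provided: an x-sweep with an actively
#' pruned candidate list (default above 200 edges) and a plain quadratic
#' pairwise test (default below; also exposed as [count_crossings_brute()]
#' as an independent oracle). Both give identical counts by contract.
#'
#' @param coords numeric matrix with exactly 2 columns (the drawing).
#' @param edges two-column matrix/data frame of 1-based node indices (a
#'   [spatial_graph()] edge list works).
#' @param method `"auto"`, `"sweep"` or `"brute"`.
#' @return integer crossing count.
#' @export
count_crossings <- function(coords, edges,
                            method = c("auto", "sweep", "brute")) {
  method <- match.arg(method)
  coords <- as.matrix(coords)
  if (ncol(coords) != 2) stop("crossing counts require 2-D coordinates")
  e <- edge_index_matrix(edges, nrow(coords))
  if (nrow(e) < 2) return(0)
  if (method == "auto") method <- if (nrow(e) < 200) "brute" else "sweep"
  if (method == "sweep")
    cpp_count_crossings_sweep(coords[, 1], coords[, 2], e)
  else
    cpp_count_crossings_brute(coords[, 1], coords[, 2], e)
}

#' @rdname count_crossings
#' @export
count_crossings_brute <- function(coords, edges) {
  count_crossings(coords, edges, method = "brute")
}

edge_index_matrix <- function(edges, n) {
  if (is.data.frame(edges)) {
    cols <- if (all(c("from", "to") %in% names(edges))) c("from", "to")
            else 1:2
    edges <- as.matrix(edges[, cols])
  }
  e <- matrix(as.integer(edges), ncol = 2)
  if (nrow(e) && (anyNA(e) || min(e) < 1L || max(e) > n))
    stop("edge indices out of range")
  e
}

#' Maximum crossing count of a layout
#'
#' Crossings of the complete graph drawn on `coords`; the ceiling `Ec_max`
#' of the quadratic scaling law.
#'
#' @inheritParams count_crossings
#' @return integer crossing count of the complete graph.
#' @export
max_crossings <- function(coords) {
  coords <- as.matrix(coords)
  count_crossings(coords, all_pairs(nrow(coords)))
}

#' Expected crossings of a random edge subset
#'
#' For a uniformly random subset of `L` of the layout's `L_max` edges, each
#' crossing pair of the full drawing survives with probability
#' `L (L - 1) / (L_max (L_max - 1))`, so the exact expected count is
#' `Ec_max * L (L - 1) / (L_max (L_max - 1))`, which tends to the quadratic
#' density law `Ec = Ec_max * rho^2` for large graphs. This function returns
#' the large-graph form.
#'
#' @param rho connection density in `[0, 1]` (vectorized).
#' @param ec_max crossing count of the complete drawing, `>= 0`.
#' @return expected crossing count `ec_max * rho^2`.
#' @export
expected_crossings <- function(rho, ec_max) {
  check_unit(rho, "rho")
  if (ec_max < 0) stop("ec_max must be non-negative")
  ec_max * rho^2
}

#' Per-density crossing profile of a layout regime
#'
#' Reverse-engineers the mapping from the number of displayed edges to the
#' expected number of crossings: for `n_samples` jittered replicates of the
#' layout, edges are ranked under the given regime and the cumulative
#' crossing count of every ranking prefix `L = 0 .. L_max` is recorded; the
#' mean over replicates is the profile. Randomness enters through the layout
#' jitter (via `layout_fn`) and the random ranking; fixed `seed` gives a
#' deterministic profile.
#'
#' @param layout_fn function(seed) returning a 2-column coordinate matrix
#'   (e.g. [netviz_layout()]); alternatively a fixed coordinate matrix, in
#'   which case only the random regime varies across samples.
#' @param regime ranking criterion: `"random"`, `"short"` (length
#'   ascending) or `"long"` (length descending).
#' @param n_samples number of replicates to average.
#' @param seed integer seed.
#' @return list of class `crossing_profile` with `per_L_mean` (length
#'   `L_max + 1`, entry `L + 1` is the mean crossing count at `L` edges),
#'   `regime`, `n_samples` and `ec_max` (mean complete-graph count).
#' @export
crossing_profile <- function(layout_fn, regime = c("random", "short", "long"),
                             n_samples = 100, seed = 1) {
  regime <- check_regime(regime)
  fixed <- !is.function(layout_fn)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, n_samples)
  acc <- NULL
  ecm <- 0
  for (k in seq_len(n_samples)) {
    coords <- if (fixed) as.matrix(layout_fn) else layout_fn(seeds[k])
    g <- spatial_graph(coords, all_pairs(nrow(coords)))
    crit <- switch(regime, random = "random", short = "length_asc",
                   long = "length_desc")
    r <- rank_edges(g, crit, seed = seeds[k] %% .Machine$integer.max)
    cum <- cpp_crossing_increments(coords[, 1], coords[, 2],
                                   as.matrix(r$edges[, c("from", "to")]))
    if (is.null(acc)) acc <- numeric(length(cum))
    acc <- acc + cum
    ecm <- ecm + cum[length(cum)]
  }
  structure(list(per_L_mean = acc / n_samples, regime = regime,
                 n_samples = n_samples, ec_max = ecm / n_samples,
                 seed = seed),
            class = "crossing_profile")
}
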