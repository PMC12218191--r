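#' Benefit-cost functional J
#'
#' `J = rho^alpha * (1 - delta)^beta`: the benefit of connection density
#' `rho` discounted by the cumulative spatial cost `delta`. To first order in
#' `delta` this is `rho^alpha - rho^alpha * beta * delta`, i.e. a cost per
#' length unit `c = rho^alpha * beta` that grows with density — the
#' progressive-cost principle at the core of the package. The convention
#' `0^0 = 1` makes `alpha = 0` pure-cost behaviour continuous.
#'
#' @param rho connection density in `[0, 1]` (vectorized).
#' @param delta spatial density in `[0, 1]` (vectorized).
#' @param alpha benefit exponent, `>= 0`.
#' @param beta cost exponent, `>= 0`.
#' @return numeric, `J` values.
#' @export
functional_J <- function(rho, delta, alpha = 1, beta = 1) {
  check_unit(rho, "rho"); check_unit(delta, "delta")
  if (alpha < 0 || beta < 0) stop("alpha and beta must be non-negative")
  pow0 <- function(x, p) if (p == 0) rep(1, length(x)) else x^p
  unname(pow0(rho, alpha) * pow0(1 - delta, beta))
}

check_unit <- function(x, nm) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop(nm, " must lie in [0, 1]")
  invisible(x)
}

check_regime <- function(regime) {
  match.arg(regime, c("random", "short", "long"))
}

#' Expected spatial density under the three weight-length regimes
#'
#' When edge weights are uncorrelated with lengths, picking edges by weight
#' samples lengths uniformly and the expected spatial density is
#' `delta = rho`. Under perfect (anti)correlation the picked lengths are
#' order statistics, giving `delta = rho^2` (short-range: strongest edges are
#' the shortest) or `delta = 2 rho - rho^2` (long-range). The order-statistic
#' forms are exact for a uniform edge-length spectrum and first-order
#' approximations otherwise.
#'
#' @param rho connection density in `[0, 1]` (vectorized).
#' @param regime one of `"random"`, `"short"`, `"long"`.
#' @return expected `delta`, same length as `rho`.
#' @export
expected_delta <- function(rho, regime = c("random", "short", "long")) {
  regime <- check_regime(regime)
  check_unit(rho, "rho")
  switch(regime,
         random = rho,
         short = rho^2,
         long = 2 * rho - rho^2)
}

#' Closed-form optimal connection density
#'
#' The density maximizing `J = rho^alpha (1 - delta(rho))` (cost exponent
#' `beta = 1`) with `delta(rho)` replaced by its regime expectation:
#' `alpha / (alpha + 1)` (random), `sqrt(alpha / (alpha + 2))` (short) and
#' `alpha / (alpha + 2)` (long). For every `alpha > 0` the ordering
#' `rho_long <= rho_rand <= rho_short` holds; all increase to 1 with `alpha`.
#'
#' @param alpha benefit exponent `>= 0` (vectorized).
#' @param regime one of `"random"`, `"short"`, `"long"`.
#' @return optimal density `rho*` in `[0, 1]`.
#' @examples
#' optimal_density(1, "random")  # 0.5
#' @export
optimal_density <- function(alpha, regime = c("random", "short", "long")) {
  regime <- check_regime(regime)
  if (any(!is.finite(alpha)) || any(alpha < 0))
    stop("alpha must be non-negative")
  switch(regime,
         random = alpha / (alpha + 1),
         short = sqrt(alpha / (alpha + 2)),
         long = alpha / (alpha + 2))
}

#' Size scaling of the filtering parameter
#'
#' For readable drawings of large networks the filtering parameter is scaled
#' with the typical internode distance, `alpha = phi * N^(-1/s)`, with `phi`
#' a positive constant. `phi_from_alpha()` is the inverse conversion.
#'
#' @param phi positive scaling constant.
#' @param alpha filtering parameter.
#' @param N number of nodes, `>= 1`.
#' @param s embedding dimension, `>= 1`.
#' @return `alpha` (resp. `phi`).
#' @export
scaled_alpha <- function(phi, N, s) {
  if (any(phi <= 0)) stop("phi must be positive")
  if (N < 1 || s < 1) stop("N and s must be positive integers")
  phi * N^(-1 / s)
}

#' @rdname scaled_alpha
#' @export
phi_from_alpha <- function(alpha, N, s) {
  if (any(alpha < 0)) stop("alpha must be non-negative")
  alpha * N^(1 / s)
}

#' Empirical density curve of an edge ranking
#'
#' For each prefix of the ranking (length `L = 0 .. L_total`) returns the
#' connection density and the spatial density of the prefix. `delta` is
#' nondecreasing in `L`.
#'
#' @param graph a [spatial_graph()].
#' @param ranking an [rank_edges()] result for the same graph.
#' @return data frame with columns `L`, `rho`, `delta`.
#' @export
density_curve <- function(graph, ranking) {
  check_ranking(graph, ranking)
  n <- n_nodes(graph)
  len <- edge_lengths(graph, ranking$edges)
  total <- sum(dist(graph$coords))
  if (total <= 0) stop("degenerate geometry: full-graph length is zero")
  L <- 0:length(len)
  data.frame(L = L,
             rho = 2 * L / (n * (n - 1)),
             delta = c(0, cumsum(len)) / total)
}

#' Maximize J over the prefixes of an edge ranking
#'
#' Scans all prefix lengths `L = 0 .. L_total` of the ranking and returns the
#' `L` maximizing `J(rho(L), delta(L))`. Ties are broken toward the smallest
#' `L` (the sparser representation).
#'
#' @inheritParams density_curve
#' @param alpha,beta functional exponents.
#' @return list with `L_star`, `rho_star`, `J_star` and the scanned `curve`
#'   (the [density_curve()] with a `J` column).
#' @export
maximize_J <- function(graph, ranking, alpha = 1, beta = 1) {
  curve <- density_curve(graph, ranking)
  curve$J <- functional_J(curve$rho, pmin(curve$delta, 1), alpha, beta)
  i <- which.max(curve$J)  # which.max takes the first maximum: smallest L
  list(L_star = curve$L[i], rho_star = curve$rho[i], J_star = curve$J[i],
       curve = curve)
}
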