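#' Synthetic geometric graphs with controlled weight-length correlation
#'
#' Generates a spatial graph whose edge weights realize one of the three
#' canonical regimes: `"short"` (weights a strictly decreasing function of
#' length, so the strongest edges are the shortest), `"long"` (strictly
#' increasing) or `"random"` (weights independent of length). Weights are
#' rank-based (a permutation of `1 .. L` mapped through the regime), which
#' makes the correlation perfect by construction and keeps them strictly
#' positive and unique.
#'
#' @param n number of nodes.
#' @param regime weight-length regime.
#' @param density fraction of the `n (n - 1) / 2` pairs to keep as edges
#'   (edges are a uniform random subset; 1 = complete graph).
#' @param domain point domain, see [sample_points()].
#' @param seed integer seed.
#' @return a [spatial_graph()].
#' @export
synthetic_spatial_graph <- function(n, regime = c("random", "short", "long"),
                                    density = 1,
                                    domain = "unit_square", seed = NULL) {
  regime <- check_regime(regime)
  if (!is.null(seed)) set.seed(seed)
  coords <- sample_points(n, domain)
  pairs <- all_pairs(n)
  if (density < 1) {
    keep <- sort(sample.int(nrow(pairs), max(1, round(density * nrow(pairs)))))
    pairs <- pairs[keep, , drop = FALSE]
  }
  g0 <- spatial_graph(coords, pairs)
  e <- g0$edges  # canonical order; lengths and weights stay aligned
  len <- edge_lengths(g0)
  r <- rank(len, ties.method = "first")
  L <- length(len)
  e$weight <- switch(regime,
                     short = (L - r + 1) / L,  # shortest edge strongest
                     long = r / L,
                     random = sample.int(L) / L)
  spatial_graph(coords, e)
}

#' Synthetic developing-connectome fixture
#'
#' A small stand-in for a real developing neuronal network, used to exercise
#' the accelerated growth model and its calibration end to end without any
#' external data: `n` neurons on a 1-D body axis (uniform positions),
#' heavy-tailed adult-stage (hidden) degrees drawn from a truncated Pareto
#' law, a random arrival schedule, and one realized network grown at the
#' given ground-truth parameters. This emulates the ingredients of a real
#' connectome fit (positions, birth order, adult degrees) but not its
#' biology: positions are uniform, degrees are i.i.d., and arrival order is
#' independent of degree.
#'
#' @param n number of neurons.
#' @param alpha,beta ground-truth growth parameters used for the realized
#'   network (defaults: the benefit-cost exponents fitted to the adult
#'   nematode connectome, 2.51 and 0.18).
#' @param k_min,k_exponent,k_cap truncated Pareto hidden-degree parameters.
#' @param seed integer seed.
#' @return list with `coords` (in arrival order), `hidden_degrees`,
#'   `network` (a `grown_network`), `alpha`, `beta` and a `simulate`
#'   function(alpha, beta, seed) regrowing networks on the same scaffold
#'   (for calibration).
#' @export
synthetic_connectome <- function(n = 200, alpha = 2.51, beta = 0.18,
                                 k_min = 5, k_exponent = 2.5, k_cap = 40,
                                 seed = 1) {
  set.seed(seed)
  coords <- matrix(runif(n), ncol = 1)
  k <- round(k_min * runif(n)^(-1 / (k_exponent - 1)))
  k <- pmin(pmax(k, k_min), k_cap)
  simulate <- function(a, b, s)
    grow_accelerated(coords, k, alpha = a, beta = b, seed = s)
  net <- simulate(alpha, beta, seed + 1L)
  list(coords = coords, hidden_degrees = k, network = net,
       alpha = alpha, beta = beta, simulate = simulate)
}
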