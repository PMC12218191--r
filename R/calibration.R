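#' Relative edge-count error of a growth configuration
#'
#' Simulates `n_rep` networks at the given parameters, averages their edge
#' counts and returns the relative error `|<L_sim> - L| / L` against the
#' target. This is the stage-1 objective of the calibration pipeline.
#'
#' @param simulate_fn function(alpha, beta, seed) returning a
#'   `grown_network` (or any list with a `graph` element, or a
#'   [spatial_graph()]).
#' @param alpha,beta model parameters.
#' @param target_L observed edge count, `> 0`.
#' @param n_rep ensemble size.
#' @param seed integer seed; per-replicate seeds are derived from it.
#' @return non-negative relative error.
#' @export
epsilon_dif <- function(simulate_fn, alpha, beta, target_L, n_rep = 30,
                        seed = 1) {
  if (target_L <= 0) stop("target_L must be positive")
  seeds <- derive_seeds(seed, n_rep)
  Ls <- vapply(seeds, function(s) n_edges(as_graph(simulate_fn(alpha, beta, s))), 0)
  abs(mean(Ls) - target_L) / target_L
}

as_graph <- function(x) {
  if (inherits(x, "spatial_graph")) x
  else if (!is.null(x$graph)) x$graph
  else stop("simulate_fn must return a spatial_graph or a grown_network")
}

derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Stage-1 grid search on the edge-count error
#'
#' Evaluates [epsilon_dif()] on a log-spaced `(alpha, beta)` grid and
#' returns the feasible combinations (relative error below `threshold`).
#' An empty feasible set is returned with a warning, not an error.
#'
#' @inheritParams epsilon_dif
#' @param bounds length-2 positive range for both parameters (log-spaced).
#' @param n_grid grid points per axis.
#' @param threshold feasibility cut on the relative edge-count error.
#' @return list with `grid` (data frame `alpha`, `beta`, `epsilon_dif`),
#'   `feasible` (subset under threshold) and `bounds`.
#' @export
grid_search <- function(simulate_fn, target_L, bounds = c(1e-3, 1e3),
                        n_grid = 50, threshold = 0.05, n_rep = 30,
                        seed = 1) {
  if (n_grid < 2) stop("n_grid must be at least 2 per axis")
  vals <- 10^seq(log10(bounds[1]), log10(bounds[2]), length.out = n_grid)
  grid <- expand.grid(alpha = vals, beta = vals)
  seeds <- derive_seeds(seed, nrow(grid))
  grid$epsilon_dif <- vapply(seq_len(nrow(grid)), function(i)
    epsilon_dif(simulate_fn, grid$alpha[i], grid$beta[i], target_L,
                n_rep = n_rep, seed = seeds[i]), 0)
  feasible <- grid[grid$epsilon_dif < threshold, , drop = FALSE]
  if (nrow(feasible) == 0)
    warning("no parameter combination reached epsilon_dif < ", threshold)
  list(grid = grid, feasible = feasible, bounds = bounds,
       threshold = threshold)
}

#' Jensen-Shannon divergence between two histograms
#'
#' Symmetric, bounded divergence with logarithms in base 2 so values lie in
#' `[0, 1]`; 0 iff the normalized histograms coincide, 1 for disjoint
#' supports. Inputs are counts or probabilities over identical bins.
#'
#' @param p,q non-negative numeric vectors of equal length with positive
#'   sums.
#' @return JS divergence in `[0, 1]`.
#' @export
js_divergence <- function(p, q) {
  if (length(p) != length(q))
    stop("histograms must share the same binning")
  if (any(p < 0) || any(q < 0) || sum(p) <= 0 || sum(q) <= 0)
    stop("histograms must be non-negative with positive mass")
  p <- p / sum(p); q <- q / sum(q)
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log2(a[i] / b[i]))
  }
  (kl(p, m) + kl(q, m)) / 2
}

#' Histograms of a network's degree and link-length distributions
#'
#' Degrees use unit-width integer bins `0 .. k_max`; link lengths use
#' `n_dist_bins` equal-width bins over `[0, d_max]`. The same `k_max`,
#' `d_max` must be used for every histogram entering a divergence.
#'
#' @param graph a [spatial_graph()]
#' @param k_max top degree bin.
#' @param d_max top of the distance range.
#' @param n_dist_bins number of distance bins.
#' @return list with `degree` (length `k_max + 1`) and `distance`
#'   (length `n_dist_bins`) count vectors.
#' @export
network_histograms <- function(graph, k_max, d_max, n_dist_bins = 50) {
  deg <- pmin(node_degrees(graph), k_max)
  dh <- tabulate(deg + 1L, nbins = k_max + 1L)
  len <- pmin(edge_lengths(graph), d_max)
  br <- seq(0, d_max, length.out = n_dist_bins + 1)
  lh <- if (length(len))
    tabulate(pmax(1L, findInterval(len, br, rightmost.closed = TRUE)),
             nbins = n_dist_bins) else numeric(n_dist_bins)
  list(degree = dh, distance = lh)
}

#' Stage-2 distribution mismatch
#'
#' Simulates `n_rep` networks, averages their degree and link-length
#' histograms (same bins as the reference) and returns the maximum of the
#' two Jensen-Shannon divergences against the reference histograms.
#'
#' @inheritParams epsilon_dif
#' @param ref list with `degree` and `distance` reference histograms, as
#'   produced by [network_histograms()].
#' @param k_max,d_max,n_dist_bins binning, shared with the reference.
#' @return `max(JS_degree, JS_distance)` in `[0, 1]`.
#' @export
epsilon_div <- function(simulate_fn, alpha, beta, ref, k_max, d_max,
                        n_dist_bins = 50, n_rep = 100, seed = 1) {
  seeds <- derive_seeds(seed, n_rep)
  dh <- numeric(k_max + 1L); lh <- numeric(n_dist_bins)
  for (s in seeds) {
    h <- network_histograms(as_graph(simulate_fn(alpha, beta, s)),
                            k_max, d_max, n_dist_bins)
    dh <- dh + h$degree; lh <- lh + h$distance
  }
  max(js_divergence(dh, ref$degree), js_divergence(lh, ref$distance))
}

#' Global-best particle swarm optimization
#'
#' Plain global-best PSO: inertia 0.7, cognitive and social weights 1.5,
#' velocities clamped to 20% of each bound range, particles reflected at the
#' bounds. Terminates when the best objective value has not improved by more
#' than `tol` over 20 consecutive iterations, or at `max_iter`. Degenerate
#' bounds (`lower == upper`) return that point. Reproducible given `seed`.
#'
#' @param objective function of a parameter vector returning a scalar.
#' @param lower,upper bound vectors of equal length.
#' @param n_particles swarm size.
#' @param max_iter iteration cap.
#' @param tol absolute improvement defining stagnation.
#' @param init optional matrix of starting positions (one row per
#'   particle, clipped to the bounds); remaining particles are placed
#'   uniformly at random.
#' @param seed integer seed.
#' @return list with `par`, `value`, `trajectory` (best value per
#'   iteration) and `n_iter`.
#' @export
pso_optimize <- function(objective, lower, upper, n_particles = 20,
                         max_iter = 400, tol = 1e-3, init = NULL,
                         seed = 1) {
  d <- length(lower)
  if (length(upper) != d || any(upper < lower)) stop("invalid bounds")
  if (all(upper == lower)) {
    x <- lower
    return(list(par = x, value = objective(x), trajectory = numeric(),
                n_iter = 0L))
  }
  set.seed(seed)
  range <- upper - lower
  vmax <- 0.2 * range
  X <- matrix(runif(n_particles * d, lower, upper), n_particles, d,
              byrow = TRUE)
  if (!is.null(init)) {
    init <- matrix(pmin(pmax(t(init), lower), upper), ncol = d,
                   byrow = TRUE)
    k <- min(nrow(init), n_particles)
    X[seq_len(k), ] <- init[seq_len(k), , drop = FALSE]
  }
  V <- matrix(runif(n_particles * d, -1, 1), n_particles, d,
              byrow = TRUE) * rep(vmax, each = n_particles)
  fvals <- apply(X, 1, objective)
  P <- X; pbest <- fvals
  gi <- which.min(pbest)
  gbest <- pbest[gi]; G <- P[gi, ]
  traj <- numeric(max_iter)
  stagnant <- 0L
  it <- 0L
  w <- 0.7; c1 <- 1.5; c2 <- 1.5
  while (it < max_iter) {
    it <- it + 1L
    r1 <- matrix(runif(n_particles * d), n_particles, d)
    r2 <- matrix(runif(n_particles * d), n_particles, d)
    V <- w * V + c1 * r1 * (P - X) +
      c2 * r2 * (matrix(G, n_particles, d, byrow = TRUE) - X)
    V <- pmin(pmax(V, rep(-vmax, each = n_particles)),
              rep(vmax, each = n_particles))
    X <- X + V
    for (j in seq_len(d)) {  # reflect at bounds
      over <- X[, j] > upper[j]; under <- X[, j] < lower[j]
      X[over, j] <- 2 * upper[j] - X[over, j]
      X[under, j] <- 2 * lower[j] - X[under, j]
      X[, j] <- pmin(pmax(X[, j], lower[j]), upper[j])
      V[over | under, j] <- -V[over | under, j]
    }
    fvals <- apply(X, 1, objective)
    better <- fvals < pbest
    P[better, ] <- X[better, , drop = FALSE]
    pbest[better] <- fvals[better]
    gi <- which.min(pbest)
    improvement <- gbest - pbest[gi]
    if (pbest[gi] < gbest) { gbest <- pbest[gi]; G <- P[gi, ] }
    traj[it] <- gbest
    stagnant <- if (improvement > tol) 0L else stagnant + 1L
    if (stagnant >= 20L) break
  }
  list(par = G, value = gbest, trajectory = traj[seq_len(it)], n_iter = it)
}

#' Two-step calibration of the growth model
#'
#' Stage 1 scans a log-spaced `(alpha, beta)` grid for combinations whose
#' mean simulated edge count is within `threshold` of the observed one
#' ([grid_search()]). Stage 2 selects among those solutions: a particle
#' swarm bounded by the feasible set's bounding box (log10 parameter space)
#' minimizes [epsilon_div()], the maximum Jensen-Shannon divergence of the
#' ensemble-averaged degree and link-length histograms from the observed
#' ones, with a linear penalty `penalty * max(0, epsilon_dif - threshold)`
#' keeping the swarm on the edge-count manifold (the bounding box alone
#' contains parameter pairs that match the distributions but not the edge
#' count).
#'
#' @inheritParams grid_search
#' @param ref_graph the observed network (a [spatial_graph()]); supplies the
#'   target edge count and the reference histograms.
#' @param n_rep1,n_rep2 ensemble sizes of the two stages.
#' @param n_dist_bins distance histogram bins.
#' @param n_particles,max_iter,tol PSO controls, see [pso_optimize()].
#' @param penalty weight of the edge-count feasibility penalty in the
#'   stage-2 objective.
#' @return list of class `calibration_result`: `grid`, `feasible`,
#'   `best_alpha`, `best_beta`, `epsilon_div`, `epsilon_dif_best`, `pso`,
#'   binning metadata and ensemble sizes.
#' @export
calibrate_growth <- function(simulate_fn, ref_graph, bounds = c(1e-3, 1e3),
                             n_grid = 50, threshold = 0.05, n_rep1 = 30,
                             n_rep2 = 100, n_dist_bins = 50,
                             n_particles = 20, max_iter = 400, tol = 1e-3,
                             penalty = 10, seed = 1) {
  target_L <- n_edges(ref_graph)
  k_max <- max(node_degrees(ref_graph)) * 2L
  d_max <- max(dist(ref_graph$coords))
  ref <- network_histograms(ref_graph, k_max, d_max, n_dist_bins)
  s1 <- grid_search(simulate_fn, target_L, bounds = bounds, n_grid = n_grid,
                    threshold = threshold, n_rep = n_rep1, seed = seed)
  if (nrow(s1$feasible) == 0)
    return(structure(c(s1, list(best_alpha = NA, best_beta = NA,
                                epsilon_div = NA)),
                     class = "calibration_result"))
  lo <- log10(c(min(s1$feasible$alpha), min(s1$feasible$beta)))
  hi <- log10(c(max(s1$feasible$alpha), max(s1$feasible$beta)))
  obj <- function(x) {
    ediv <- epsilon_div(simulate_fn, 10^x[1], 10^x[2], ref, k_max, d_max,
                        n_dist_bins = n_dist_bins, n_rep = n_rep2,
                        seed = seed + 1L)
    edif <- epsilon_dif(simulate_fn, 10^x[1], 10^x[2], target_L,
                        n_rep = n_rep1, seed = seed + 1L)
    ediv + penalty * max(0, edif - threshold)
  }
  # seed the swarm at the stage-1 solutions (thinned if too many): stage 2
  # chooses among them, so the search starts on the edge-count manifold
  fp <- log10(as.matrix(s1$feasible[, c("alpha", "beta")]))
  if (nrow(fp) > n_particles)
    fp <- fp[seq(1, nrow(fp), length.out = n_particles), , drop = FALSE]
  pso <- pso_optimize(obj, lo, hi, n_particles = n_particles,
                      max_iter = max_iter, tol = tol, init = fp,
                      seed = seed + 2L)
  best <- 10^pso$par
  ediv_best <- epsilon_div(simulate_fn, best[1], best[2], ref, k_max,
                           d_max, n_dist_bins = n_dist_bins,
                           n_rep = n_rep2, seed = seed + 1L)
  structure(list(
    grid = s1$grid, feasible = s1$feasible, bounds = bounds,
    threshold = threshold,
    best_alpha = best[1], best_beta = best[2],
    epsilon_div = ediv_best,
    epsilon_dif_best = epsilon_dif(simulate_fn, best[1], best[2], target_L,
                                   n_rep = n_rep1, seed = seed + 3L),
    pso = pso, k_max = k_max, d_max = d_max, n_dist_bins = n_dist_bins,
    n_rep1 = n_rep1, n_rep2 = n_rep2), class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(
    "<calibration_result> feasible grid points: %d; best alpha = %.3g, beta = %.3g, epsilon_div = %.3g\n",
    nrow(x$feasible), x$best_alpha, x$best_beta, x$epsilon_div))
  invisible(x)
}
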