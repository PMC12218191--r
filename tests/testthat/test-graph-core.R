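test_that("spatial_graph validates its invariants", {
  co <- matrix(runif(10), 5, 2)
  expect_s3_class(spatial_graph(co, data.frame(from = 1, to = 2)),
                  "spatial_graph")
  expect_error(spatial_graph(co, data.frame(from = 1, to = 1)), "self-loop")
  expect_error(spatial_graph(co, data.frame(from = c(1, 2), to = c(2, 1))),
               "duplicate")
  expect_error(spatial_graph(co, data.frame(from = 1, to = 2, weight = -1)),
               "positive")
  expect_error(spatial_graph(co, data.frame(from = 1, to = 9)), "range")
  expect_error(spatial_graph(matrix(c(0, NA), 1, 2)), "finite")
  # canonical i < j storage
  g <- spatial_graph(co, data.frame(from = 4, to = 2))
  expect_equal(g$edges$from, 2)
  expect_equal(g$edges$to, 4)
})

test_that("connection density is 2L / (N (N - 1))", {
  co <- matrix(runif(8), 4, 2)
  expect_equal(connection_density(spatial_graph(co, t(combn(4, 2)))), 1)
  co10 <- matrix(runif(20), 10, 2)
  expect_equal(connection_density(spatial_graph(co10)), 0)
  expect_error(connection_density(spatial_graph(matrix(0.5, 1, 2))),
               "at least 2")
  # mean selected edges of the random condition on the 49-node layout
  expect_equal(150.27 / 1176, 0.1277806, tolerance = 1e-6)
})

test_that("spatial density normalizes by the complete-graph length", {
  g <- collinear3()
  expect_equal(spatial_density(g), 1)
  expect_equal(spatial_density(g, g$edges[0, ]), 0)
  # the two unit edges carry half the total pairwise length (1+1)/(1+1+2)
  expect_equal(spatial_density(g, data.frame(from = c(1, 2), to = c(2, 3))),
               0.5)
  expect_error(spatial_density(spatial_graph(matrix(0, 3, 2),
                                             data.frame(from = 1, to = 2))),
               "degenerate")
})

test_that("functional J follows rho^alpha (1 - delta)^beta with 0^0 = 1", {
  expect_equal(functional_J(0.5, 0.5, 1, 1), 0.25)
  expect_equal(functional_J(0.7, 1, alpha = 1, beta = 2), 0)
  expect_equal(functional_J(0, 0, alpha = 0, beta = 0), 1)
  expect_equal(functional_J(0.5, 0.25, 1, 1), 0.375)
  # the short-regime J at alpha = 1 peaks at rho = 1/sqrt(3) with value
  # 2/(3 sqrt(3)); verified by grid scan of rho (1 - rho^2)
  grid <- seq(0, 1, 1e-4)
  expect_equal(max(grid * (1 - grid^2)), 2 / (3 * sqrt(3)),
               tolerance = 1e-6)
  expect_error(functional_J(1.2, 0), "\\[0, 1\\]")
})

test_that("closed-form optima match grid maximization of J", {
  # independent oracle: argmax on a fine grid, per regime delta(rho)
  grid <- seq(0, 1, 1e-5)
  for (alpha in c(0.146, 0.5, 1, 2.7)) {
    for (regime in c("random", "short", "long")) {
      J <- grid^alpha * (1 - expected_delta(grid, regime))
      expect_within(optimal_density(alpha, regime), grid[which.max(J)],
                    1e-4)
    }
  }
  expect_equal(optimal_density(1, "random"), 0.5)
  expect_equal(optimal_density(1, "long"), 1 / 3)
  expect_equal(optimal_density(1, "short"), sqrt(1 / 3))
  expect_equal(optimal_density(0, "short"), 0)
  expect_error(optimal_density(-1, "random"), "non-negative")
  expect_error(expected_delta(0.5, "weird"))
})

test_that("optimal densities are ordered, increasing, and tend to 1", {
  a <- c(0.01, 0.1, 0.5, 1, 5, 50, 1000)
  rl <- optimal_density(a, "long")
  rr <- optimal_density(a, "random")
  rs <- optimal_density(a, "short")
  expect_true(all(rl <= rr & rr <= rs))
  expect_true(all(diff(rl) > 0) && all(diff(rr) > 0) && all(diff(rs) > 0))
  expect_true(all(optimal_density(1e8, c("random")) > 1 - 1e-6))
})

test_that("small-alpha size scaling follows phi N^(-1/s)", {
  expect_equal(scaled_alpha(1.026, 49, 2), 1.026 / 7)
  expect_equal(scaled_alpha(1, 3214, 3), 3214^(-1 / 3))
  expect_equal(phi_from_alpha(0.146, 49, 2), 0.146 * 7)
  expect_error(scaled_alpha(-1, 10, 2), "positive")
  # with alpha = phi N^(-1/s), the scaled optima converge:
  # rho_long N^(1/s) -> phi/2, rho_rand N^(1/s) -> phi,
  # rho_short N^(1/(2s)) -> sqrt(phi/2)
  phi <- 1.3; s <- 2
  for (N in c(1e6, 1e8)) {
    a <- scaled_alpha(phi, N, s)
    expect_within(optimal_density(a, "long") * N^(1 / s), phi / 2, 0.01)
    expect_within(optimal_density(a, "random") * N^(1 / s), phi, 0.01)
    expect_within(optimal_density(a, "short") * N^(1 / (2 * s)),
                  sqrt(phi / 2), 0.01)
  }
})

test_that("binomial approximation agrees with J to first order in delta", {
  alpha <- 0.8; beta <- 1.7; rho <- 0.6
  deltas <- 10^seq(-4, -1, length.out = 10)
  err <- abs(functional_J(rho, deltas, alpha, beta) -
             (rho^alpha - rho^alpha * beta * deltas))
  # O(delta^2): error / delta^2 stays bounded as delta -> 0
  ratio <- err / deltas^2
  expect_lt(max(ratio) / min(ratio), 1.6)
})

test_that("density curve tracks ranking prefixes and is monotone", {
  g <- random_graph(10, seed = 3)
  r <- rank_edges(g, "length_asc")
  cur <- density_curve(g, r)
  expect_equal(nrow(cur), n_edges(g) + 1)
  expect_equal(cur$delta[1], 0)
  expect_equal(cur$delta[nrow(cur)], 1)
  expect_true(all(diff(cur$delta) >= 0))
  expect_true(all(diff(cur$rho) > 0))
  # single-edge graph
  co <- matrix(runif(6), 3, 2)
  g1 <- spatial_graph(co, data.frame(from = 1, to = 2))
  c1 <- density_curve(g1, rank_edges(g1, "weight_desc"))
  expect_equal(c1$delta[2], spatial_density(g1))
  # ranking from another graph is rejected
  expect_error(density_curve(g, rank_edges(random_graph(10, seed = 4,
                                                        density = 0.5),
                                           "weight_desc")),
               "cover")
})

test_that("random edge subsets have mean spatial density rho", {
  g <- random_graph(15, seed = 5)
  M <- n_edges(g)
  for (L in c(20, 60)) {
    vals <- vapply(1:300, function(i) {
      spatial_density(g, g$edges[sample.int(M, L), ])
    }, 0)
    se <- sd(vals) / sqrt(length(vals))
    expect_lt(abs(mean(vals) - L / M), 3 * se + 1e-12)
  }
})

test_that("maximize_J recovers closed-form optima and limit behavior", {
  set.seed(42)
  g <- synthetic_spatial_graph(46, "random", seed = 42)  # 1035 edges
  r <- rank_edges(g, "weight_desc")
  res <- maximize_J(g, r, alpha = 1, beta = 1)
  expect_within(res$L_star / n_edges(g), 0.5, 0.05)
  # huge alpha: benefit dominates, keep everything (beta = 0 so the last
  # edge, which brings delta to exactly 1, is not annihilated by the cost)
  expect_equal(maximize_J(g, r, alpha = 1e3, beta = 0)$L_star, n_edges(g))
  expect_gt(maximize_J(g, r, alpha = 1e3, beta = 1)$L_star / n_edges(g),
            0.99)
  # alpha = 0: pure cost, keep nothing
  expect_equal(maximize_J(g, r, alpha = 0)$L_star, 0)
  # with the regime's closed-form delta the scan reproduces optimal_density
  # to grid resolution: short regime, weights anticorrelated with length
  gs <- synthetic_spatial_graph(46, "short", seed = 7)
  rs <- rank_edges(gs, "weight_desc")
  cs <- density_curve(gs, rs)
  Jc <- cs$rho^1 * (1 - expected_delta(cs$rho, "short"))
  Lc <- cs$L[which.max(Jc)]
  expect_within(Lc / n_edges(gs), optimal_density(1, "short"),
                1 / n_edges(gs) + 1e-9)
})
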