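test_that("attachment probability has the benefit-cost form", {
  expect_equal(attachment_probability(0.3, 0.9, 0, 0), 1)  # uniform model
  expect_equal(attachment_probability(0.5, 1, 1, 2), 0)
  expect_equal(attachment_probability(0.5, 0.5, 1, 1), 0.25)
  # first-order expansion k - k beta d is exact at these values
  expect_equal(0.5 - 0.5 * 1 * 0.5, 0.25)
  expect_error(attachment_probability(1.2, 0, 1, 1), "\\[0, 1\\]")
  expect_error(attachment_probability(0.5, 0.5, -1, 1), "non-negative")
})

test_that("plain growth has deterministic edge count and valid structure", {
  net <- grow_network(N = 200, m = 5, alpha = 1, beta = 1, n0 = 6,
                      seed = 1)
  g <- net$graph
  expect_equal(n_edges(g), 6 * 5 / 2 + 5 * (200 - 6))
  expect_equal(sum(node_degrees(g)), 2 * n_edges(g))
  expect_false(any(g$edges$from == g$edges$to))
  expect_false(anyDuplicated(g$edges[, c("from", "to")]) > 0)
  # reproducible given seed
  net2 <- grow_network(N = 200, m = 5, alpha = 1, beta = 1, n0 = 6,
                       seed = 1)
  expect_identical(net$graph$edges, net2$graph$edges)
  expect_error(grow_network(N = 10, m = 7, n0 = 6), "exceed")
  expect_error(grow_network(N = 5, m = 2, n0 = 6), "exceed|N must")
})

test_that("uniform attachment gives the exponential degree profile", {
  set.seed(20)
  deg <- unlist(lapply(1:20, function(i)
    node_degrees(grow_network(N = 600, m = 5, alpha = 0, beta = 0,
                              seed = i)$graph)))
  # asymptotic law: P(k) = (1/(m+1)) (m/(m+1))^(k-m), geometric decay
  tab <- table(deg[deg >= 5])
  k <- as.numeric(names(tab))
  keep <- tab >= 20
  fit <- lm(log(as.numeric(tab[keep])) ~ k[keep])
  slope <- coef(fit)[2]
  expect_within(slope, log(5 / 6), 0.03)
  expect_gt(summary(fit)$r.squared, 0.98)
})

test_that("alpha=1, beta=0 reproduces preferential attachment", {
  set.seed(21)
  deg <- unlist(lapply(1:10, function(i)
    node_degrees(grow_network(N = 1000, m = 5, alpha = 1, beta = 0,
                              seed = 100 + i)$graph)))
  # heavy tail: log-log slope about -3 over the scaling window
  tab <- table(deg)
  k <- as.numeric(names(tab))
  keep <- k >= 5 & k <= quantile(deg, 0.99)
  fit <- lm(log(as.numeric(tab[keep])) ~ log(k[keep]))
  expect_within(coef(fit)[2], -3, 0.5)
  # distributionally indistinguishable from a standard PA implementation
  ours <- node_degrees(grow_network(N = 2000, m = 5, alpha = 1, beta = 0,
                                    seed = 5)$graph)
  ref <- igraph::degree(igraph::sample_pa(2000, power = 1, m = 5,
                                          directed = FALSE))
  ks <- suppressWarnings(stats::ks.test(ours, ref))
  expect_gt(ks$p.value, 0.01)
})

test_that("spatial cost suppresses long links and alpha spreads degrees", {
  set.seed(22)
  len0 <- unlist(lapply(1:10, function(i)
    edge_lengths(grow_network(N = 300, m = 5, alpha = 0, beta = 0,
                              seed = i)$graph)))
  lenB <- unlist(lapply(1:10, function(i)
    edge_lengths(grow_network(N = 300, m = 5, alpha = 0, beta = 100,
                              seed = i)$graph)))
  # stochastic dominance: high-beta lengths are shorter at every quantile
  qs <- seq(0.1, 0.9, 0.1)
  expect_true(all(quantile(lenB, qs) < quantile(len0, qs)))
  v0 <- var(unlist(lapply(1:10, function(i)
    node_degrees(grow_network(N = 300, m = 5, alpha = 0, beta = 0,
                              seed = 30 + i)$graph))))
  v1 <- var(unlist(lapply(1:10, function(i)
    node_degrees(grow_network(N = 300, m = 5, alpha = 1, beta = 0,
                              seed = 30 + i)$graph))))
  expect_gt(v1, v0)
})

test_that("accelerated growth follows hidden degrees and stays reproducible", {
  sc <- synthetic_connectome(n = 120, seed = 4)
  n1 <- sc$simulate(1, 1, 7)
  n2 <- sc$simulate(1, 1, 7)
  expect_identical(n1$graph$edges, n2$graph$edges)
  # alpha = beta = 0: every pair links exactly once
  full <- grow_accelerated(matrix(runif(30), ncol = 1), rep(3, 30),
                           alpha = 0, beta = 0, seed = 1)
  expect_equal(n_edges(full$graph), 30 * 29 / 2)
  # huge beta: all positive-length links suppressed
  tiny <- grow_accelerated(matrix(1:20 / 20, ncol = 1), rep(2, 20),
                           alpha = 0, beta = 1e8, seed = 1)
  expect_lt(n_edges(tiny$graph), 20)
  expect_error(grow_accelerated(matrix(runif(10), ncol = 1), rep(-1, 10),
                                1, 1), "positive")
  expect_error(grow_accelerated(matrix(runif(10), ncol = 1), rep(1, 5),
                                1, 1), "match")
  # mean edge count is stable across seed batches (3 SE)
  L1 <- vapply(1:30, function(s) n_edges(sc$simulate(2.51, 0.18, s)$graph), 0)
  L2 <- vapply(31:60, function(s) n_edges(sc$simulate(2.51, 0.18, s)$graph), 0)
  se <- sqrt(var(L1) / 30 + var(L2) / 30)
  expect_lt(abs(mean(L1) - mean(L2)), 3 * se)
})

test_that("unit-disk distance density is a proper, verified reference", {
  d <- seq(0, 2, length.out = 2001)
  f <- distance_density_reference(d)
  expect_within(sum(f) * (d[2] - d[1]), 1, 1e-3)  # integrates to 1
  # Monte-Carlo oracle: histogram of 1e6 sampled pair distances
  set.seed(33)
  a <- sample_points(1e6, "unit_disk"); b <- sample_points(1e6, "unit_disk")
  dd <- sqrt(rowSums((a - b)^2))
  br <- seq(0, 2, length.out = 51)
  emp <- hist(dd, breaks = br, plot = FALSE)$density
  theo <- distance_density_reference((br[-1] + br[-51]) / 2)
  expect_lt(max(abs(emp - theo)), 0.01)
  expect_error(distance_density_reference(0.5, domain = "unit_square"),
               "unsupported")
})

test_that("beta=0 grown networks draw link lengths from the disk reference", {
  set.seed(44)
  lens <- unlist(lapply(1:10, function(i)
    edge_lengths(grow_network(N = 500, m = 5, alpha = 10, beta = 0,
                              seed = 200 + i)$graph)))
  br <- seq(0, 2, length.out = 41)
  emp <- tabulate(findInterval(lens, br, rightmost.closed = TRUE), 40)
  mid <- (br[-1] + br[-41]) / 2
  theo <- distance_density_reference(mid)
  expect_lt(js_divergence(emp, theo), 0.02)
})
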