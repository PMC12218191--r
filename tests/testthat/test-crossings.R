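test_that("crossing counts handle the canonical small cases", {
  co <- convex4()
  expect_equal(count_crossings(co, rbind(c(1, 3), c(2, 4))), 1)  # the X
  expect_equal(count_crossings(co, k4_edges()), 1)  # K4, convex position
  # brute-force oracle agrees by direct pairwise testing
  expect_equal(count_crossings_brute(co, k4_edges()), 1)
  # star graph: all edges share the hub, never a crossing
  hub <- rbind(c(0.5, 0.5), c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  star <- cbind(1, 2:5)
  expect_equal(count_crossings(hub, star), 0)
  expect_equal(count_crossings(co, matrix(integer(), 0, 2)), 0)
  # touching at a shared vertex region: T-junction is not a crossing
  tj <- rbind(c(0, 0), c(2, 0), c(1, 0), c(1, 1), c(1, -1))
  expect_equal(count_crossings(tj, rbind(c(1, 2), c(4, 5))), 1)
  expect_equal(count_crossings(tj, rbind(c(1, 2), c(3, 4))), 0)
  expect_error(count_crossings(matrix(runif(12), 4, 3), rbind(c(1, 2))),
               "2-D")
})

test_that("collinear overlapping segments raise a degeneracy error", {
  co <- rbind(c(0, 0), c(2, 0), c(1, 0), c(3, 0))
  expect_error(count_crossings(co, rbind(c(1, 2), c(3, 4))), "degenerate")
  expect_error(count_crossings_brute(co, rbind(c(1, 2), c(3, 4))),
               "degenerate")
  # the exact regular grid has overlapping collinear edge pairs
  grid0 <- netviz_layout(seed = 1, jitter = 0)
  expect_error(count_crossings(grid0, all_pairs(49)), "degenerate")
})

test_that("sweep line and brute force agree on random instances", {
  set.seed(99)
  for (rep in 1:500) {
    n <- sample(4:12, 1)
    co <- matrix(runif(2 * n), n, 2)
    pairs <- all_pairs(n)
    L <- min(nrow(pairs), sample(2:60, 1))
    e <- pairs[sample.int(nrow(pairs), L), ]
    expect_identical(count_crossings(co, e, method = "sweep"),
                     count_crossings(co, e, method = "brute"))
  }
})

test_that("sweep line matches brute force on near-degenerate layouts", {
  set.seed(7)
  for (rep in 1:50) {
    # jittered grid: many nearly collinear triples
    co <- netviz_layout(seed = rep, jitter = 1e-5)
    pairs <- all_pairs(49)
    e <- pairs[sample.int(nrow(pairs), 80), ]
    sweep <- tryCatch(count_crossings(co, e, method = "sweep"),
                      error = function(e) "degenerate")
    brute <- tryCatch(count_crossings(co, e, method = "brute"),
                      error = function(e) "degenerate")
    expect_identical(sweep, brute)
  }
})

test_that("crossing counts are invariant under similarity transforms", {
  set.seed(3)
  co <- matrix(runif(24), 12, 2)
  e <- all_pairs(12)
  base <- count_crossings(co, e)
  th <- 0.63
  rot <- co %*% rbind(c(cos(th), sin(th)), c(-sin(th), cos(th)))
  expect_equal(count_crossings(rot, e), base)
  expect_equal(count_crossings(3.7 * co, e), base)
  expect_equal(count_crossings(sweep(co, 2, c(5, -2), "+"), e), base)
})

test_that("expected crossings follow the quadratic density law", {
  expect_equal(expected_crossings(1, 147), 147)
  expect_equal(expected_crossings(0.5, 100), 25)
  expect_error(expected_crossings(1.5, 10), "\\[0, 1\\]")
  # combinatorial oracle on a small layout: uniform subsets of L of L_max
  # edges keep each crossing pair with prob L(L-1)/(L_max(L_max-1))
  set.seed(11)
  co <- matrix(runif(20), 10, 2)
  pairs <- all_pairs(10)
  Lmax <- nrow(pairs)
  ecm <- count_crossings(co, pairs)
  for (L in c(10, 25)) {
    vals <- vapply(1:400, function(i)
      count_crossings(co, pairs[sample.int(Lmax, L), ]), 0)
    exact <- ecm * L * (L - 1) / (Lmax * (Lmax - 1))
    se <- sd(vals) / sqrt(length(vals))
    expect_lt(abs(mean(vals) - exact), 3 * se + 1e-9)
  }
})

test_that("crossing profiles are monotone and ordered across regimes", {
  profs <- lapply(c("long", "random", "short"), function(rg)
    crossing_profile(function(s) netviz_layout(s),
                     regime = rg, n_samples = 8, seed = 42))
  names(profs) <- c("long", "random", "short")
  for (p in profs) {
    expect_true(all(diff(p$per_L_mean) >= 0))
    expect_equal(p$per_L_mean[1], 0)  # L = 0
    expect_equal(p$per_L_mean[2], 0)  # a single edge cannot cross
  }
  # at equal L, long-range layouts accumulate crossings fastest
  Ls <- round(c(0.1, 0.3, 0.6) * 1176)
  for (L in Ls) {
    expect_gte(profs$long$per_L_mean[L + 1], profs$random$per_L_mean[L + 1])
    expect_gte(profs$random$per_L_mean[L + 1], profs$short$per_L_mean[L + 1])
  }
  # deterministic given the seed
  p2 <- crossing_profile(function(s) netviz_layout(s), "random",
                         n_samples = 8, seed = 42)
  expect_identical(p2$per_L_mean, profs$random$per_L_mean)
})
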