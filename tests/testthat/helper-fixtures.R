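# Shared fixtures built in code at test time.

# Three collinear equispaced points: pairwise lengths 1, 1, 2.
collinear3 <- function() {
  spatial_graph(matrix(c(0, 1, 2), ncol = 1),
                data.frame(from = c(1, 2, 3), to = c(2, 3, 1)))
}

# Four points in convex position; the two diagonals of K4 cross once.
convex4 <- function() cbind(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))

k4_edges <- function() t(combn(4, 2))

# A small random geometric graph (complete by default).
random_graph <- function(n = 12, seed = 1, regime = "random",
                         density = 1) {
  synthetic_spatial_graph(n, regime, density = density, seed = seed)
}

expect_within <- function(x, target, tol) {
  expect_lt(abs(x - target), tol)
}
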