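# A 4-region association matrix whose off-diagonal values are all distinct:
# pairs (1,2)=.9 (1,3)=.8 (1,4)=.7 (2,3)=.3 (2,4)=.2 (3,4)=.1
toy_r <- function() {
  r <- diag(4)
  r[1, 2] <- r[2, 1] <- 0.9
  r[1, 3] <- r[3, 1] <- 0.8
  r[1, 4] <- r[4, 1] <- 0.7
  r[2, 3] <- r[3, 2] <- 0.3
  r[2, 4] <- r[4, 2] <- 0.2
  r[3, 4] <- r[4, 3] <- 0.1
  dimnames(r) <- list(paste0("R", 1:4), paste0("R", 1:4))
  r
}

test_that("association matrix reproduces hand-computed Pearson values", {
  vals <- cbind(x = c(1, 2, 3, 4), y = c(1, 3, 2, 4), z = -c(1, 2, 3, 4),
                w = c(1, 2, 3, 4) * 2 + 5)
  A <- association_matrix(vals)
  expect_equal(A$r["x", "y"], 0.8)
  expect_equal(A$r["x", "z"], -1)
  expect_equal(A$r["x", "w"], 1)
  expect_equal(diag(A$r), rep(1, 4), ignore_attr = TRUE)
  expect_lt(max(abs(A$r - t(A$r))), 1e-12)
  expect_equal(A$n_subjects, 4L)

  vals_bad <- cbind(x = c(1, 2, 3), flat = c(2, 2, 2))
  expect_error(association_matrix(vals_bad), "flat")
  expect_error(association_matrix(vals[1:2, ]), "3 subjects")
})

test_that("density thresholding keeps the E strongest signed correlations", {
  G <- threshold_by_density(toy_r(), 0.5)
  expect_equal(sum(G$adjacency) / 2, 3)
  expect_equal(G$adjacency[1, 2], 1L)
  expect_equal(G$adjacency[1, 3], 1L)
  expect_equal(G$adjacency[1, 4], 1L)
  expect_equal(G$adjacency[2, 3], 0L)
  expect_equal(G$density, 0.5)

  expect_equal(sum(threshold_by_density(toy_r(), 1)$adjacency) / 2, 6)
  expect_error(threshold_by_density(toy_r(), 0.01), "zero edges")

  # n = 90 at d = 0.22 quantizes to round(0.22 * 4005) = 881 edges
  set.seed(1)
  vals <- matrix(rnorm(30 * 90), 30, 90)
  A90 <- association_matrix(vals)
  G90 <- threshold_by_density(A90, 0.22)
  expect_equal(sum(G90$adjacency) / 2, 881)
  expect_equal(sum(threshold_by_density(A90, 1)$adjacency) / 2, 4005)
})

test_that("correlation thresholding records achieved density and allows empty graphs", {
  G <- threshold_by_correlation(toy_r(), 0.65)
  expect_equal(sum(G$adjacency) / 2, 3)
  expect_equal(G$density, 0.5)
  expect_equal(sum(threshold_by_correlation(toy_r(), -0.999)$adjacency) / 2, 6)
  expect_warning(Ge <- threshold_by_correlation(toy_r(), 0.95), "empty")
  expect_equal(sum(Ge$adjacency), 0)
})

test_that("edge sets are nested in density and agree with correlation cuts", {
  set.seed(7)
  for (rep in 1:5) {
    vals <- matrix(rnorm(20 * 15), 20, 15)
    A <- association_matrix(vals)
    prev <- NULL
    for (d in c(0.1, 0.2, 0.4, 0.7, 1)) {
      adj <- threshold_by_density(A, d)$adjacency
      if (!is.null(prev)) expect_true(all(adj[prev == 1] == 1))
      prev <- adj
    }
    # density cut == correlation cut at the E-th largest off-diagonal value
    E <- round(0.3 * choose(15, 2))
    off <- sort(A$r[upper.tri(A$r)], decreasing = TRUE)
    G_d <- threshold_by_density(A, 0.3)
    G_r <- threshold_by_correlation(A, off[E + 1])
    expect_identical(G_d$adjacency, G_r$adjacency)
  }
})

test_that("connectivity is monotone in density and D_min is the first connecting density", {
  # star construction: top-3 edges form a star on 4 nodes, so the graph is
  # connected at density 0.5 (3 edges) but not at 0.25 (2 edges)
  grid <- density_grid(0.25, 0.25, 1, windows = list())
  expect_equal(minimum_connected_density(toy_r(), grid), 0.5)

  set.seed(8)
  vals <- matrix(rnorm(15 * 12), 15, 12)
  A <- association_matrix(vals)
  grid2 <- density_grid(0.1, 0.05, 1, windows = list())
  dmin <- minimum_connected_density(A, grid2)
  expect_lte(dmin, 1)
  conn <- sapply(grid2$densities, function(d) {
    igraph::is_connected(igraph::graph_from_adjacency_matrix(
      threshold_by_density(A, d)$adjacency, mode = "undirected"))
  })
  expect_true(all(diff(conn) >= 0))
  expect_equal(grid2$densities[which(conn)[1]], dmin)
})

test_that("density grid validates windows", {
  expect_error(density_grid(0.3, 0.02, 0.2), "start")
  expect_error(density_grid(0.22, 0.02, 0.5, windows = list(c(0.1, 0.3))),
               "window")
  g <- density_grid()
  expect_equal(length(g$densities), 15)
  expect_equal(g$densities[1], 0.22)
  expect_equal(g$densities[15], 0.5)
})
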