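# Independent brute-force oracles, kept free of the package's own
# implementations: triangle enumeration for clustering, breadth-first
# search for shortest paths, and exhaustive small-graph enumeration.

oracle_cc <- function(adj) {
  n <- nrow(adj)
  local <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] == 1)
    k <- length(nb)
    if (k < 2) next
    tri <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k)
      if (adj[nb[a], nb[b]] == 1) tri <- tri + 1
    local[i] <- tri / (k * (k - 1) / 2)
  }
  mean(local)
}

oracle_bfs_dist <- function(adj, s) {
  n <- nrow(adj)
  dist <- rep(Inf, n)
  dist[s] <- 0
  frontier <- s
  d <- 0
  while (length(frontier) > 0) {
    d <- d + 1
    nxt <- integer(0)
    for (u in frontier) {
      for (v in which(adj[u, ] == 1)) {
        if (dist[v] > d) {
          dist[v] <- d
          nxt <- c(nxt, v)
        }
      }
    }
    frontier <- unique(nxt)
  }
  dist
}

# Mean shortest-path distance over connected ordered pairs.
oracle_cpl <- function(adj) {
  n <- nrow(adj)
  vals <- c()
  for (s in seq_len(n)) {
    d <- oracle_bfs_dist(adj, s)[-s]
    vals <- c(vals, d[is.finite(d)])
  }
  mean(vals)
}

oracle_connected <- function(adj) {
  all(is.finite(oracle_bfs_dist(adj, 1L)))
}

# All simple undirected graphs on n labeled nodes as adjacency matrices.
enumerate_graphs <- function(n) {
  pairs <- t(combn(n, 2))
  n_pairs <- nrow(pairs)
  lapply(0:(2^n_pairs - 1), function(mask) {
    bits <- as.integer(intToBits(mask))[seq_len(n_pairs)]
    adj <- matrix(0L, n, n)
    on <- which(bits == 1L)
    adj[pairs[on, , drop = FALSE]] <- 1L
    adj[pairs[on, c(2, 1), drop = FALSE]] <- 1L
    adj
  })
}

# Erdos-Renyi draw conditioned on connectivity.
rand_connected_adj <- function(n, p, seed) {
  set.seed(seed)
  repeat {
    adj <- matrix(0L, n, n)
    ut <- upper.tri(adj)
    adj[ut] <- rbinom(sum(ut), 1L, p)
    adj <- adj + t(adj)
    if (oracle_connected(adj)) return(adj)
  }
}

# Wrap a plain adjacency matrix as a binary_network for functions that
# need the full object.
new_binary_network_for_test <- function(adj) {
  n <- nrow(adj)
  structure(list(adjacency = adj, density = sum(adj) / (n * (n - 1)),
                 threshold_kind = "density", threshold_value = NA_real_,
                 provenance = "empirical", region_names = rownames(adj)),
            class = "binary_network")
}

# Assemble a bootstrap_curves object from explicit per-bootstrap curve
# matrices (rows = bootstrap samples, columns = grid densities) so the
# dependent-samples test can be exercised on constructed curves.
fake_bootstrap_curves <- function(Y1, Y2, densities,
                                  models = c("TOP", "HQS")) {
  grid <- density_grid(min(densities), diff(densities)[1], max(densities),
                       windows = list())
  curves <- list(list(SW = Y1, CC_norm = Y1, CPL_norm = Y1),
                 list(SW = Y2, CC_norm = Y2, CPL_norm = Y2))
  names(curves) <- models
  structure(list(grid = grid, models = models, m = 1L,
                 n_boot = nrow(Y1), seed = 0L, curves = curves,
                 dmin_table = NULL, group_label = NA_character_),
            class = "bootstrap_curves")
}

# Small block-structured dataset used across null-model and inference tests.
block_fixture <- function(n_subjects = 40L, n_regions = 30L, n_blocks = 3L,
                          seed = 11L, within = 0.6, between = 0.1) {
  cfg <- simulation_config(n_subjects_per_group = c(n_subjects, 3L),
                           n_regions = n_regions, n_blocks = n_blocks,
                           within_block_r = within, between_block_r = between,
                           seed = seed)
  data <- correct_regional_volumes(generate_group_morphometry(cfg, 1L),
                                   covariate_names = character(0))
  list(config = cfg, data = data, assoc = association_matrix(data))
}
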