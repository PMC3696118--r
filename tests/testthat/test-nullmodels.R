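test_that("TOP rewiring preserves degrees, simplicity and connectedness", {
  for (rep in 1:10) {
    adj <- rand_connected_adj(30, 0.2, seed = 200 + rep)
    G <- new_binary_network_for_test(adj)
    null <- top_null(G, seed = rep)
    a <- null$adjacency
    expect_identical(sort(rowSums(a)), sort(rowSums(adj)))
    expect_identical(a, t(a))
    expect_true(all(diag(a) == 0))
    expect_true(all(a %in% c(0L, 1L)))
    expect_true(oracle_connected(a))
    expect_equal(null$provenance, "TOP")
  }
})

test_that("TOP rewiring is deterministic under a seed and rewires the topology", {
  adj <- rand_connected_adj(40, 0.15, seed = 77)
  G <- new_binary_network_for_test(adj)
  n1 <- top_null(G, seed = 5)
  n2 <- top_null(G, seed = 5)
  expect_identical(n1$adjacency, n2$adjacency)
  n3 <- top_null(G, seed = 6)
  expect_false(identical(n1$adjacency, n3$adjacency))
  # topology actually changes
  expect_gt(sum(abs(n1$adjacency - adj)), 0)
})

test_that("complete graphs have no rewirable pair and are returned unchanged", {
  K5 <- matrix(1L, 5, 5); diag(K5) <- 0L
  G <- new_binary_network_for_test(K5)
  expect_warning(out <- top_null(G, seed = 1), "unchanged")
  expect_identical(out$adjacency, K5)
})

test_that("HQS constants satisfy the Gram-construction moment identities", {
  fx <- block_fixture(seed = 31)
  mom <- hqs_moments(fx$assoc)
  expect_gte(mom$m_f, 2)
  # E[C_ij] = m_f mu^2 = e
  expect_equal(mom$m_f * mom$mu^2, mom$e, tolerance = 1e-12)
  # Var[C_ij] = m_f ((mu^2 + sigma^2)^2 - mu^4) = v
  s2 <- mom$sigma^2
  expect_equal(mom$m_f * ((mom$mu^2 + s2)^2 - mom$mu^4), mom$v,
               tolerance = 1e-9)
  # E[C_ii] = m_f (mu^2 + sigma^2) = sqrt(e^2 + m_f v) ~ dbar up to the
  # integer rounding of m_f
  expect_equal(mom$m_f * (mom$mu^2 + s2), sqrt(mom$e^2 + mom$m_f * mom$v),
               tolerance = 1e-9)
})

test_that("HQS draws are PSD, seed-stable, and threshold to the target density", {
  fx <- block_fixture(seed = 32)
  C1 <- hqs_null_covariance(fx$assoc, seed = 9)
  C2 <- hqs_null_covariance(fx$assoc, seed = 9)
  expect_identical(C1, C2)
  ev <- eigen(C1, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8)
  G <- hqs_null_network(fx$assoc, 0.3, seed = 9)
  expect_equal(G$density, sum(G$adjacency) / (30 * 29), tolerance = 1e-12)
  # 0.3 * 435 = 130.5 rounds half away from zero to 131 edges
  expect_equal(sum(G$adjacency) / 2, 131)
  expect_equal(sum(hqs_null_network(fx$assoc, 1, seed = 2)$adjacency) / 2,
               choose(30, 2))
})

test_that("HQS rejects covariance matrices with non-positive mean off-diagonal", {
  S <- diag(4)
  S[upper.tri(S)] <- S[lower.tri(S)] <- -0.1
  expect_error(hqs_moments(S), "non-positive mean covariance")
  expect_error(hqs_moments(diag(4)), "variance")
})

test_that("COR permutation preserves subject value multisets and target density", {
  fx <- block_fixture(seed = 33)
  G <- cor_null(fx$data, 0.25, seed = 4)
  perm <- attr(G, "permuted_values")
  orig <- fx$data$residuals
  for (i in seq_len(nrow(orig)))
    expect_identical(sort(unname(perm[i, ])), sort(unname(orig[i, ])))
  expect_equal(sum(G$adjacency) / 2, round(0.25 * choose(30, 2)))
  expect_identical(cor_null(fx$data, 0.25, seed = 4)$adjacency, G$adjacency)
})

test_that("COR destroys block correlation structure", {
  fx <- block_fixture(seed = 34)
  orig_mean <- mean(abs(fx$assoc$r[upper.tri(fx$assoc$r)]))
  perm_means <- sapply(1:10, function(s) {
    r <- cor(attr(cor_null(fx$data, 0.25, seed = s), "permuted_values"))
    mean(abs(r[upper.tri(r)]))
  })
  expect_true(all(perm_means < orig_mean))
})

test_that("two regions reduce permutation to per-subject keep-or-swap", {
  set.seed(9)
  vals <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  data <- structure(list(residuals = vals), class = "corrected_rgv")
  G <- cor_null(data, 1, seed = 3)
  expect_equal(sum(G$adjacency) / 2, 1)
  perm <- attr(G, "permuted_values")
  kept <- apply(perm == vals, 1, all)
  swapped <- apply(perm == vals[, 2:1], 1, all)
  expect_true(all(kept | swapped))
})

test_that("null ensembles are reproducible and average their members", {
  fx <- block_fixture(seed = 35)
  G <- threshold_by_density(fx$assoc, 0.25)
  e1 <- null_ensemble(G, "TOP", m = 5, seed = 21)
  e2 <- null_ensemble(G, "TOP", m = 5, seed = 21)
  expect_identical(e1$C_null_values, e2$C_null_values)
  expect_equal(e1$C_null_mean, mean(e1$C_null_values))
  expect_equal(e1$L_null_mean, mean(e1$L_null_values))
  expect_equal(e1$n_fragmented, 0L)

  K5 <- matrix(1L, 5, 5); diag(K5) <- 0L
  eK <- suppressWarnings(null_ensemble(new_binary_network_for_test(K5),
                                       "TOP", m = 1, seed = 1))
  expect_equal(eK$C_null_mean, 1)
  expect_equal(eK$L_null_mean, 1)
})

test_that("discard policy redraws fragmented members", {
  fx <- block_fixture(n_subjects = 20L, seed = 36)
  # low density fragments HQS draws often enough to exercise redraws
  ens <- null_ensemble(fx$assoc, "HQS", m = 10, seed = 2, density = 0.2,
                       fragment_policy = "discard")
  expect_equal(ens$n_fragmented, 0L)
  connected <- vapply(ens$members, function(g) oracle_connected(g$adjacency),
                      logical(1))
  expect_true(all(connected))
})

test_that("null clustering is higher for covariance-structured nulls than for TOP", {
  fx <- block_fixture(seed = 37)
  G <- threshold_by_density(fx$assoc, 0.22)
  e_top <- null_ensemble(G, "TOP", m = 15, seed = 3)
  e_hqs <- null_ensemble(fx$assoc, "HQS", m = 15, seed = 3, density = 0.22)
  e_cor <- null_ensemble(fx$data, "COR", m = 15, seed = 3, density = 0.22)
  expect_gt(e_hqs$C_null_mean, e_top$C_null_mean)
  expect_gt(e_cor$C_null_mean, e_top$C_null_mean)
})
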