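test_that("target correlation matrix has the block-constant structure", {
  cfg <- simulation_config(n_subjects_per_group = c(5, 5), n_regions = 4,
                           n_blocks = 2, within_block_r = 0.6,
                           between_block_r = 0.1, seed = 1)
  R <- build_target_correlation(cfg)
  expect_equal(diag(R), rep(1, 4))
  expect_equal(R[1, 2], 0.6)
  expect_equal(R[3, 4], 0.6)
  expect_equal(R[1, 3], 0.1)
  expect_equal(R[1, 4], 0.1)
  expect_equal(R[2, 3], 0.1)
  expect_identical(R, t(R))

  cfg0 <- simulation_config(n_subjects_per_group = c(5, 5), n_regions = 4,
                            n_blocks = 2, within_block_r = 0,
                            between_block_r = 0, seed = 1)
  expect_equal(build_target_correlation(cfg0), diag(4))
})

test_that("default-scale block matrix is positive semidefinite", {
  cfg <- simulation_config(n_regions = 90, n_blocks = 6,
                           within_block_r = 0.5, between_block_r = 0.1)
  R <- build_target_correlation(cfg)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), 0)
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(within_block_r = 0.2, between_block_r = 0.5),
               "within_block_r")
  cfg <- simulation_config(n_subjects_per_group = c(2, 5))
  expect_error(generate_group_morphometry(cfg, 1), "3 subjects")
})

test_that("generation is deterministic and groups share the target when group_effect = 1", {
  cfg <- simulation_config(n_subjects_per_group = c(10, 10), n_regions = 12,
                           n_blocks = 3, group_effect = 1, seed = 99)
  d1 <- generate_group_morphometry(cfg, 1)
  d1b <- generate_group_morphometry(cfg, 1)
  expect_identical(d1$values, d1b$values)
  expect_identical(d1$covariates, d1b$covariates)
  expect_identical(build_target_correlation(cfg, 1),
                   build_target_correlation(cfg, 2))
  cfg2 <- simulation_config(n_subjects_per_group = c(10, 10), n_regions = 12,
                            n_blocks = 3, group_effect = 0.5, seed = 99)
  R2 <- build_target_correlation(cfg2, 2)
  expect_equal(R2[1, 12], 0.05)
})

test_that("empirical correlations converge to the target at large n", {
  cfg <- simulation_config(n_subjects_per_group = c(2000, 3), n_regions = 12,
                           n_blocks = 3, within_block_r = 0.6,
                           between_block_r = 0.1, seed = 5)
  d <- generate_group_morphometry(cfg, 1)
  r <- cor(d$values)
  blk <- rep(1:3, each = 4)
  same <- outer(blk, blk, "==") & upper.tri(r)
  diff <- (!outer(blk, blk, "==")) & upper.tri(r)
  expect_true(all(r[same] > 0.55 & r[same] < 0.65))
  # entrywise convergence within 3/sqrt(n)
  target <- build_target_correlation(cfg)
  expect_lt(max(abs(r - target)[upper.tri(r)]), 3 / sqrt(2000))
  expect_true(all(abs(r[diff] - 0.1) < 3 / sqrt(2000)))
})

test_that("covariate effects are removed by regression against true covariates", {
  cfg <- simulation_config(n_subjects_per_group = c(400, 3), n_regions = 12,
                           n_blocks = 3, within_block_r = 0.6,
                           between_block_r = 0.1,
                           covariate_effects = c(age = 1.5, sex = 2, tbv = 0.05),
                           seed = 21)
  d <- generate_group_morphometry(cfg, 1)
  # shared covariate signal inflates between-block correlation ...
  blk <- rep(1:3, each = 4)
  diff_mask <- (!outer(blk, blk, "==")) & upper.tri(diag(12))
  expect_gt(mean(cor(d$values)[diff_mask]), 0.3)
  # ... and the per-region linear correction recovers the block target
  res <- correct_regional_volumes(d)$residuals
  r_res <- cor(res)
  target <- build_target_correlation(cfg)
  expect_lt(max(abs(r_res - target)[upper.tri(target)]), 4 / sqrt(400))
})
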