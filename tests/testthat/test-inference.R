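make_curve <- function(values, densities = seq(0.22, 0.5, by = 0.02),
                       metric = "SW") {
  swnull:::new_metric_curve(densities, values, metric)
}

test_that("FDA area matches hand sums and is symmetric in magnitude", {
  d3 <- c(0.22, 0.24, 0.26)
  c1 <- make_curve(c(1.2, 1.1, 1.0), d3)
  c2 <- make_curve(c(1.0, 1.0, 1.0), d3)
  out <- fda_area(c1, c2)
  expect_equal(out$area, 0.3)
  expect_equal(out$signed_area, -0.3)
  rev_out <- fda_area(c2, c1)
  expect_equal(rev_out$area, 0.3)
  expect_equal(rev_out$signed_area, 0.3)
  expect_equal(fda_area(c1, c1), list(area = 0, signed_area = 0, window = NULL))
  expect_error(fda_area(c1, make_curve(c(1, 1), c(0.22, 0.24))), "mismatched")
})

test_that("FDA area is an L1 distance on sampled curves", {
  set.seed(14)
  d <- seq(0.22, 0.5, by = 0.02)
  for (rep in 1:20) {
    x <- make_curve(rnorm(15), d)
    y <- make_curve(rnorm(15), d)
    z <- make_curve(rnorm(15), d)
    axy <- fda_area(x, y)$area
    expect_gte(axy, 0)
    expect_equal(fda_area(y, x)$area, axy)
    expect_lte(fda_area(x, z)$area, axy + fda_area(y, z)$area + 1e-12)
  }
  x <- make_curve(rnorm(15), d)
  expect_identical(fda_area(x, x)$area, 0)
})

test_that("windowed areas over a partition of the grid sum to the cumulative area", {
  set.seed(15)
  d <- seq(0.22, 0.5, by = 0.02)
  x <- make_curve(rnorm(15), d)
  y <- make_curve(rnorm(15), d)
  # disjoint windows covering every grid point exactly once
  parts <- list(c(0.22, 0.28), c(0.30, 0.38), c(0.40, 0.50))
  part_sum <- sum(sapply(parts, function(w) fda_area(x, y, window = w)$area))
  expect_equal(part_sum, fda_area(x, y)$area)
})

test_that("bootstrap association matrices are seed-stable and inflate correlations", {
  fx <- block_fixture(seed = 41)
  b1 <- bootstrap_association(fx$data, n_boot = 3, seed = 8)
  b2 <- bootstrap_association(fx$data, n_boot = 3, seed = 8)
  expect_identical(lapply(b1, `[[`, "r"), lapply(b2, `[[`, "r"))
  boots <- bootstrap_association(fx$data, n_boot = 50, seed = 9)
  mean_abs <- sapply(boots, function(A) mean(abs(A$r[upper.tri(A$r)])))
  orig <- mean(abs(fx$assoc$r[upper.tri(fx$assoc$r)]))
  expect_gte(mean(mean_abs), orig)
})

test_that("dependent test gives p = 1 for identical curves and small p for a large offset", {
  set.seed(16)
  d <- seq(0.2, 0.4, by = 0.05)
  Y <- matrix(rnorm(20 * 5), 20, 5)
  bc_same <- fake_bootstrap_curves(Y, Y, d)
  res <- dependent_model_test(bc_same, "TOP", "HQS", metric = "SW",
                              n_perm = 500, seed = 2)
  expect_equal(res$p_value, 1)
  expect_equal(res$area, 0)

  bc_off <- fake_bootstrap_curves(Y, Y + 0.5 + matrix(rnorm(100, 0, 0.01), 20, 5), d)
  res_off <- dependent_model_test(bc_off, "TOP", "HQS", metric = "SW",
                                  n_perm = 500, seed = 2)
  expect_lte(res_off$p_value, 5 / 501)
  expect_gt(res_off$signed_area, 2)
})

test_that("dependent test p-values stay in (0, 1] and warn for tiny n_perm", {
  set.seed(17)
  d <- seq(0.2, 0.4, by = 0.05)
  for (rep in 1:5) {
    bc <- fake_bootstrap_curves(matrix(rnorm(50), 10, 5),
                                matrix(rnorm(50), 10, 5), d)
    p <- dependent_model_test(bc, "TOP", "HQS", n_perm = 200,
                              seed = rep)$p_value
    expect_gt(p, 0)
    expect_lte(p, 1)
  }
  expect_warning(dependent_model_test(fake_bootstrap_curves(
    matrix(rnorm(50), 10, 5), matrix(rnorm(50), 10, 5), d),
    "TOP", "HQS", n_perm = 50, seed = 1), "unstable")
})

test_that("independent group test is deterministic and validates inputs", {
  cfg <- simulation_config(n_subjects_per_group = c(12, 12), n_regions = 15,
                           n_blocks = 3, seed = 3)
  da <- correct_regional_volumes(generate_group_morphometry(cfg, 1))
  db <- correct_regional_volumes(generate_group_morphometry(cfg, 2))
  grid <- density_grid(0.25, 0.05, 0.45, windows = list())
  r1 <- independent_group_test(da, db, grid, metric = "CC", n_perm = 100,
                               seed = 5)
  r2 <- independent_group_test(da, db, grid, metric = "CC", n_perm = 100,
                               seed = 5)
  expect_identical(r1$p_value, r2$p_value)
  expect_gt(r1$p_value, 0)
  expect_lte(r1$p_value, 1)

  tiny <- structure(list(residuals = da$residuals[1:2, ]),
                    class = "corrected_rgv")
  expect_error(independent_group_test(tiny, db, grid, metric = "CC",
                                      n_perm = 10), "3 subjects")
  expect_error(independent_group_test(da, db, grid, metric = "SW",
                                      model = "none", n_perm = 10),
               "null model")
})

test_that("regenerate and reuse modes agree qualitatively on a strong effect", {
  cfg1 <- simulation_config(n_subjects_per_group = c(16, 16), n_regions = 12,
                            n_blocks = 3, within_block_r = 0.7,
                            between_block_r = 0.2, seed = 6)
  cfg2 <- simulation_config(n_subjects_per_group = c(16, 16), n_regions = 12,
                            n_blocks = 3, within_block_r = 0.4,
                            between_block_r = 0.15, seed = 7)
  da <- correct_regional_volumes(generate_group_morphometry(cfg1, 1))
  db <- correct_regional_volumes(generate_group_morphometry(cfg2, 1))
  grid <- density_grid(0.3, 0.1, 0.4, windows = list())
  fast <- suppressWarnings(
    independent_group_test(da, db, grid, metric = "CC_norm",
                           model = "HQS", n_perm = 60, seed = 8, m = 3))
  slow <- suppressWarnings(
    independent_group_test(da, db, grid, metric = "CC_norm",
                           model = "HQS", n_perm = 60, seed = 8, m = 3,
                           null_mode = "regenerate"))
  # both modes report a valid p, agree on the direction of the group
  # difference, and give similar evidence at this small scale
  for (r in list(fast, slow)) {
    expect_gt(r$p_value, 0)
    expect_lte(r$p_value, 1)
  }
  expect_identical(sign(fast$signed_area), sign(slow$signed_area))
  expect_lt(abs(fast$p_value - slow$p_value), 0.3)
})

test_that("the group test detects a planted attenuation far above the type-I rate", {
  # group 2 loses 90% of its between-block correlation: its thresholded
  # networks split into two near-cliques while group 1 stays mixed, a
  # clustering contrast the permutation test should catch most of the time
  grid <- density_grid(0.25, 0.05, 0.45, windows = list())
  ps <- vapply(1:12, function(run) {
    cfg <- simulation_config(n_subjects_per_group = c(30, 30), n_regions = 30,
                             n_blocks = 2, within_block_r = 0.6,
                             between_block_r = 0.5, group_effect = 0.1,
                             seed = 600 + run)
    d1 <- correct_regional_volumes(generate_group_morphometry(cfg, 1),
                                   covariate_names = character(0))
    d2 <- correct_regional_volumes(generate_group_morphometry(cfg, 2),
                                   covariate_names = character(0))
    independent_group_test(d1, d2, grid, metric = "CC", n_perm = 200,
                           seed = run)$p_value
  }, numeric(1))
  # under a true null, P(>= 5 rejections of 12 at alpha = .05) ~ 6e-5
  expect_gte(sum(ps <= 0.05), 5)
})

test_that("replicability analysis returns ANOVA and Levene reports and flags degenerate input", {
  fx <- block_fixture(n_subjects = 25L, n_regions = 20L, n_blocks = 2L,
                      seed = 51)
  rep_out <- replicability_analysis(fx$assoc, fx$data, density = 0.3,
                                    n_sets = 3, m = 5, seed = 2)
  expect_setequal(unique(rep_out$table$model), c("TOP", "HQS", "COR"))
  expect_equal(nrow(rep_out$table), 3 * 3 * 5)
  for (mod in c("TOP", "HQS", "COR")) {
    p <- rep_out$anova[[mod]]$C_null$p
    expect_true(is.na(p) || (p > 0 && p <= 1))
  }
  expect_false(rep_out$levene$C_null$degenerate)
  expect_gt(rep_out$levene$C_null$W, 0)

  # complete graph: every TOP "null" equals the target, zero variance
  cfg <- simulation_config(n_subjects_per_group = c(10, 3), n_regions = 5,
                           n_blocks = 1, within_block_r = 0.9,
                           between_block_r = 0.1, seed = 1)
  dat <- correct_regional_volumes(generate_group_morphometry(cfg, 1),
                                  covariate_names = character(0))
  A <- association_matrix(dat)
  deg <- suppressWarnings(
    replicability_analysis(A, dat, density = 1, models = "TOP",
                           n_sets = 2, m = 2, seed = 1))
  expect_true(deg$anova$TOP$C_null$degenerate)
})

test_that("skewness correlation recovers an injected linear dependence", {
  set.seed(19)
  n <- 60
  skew <- rnorm(n)
  tab <- data.frame(
    skewness = skew,
    cc_norm_top = 2 - 0.3 * skew + rnorm(n, 0, 0.05),
    cc_norm_hqs = 1.2 + rnorm(n, 0, 0.05),
    sw_top = 1.8 - 0.25 * skew + rnorm(n, 0, 0.05),
    sw_hqs = 1.1 + rnorm(n, 0, 0.05),
    c_null_top = 0.3 + 0.1 * skew + rnorm(n, 0, 0.02))
  out <- skewness_correlation(tab)
  r_cc <- out$r[out$comparison == "cc_norm_top_minus_hqs"]
  expect_lt(r_cc, -0.7)
  r_cn <- out$r[out$comparison == "c_null_top"]
  expect_gt(r_cn, 0.7)
  expect_true(all(out$n == n))

  tab$cc_norm_hqs <- tab$cc_norm_top  # constant difference
  expect_error(skewness_correlation(tab), "constant")
  expect_error(skewness_correlation(tab[1:5, ]), "10 networks")
})
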