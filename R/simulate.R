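#' Configuration for the two-group synthetic morphometry generator
#'
#' Defines the generative model for subject-by-region regional volume tables:
#' a multivariate normal with a block-constant (compound symmetry within
#' blocks) region-by-region correlation matrix, linear nuisance-covariate
#' effects (age, sex, total-volume proxy), and a multiplicative attenuation
#' of the between-block correlation in group 2 that acts as the group effect.
#'
#' The defaults emulate the cohort scale of a pediatric structural-covariance
#' study: two groups of 31 and 28 subjects, 90 regions grouped into 6
#' correlation blocks with within-block r = 0.5 and between-block r = 0.1 —
#' strong enough community structure that thresholded networks are clustered
#' well above degree-matched random graphs.
#'
#' @param n_subjects_per_group integer pair, subjects in groups 1 and 2
#' @param n_regions number of regions (columns)
#' @param n_blocks number of correlation blocks; regions are split evenly,
#'   remainder assigned to the last block
#' @param within_block_r correlation inside a block, in `[0, 1)`
#' @param between_block_r correlation between blocks, in `[0, 1)`; must not
#'   exceed `within_block_r`
#' @param group_effect multiplicative attenuation in `(0, 1]` applied to
#'   group 2's between-block correlation (1 = no group difference)
#' @param covariate_effects named numeric vector of slopes (volume units per
#'   covariate unit) for `age`, `sex`, `tbv`; applied uniformly to all regions
#' @param noise_sd marginal standard deviation of regional volumes
#' @param seed integer seed governing all draws
#' @return a `simulation_config` list
#' @export
simulation_config <- function(n_subjects_per_group = c(31L, 28L),
                              n_regions = 90L,
                              n_blocks = 6L,
                              within_block_r = 0.5,
                              between_block_r = 0.1,
                              group_effect = 1,
                              covariate_effects = c(age = 0, sex = 0, tbv = 0),
                              noise_sd = 1,
                              seed = 1L) {
  stopifnot(length(n_subjects_per_group) == 2L,
            all(n_subjects_per_group >= 1),
            n_regions >= 1, n_blocks >= 1, n_blocks <= n_regions,
            within_block_r >= 0, within_block_r < 1,
            between_block_r >= 0, between_block_r < 1,
            group_effect > 0, group_effect <= 1,
            noise_sd > 0)
  if (within_block_r < between_block_r)
    stop("within_block_r must be >= between_block_r")
  stopifnot(all(c("age", "sex", "tbv") %in% names(covariate_effects)))
  cfg <- list(n_subjects_per_group = as.integer(n_subjects_per_group),
              n_regions = as.integer(n_regions),
              n_blocks = as.integer(n_blocks),
              within_block_r = within_block_r,
              between_block_r = between_block_r,
              group_effect = group_effect,
              covariate_effects = covariate_effects,
              noise_sd = noise_sd,
              seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  # fail early on non-PSD parameter combinations
  build_target_correlation(cfg)
  cfg
}

# Region-to-block assignment: even split, remainder to the last block.
block_assignment <- function(n_regions, n_blocks) {
  base <- n_regions %/% n_blocks
  sizes <- rep(base, n_blocks)
  sizes[n_blocks] <- sizes[n_blocks] + n_regions %% n_blocks
  rep(seq_len(n_blocks), times = sizes)
}

#' Target region-by-region correlation matrix of the block model
#'
#' @param config a [simulation_config()]
#' @param group_index 1 or 2; group 2's between-block correlation is
#'   multiplied by `config$group_effect`
#' @return symmetric unit-diagonal correlation matrix, verified positive
#'   semidefinite (smallest eigenvalue >= -1e-8)
#' @export
build_target_correlation <- function(config, group_index = 1L) {
  stopifnot(inherits(config, "simulation_config") || is.list(config))
  p <- config$n_regions
  between <- config$between_block_r
  if (group_index == 2L) between <- between * config$group_effect
  blk <- block_assignment(p, config$n_blocks)
  R <- matrix(between, p, p)
  same <- outer(blk, blk, "==")
  R[same] <- config$within_block_r
  diag(R) <- 1
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop(sprintf("target correlation matrix is not PSD (smallest eigenvalue %.3e)",
                 min(ev)))
  R
}

#' Simulate one group's subject-by-region morphometry dataset
#'
#' Subjects are drawn from a multivariate normal with the (possibly
#' attenuated) block-model target correlation, scaled to `noise_sd` around a
#' baseline volume. Covariates (age uniform on a pediatric range, sex
#' Bernoulli(0.5), total-volume proxy normal) are drawn and their linear
#' effects added to every region per `covariate_effects`.
#'
#' @param config a [simulation_config()]
#' @param group_index 1 or 2
#' @return a `morphometry_dataset`: list with `values` (subject x region
#'   matrix), `region_names`, `subject_ids`, `covariates` (data.frame with
#'   `age`, `sex`, `tbv`), `group_index` and the `seed` used
#' @export
generate_group_morphometry <- function(config, group_index = 1L) {
  stopifnot(group_index %in% c(1L, 2L))
  n <- config$n_subjects_per_group[group_index]
  if (n < 3L)
    stop("at least 3 subjects are required (Pearson correlation downstream)")
  p <- config$n_regions
  R <- build_target_correlation(config, group_index)
  seed <- derive_seed(config$seed, group_index)
  with_seed(seed, {
    ed <- eigen(R, symmetric = TRUE)
    Rhalf <- ed$vectors %*% (sqrt(pmax(ed$values, 0)) * t(ed$vectors))
    values <- matrix(stats::rnorm(n * p), n, p) %*% Rhalf * config$noise_sd + 50
    age <- stats::runif(n, 4, 20)
    sex <- stats::rbinom(n, 1L, 0.5)
    tbv <- stats::rnorm(n, 1200, 100)
    eff <- config$covariate_effects
    shift <- eff[["age"]] * age + eff[["sex"]] * sex + eff[["tbv"]] * tbv
    values <- values + shift  # recycles down columns: per-subject shift
    region_names <- sprintf("R%03d", seq_len(p))
    subject_ids <- sprintf("G%d_S%03d", group_index, seq_len(n))
    dimnames(values) <- list(subject_ids, region_names)
    out <- list(values = values,
                region_names = region_names,
                subject_ids = subject_ids,
                covariates = data.frame(subject = subject_ids, age = age,
                                        sex = sex, tbv = tbv,
                                        stringsAsFactors = FALSE),
                group_index = group_index,
                seed = seed,
                config = config)
    class(out) <- "morphometry_dataset"
    out
  })
}

#' @export
print.morphometry_dataset <- function(x, ...) {
  cat(sprintf("morphometry_dataset: %d subjects x %d regions (group %d, seed %d)\n",
              nrow(x$values), ncol(x$values), x$group_index, x$seed))
  invisible(x)
}
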