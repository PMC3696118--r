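#' Pipeline configuration with study defaults
#'
#' Resolves all parameters and seeds of an end-to-end run. Study-scale
#' defaults follow the benchmarking design (300 bootstraps, 5000 dependent
#' shuffles, 1000 group permutations, 20 nulls per ensemble, density grid
#' `[0.22, 0.02, 0.50]` with four windows); the demo scale used in examples
#' and smoke runs reduces the resampling sizes.
#'
#' @param simulate a [simulation_config()] (or NULL when reading tables)
#' @param values_paths,covariates_paths length-2 character vectors of input
#'   CSVs when not simulating
#' @param grid a [density_grid()]
#' @param covariate_names covariates regressed out per region
#' @param m null networks per ensemble
#' @param n_boot bootstrap samples for the dependent model comparison
#' @param n_shuffle label shuffles in the dependent test
#' @param n_perm_group permutations in the independent group test
#' @param n_sets,m_repl replicability analysis: number of sets and set size
#' @param swaps_per_edge TOP swap budget per edge
#' @param fragment_policy disconnected-null policy
#' @param seed master seed; all stage seeds derive from it
#' @param output_dir artifact directory
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(simulate = simulation_config(),
                            values_paths = NULL, covariates_paths = NULL,
                            grid = density_grid(),
                            covariate_names = c("age", "sex", "tbv"),
                            m = 20L, n_boot = 300L, n_shuffle = 5000L,
                            n_perm_group = 1000L, n_sets = 50L, m_repl = 20L,
                            swaps_per_edge = 10, fragment_policy = "keep",
                            seed = 1L, output_dir = "results/pipeline") {
  cfg <- list(simulate = simulate, values_paths = values_paths,
              covariates_paths = covariates_paths, grid = grid,
              covariate_names = covariate_names, m = as.integer(m),
              n_boot = as.integer(n_boot), n_shuffle = as.integer(n_shuffle),
              n_perm_group = as.integer(n_perm_group),
              n_sets = as.integer(n_sets), m_repl = as.integer(m_repl),
              swaps_per_edge = swaps_per_edge,
              fragment_policy = fragment_policy,
              seed = as.integer(seed), output_dir = output_dir,
              stage_seeds = list(simulate = derive_seed(seed, 11L),
                                 bootstrap = derive_seed(seed, 12L),
                                 dependent = derive_seed(seed, 13L),
                                 independent = derive_seed(seed, 14L),
                                 replicability = derive_seed(seed, 15L),
                                 normalizers = derive_seed(seed, 16L)))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Dependent model comparison over all ranges in one shuffle pass
#'
#' Runs [dependent_model_test()] logic for one model pair and metric, but
#' evaluates the cumulative range and every grid window from a single set
#' of label shuffles (the shuffle signs are shared, so window results are
#' mutually consistent).
#'
#' @param bc a [bootstrap_model_curves()] result
#' @param model1,model2 models to compare
#' @param metric `"CC_norm"`, `"CPL_norm"` or `"SW"`
#' @param n_perm shuffles
#' @param seed integer seed
#' @return data.frame: `range`, `area`, `signed_area`, `p_value`
#' @export
dependent_model_scan <- function(bc, model1, model2, metric = "SW",
                                 n_perm = 5000L, seed = 1L) {
  stopifnot(inherits(bc, "bootstrap_curves"))
  D <- bc$curves[[model2]][[metric]] - bc$curves[[model1]][[metric]]
  n_boot <- nrow(D)
  densities <- bc$grid$densities
  M <- with_seed(seed, {
    S <- matrix(sample(c(-1, 1), n_perm * n_boot, replace = TRUE),
                n_perm, n_boot)
    S %*% D / n_boot
  })
  mbar <- colMeans(D)
  ranges <- c(list(cumulative = NULL),
              stats::setNames(bc$grid$windows,
                              paste0("w", seq_along(bc$grid$windows))))
  rows <- lapply(names(ranges), function(nm) {
    idx <- window_index(densities, ranges[[nm]])
    observed <- sum(abs(mbar[idx]))
    null_stat <- rowSums(abs(M[, idx, drop = FALSE]))
    data.frame(range = nm, area = observed, signed_area = sum(mbar[idx]),
               p_value = (sum(null_stat >= observed - 1e-12) + 1) / (n_perm + 1),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Independent group comparison across metrics, models and ranges
#'
#' One permutation pass computes raw clustering and path-length curves for
#' every pseudo-group pair; all requested metrics (raw and normalized via
#' fixed pooled null-mean curves, the approximate `"reuse"` mode) and all
#' ranges (cumulative plus windows) are then evaluated from the same
#' permutations.
#'
#' @param data1,data2 `corrected_rgv` objects for the two groups
#' @param grid a [density_grid()]
#' @param models null models for the normalized metrics
#' @param n_perm permutations
#' @param seed integer seed
#' @param m nulls per ensemble for the pooled normalizer curves
#' @param swaps_per_edge TOP swap budget
#' @return data.frame: `metric`, `model`, `range`, `area`, `signed_area`,
#'   `p_value`
#' @export
group_comparison_scan <- function(data1, data2, grid = density_grid(),
                                  models = c("TOP", "HQS", "COR"),
                                  n_perm = 1000L, seed = 1L, m = 20L,
                                  swaps_per_edge = 10) {
  v1 <- data1$residuals; v2 <- data2$residuals
  n1 <- nrow(v1); n2 <- nrow(v2)
  stopifnot(n1 >= 3L, n2 >= 3L)
  densities <- grid$densities
  G_len <- length(densities)
  pooled <- rbind(v1, v2)

  # fixed pooled normalizer curves per model (reuse mode)
  A_pool <- association_matrix(pooled)
  pool_data <- structure(list(residuals = pooled), class = "corrected_rgv")
  norms <- list()
  for (mod in models) {
    Cn <- Ln <- numeric(G_len)
    for (k in seq_len(G_len)) {
      G <- threshold_by_density(A_pool, densities[k])
      target <- switch(mod, TOP = G, HQS = A_pool, COR = pool_data)
      ens <- null_ensemble(target, model = mod, m = m,
                           seed = derive_seed(seed, 900L + k),
                           density = densities[k],
                           swaps_per_edge = swaps_per_edge)
      Cn[k] <- ens$C_null_mean; Ln[k] <- ens$L_null_mean
    }
    norms[[mod]] <- list(Cn = Cn, Ln = Ln)
  }

  raw_pair <- function(va, vb) {
    list(a = raw_metric_curves(stats::cor(va), densities, compute_cpl = TRUE),
         b = raw_metric_curves(stats::cor(vb), densities, compute_cpl = TRUE))
  }
  obs <- raw_pair(v1, v2)
  perms <- vector("list", n_perm)
  for (t in seq_len(n_perm)) {
    pm <- with_seed(derive_seed(seed, t), sample.int(n1 + n2))
    perms[[t]] <- raw_pair(pooled[pm[seq_len(n1)], , drop = FALSE],
                           pooled[pm[n1 + seq_len(n2)], , drop = FALSE])
  }

  metric_values <- function(raw, metric, mod) {
    switch(metric,
           CC = raw$CC, CPL = raw$CPL,
           CC_norm = raw$CC / norms[[mod]]$Cn,
           CPL_norm = raw$CPL / norms[[mod]]$Ln,
           SW = (raw$CC / norms[[mod]]$Cn) / (raw$CPL / norms[[mod]]$Ln))
  }
  ranges <- c(list(cumulative = NULL),
              stats::setNames(grid$windows,
                              paste0("w", seq_along(grid$windows))))
  specs <- rbind(data.frame(metric = c("CC", "CPL"), model = "none",
                            stringsAsFactors = FALSE),
                 expand.grid(metric = c("CC_norm", "CPL_norm", "SW"),
                             model = models, stringsAsFactors = FALSE))
  rows <- list()
  for (si in seq_len(nrow(specs))) {
    met <- specs$metric[si]; mod <- specs$model[si]
    d_obs <- metric_values(obs$b, met, mod) - metric_values(obs$a, met, mod)
    d_null <- vapply(perms, function(pp) {
      metric_values(pp$b, met, mod) - metric_values(pp$a, met, mod)
    }, numeric(G_len))
    for (nm in names(ranges)) {
      idx <- window_index(densities, ranges[[nm]])
      a_obs <- sum(abs(d_obs[idx]))
      a_null <- colSums(abs(d_null[idx, , drop = FALSE]))
      rows[[length(rows) + 1L]] <- data.frame(
        metric = met, model = mod, range = nm, area = a_obs,
        signed_area = sum(d_obs[idx]),
        p_value = (sum(a_null >= a_obs - 1e-12) + 1) / (n_perm + 1),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

log_line <- function(log_path, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                 paste0(...))
  cat(msg, "\n", sep = "")
  cat(msg, "\n", sep = "", file = log_path, append = TRUE)
}

#' Run the full benchmarking pipeline
#'
#' Executes simulate (optional) -> covariate correction -> association
#' matrices -> D_min -> small-world curves per null model -> dependent
#' model comparison -> independent group comparison (cumulative and
#' windowed) -> replicability and skewness analyses, writing every artifact
#' (with embedded seeds) plus the resolved configuration and a log to the
#' output directory.
#'
#' @param config a [pipeline_config()]
#' @return invisibly, a list with the in-memory results and artifact paths
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "log.txt")
  cat("", file = log_path)
  paths <- list(log = log_path)
  stage <- "configuration"
  result <- tryCatch({
    grid <- config$grid

    stage <- "input"
    if (!is.null(config$simulate)) {
      log_line(log_path, "simulating two groups (seed ",
               config$simulate$seed, ")")
      groups <- lapply(1:2, function(g)
        generate_group_morphometry(config$simulate, g))
    } else {
      log_line(log_path, "reading morphometry tables")
      groups <- lapply(1:2, function(g)
        read_morphometry_table(config$values_paths[g],
                               config$covariates_paths[g]))
    }
    for (g in 1:2) {
      paths[[paste0("values", g)]] <- file.path(out_dir,
                                                sprintf("group%d_values.csv", g))
      paths[[paste0("covariates", g)]] <-
        file.path(out_dir, sprintf("group%d_covariates.csv", g))
      write_morphometry_table(groups[[g]], paths[[paste0("values", g)]],
                              paths[[paste0("covariates", g)]])
    }

    stage <- "covariate correction"
    corrected <- lapply(groups, correct_regional_volumes,
                        covariate_names = config$covariate_names)

    stage <- "network construction"
    assoc <- lapply(corrected, association_matrix)
    for (g in 1:2) {
      p <- file.path(out_dir, sprintf("association_group%d.csv", g))
      write_association(assoc[[g]], p)
      paths[[paste0("association", g)]] <- p
      log_line(log_path, sprintf("association matrix group %d written (md5 %s)",
                                 g, unname(tools::md5sum(p))))
    }
    d_min <- minimum_connected_density(assoc, grid)
    log_line(log_path, "D_min = ", format(d_min))
    if (d_min > grid$start) {
      windows <- Filter(function(w) w[2] > d_min, grid$windows)
      windows <- lapply(windows, function(w) c(max(w[1], d_min), w[2]))
      grid <- density_grid(d_min, grid$step, grid$stop, windows)
      log_line(log_path, "grid start raised to D_min")
    }

    stage <- "small-world curves"
    curves <- list()
    for (g in 1:2) {
      for (met in c("CC", "CPL")) {
        curves[[length(curves) + 1L]] <-
          metric_curve(assoc[[g]], grid, met,
                       group_label = sprintf("group%d", g))
      }
      for (mod in c("TOP", "HQS", "COR")) {
        sw_curves <- small_world_curves(
          assoc[[g]], grid, model = mod, m = config$m,
          seed = derive_seed(config$stage_seeds$normalizers, g),
          data = corrected[[g]], group_label = sprintf("group%d", g),
          swaps_per_edge = config$swaps_per_edge)
        curves <- c(curves, sw_curves)
      }
    }
    paths$curves <- file.path(out_dir, "curves.csv")
    write_curves(curves, paths$curves)
    log_line(log_path, "curve table written: ", paths$curves)

    stage <- "dependent model comparison"
    bc <- bootstrap_model_curves(corrected[[1]], grid,
                                 models = c("TOP", "HQS", "COR"),
                                 m = config$m, n_boot = config$n_boot,
                                 seed = config$stage_seeds$bootstrap,
                                 swaps_per_edge = config$swaps_per_edge,
                                 group_label = "group1")
    pairs <- list(c("TOP", "HQS"), c("TOP", "COR"), c("HQS", "COR"))
    dep_rows <- list()
    for (pr in pairs) {
      for (met in c("CC_norm", "CPL_norm", "SW")) {
        sc <- dependent_model_scan(bc, pr[1], pr[2], metric = met,
                                   n_perm = config$n_shuffle,
                                   seed = config$stage_seeds$dependent)
        sc$model1 <- pr[1]; sc$model2 <- pr[2]; sc$metric <- met
        dep_rows[[length(dep_rows) + 1L]] <- sc
      }
    }
    dep <- do.call(rbind, dep_rows)
    # Bonferroni across the model pairs and metrics, within each range
    dep$p_bonferroni <- stats::ave(dep$p_value, dep$range,
                                   FUN = adjust_bonferroni)
    paths$model_comparison <- file.path(out_dir, "model_comparison.json")
    jsonlite::write_json(list(seed = config$stage_seeds$dependent,
                              n_boot = config$n_boot,
                              n_shuffle = config$n_shuffle,
                              results = dep),
                         paths$model_comparison, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    log_line(log_path, "dependent model comparison written")

    stage <- "independent group comparison"
    grp <- group_comparison_scan(corrected[[1]], corrected[[2]], grid,
                                 models = c("TOP", "HQS", "COR"),
                                 n_perm = config$n_perm_group,
                                 seed = config$stage_seeds$independent,
                                 m = config$m,
                                 swaps_per_edge = config$swaps_per_edge)
    paths$group_comparison <- file.path(out_dir, "group_comparison.json")
    jsonlite::write_json(list(seed = config$stage_seeds$independent,
                              n_perm = config$n_perm_group,
                              null_mode = "reuse (approximate)",
                              results = grp),
                         paths$group_comparison, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    log_line(log_path, "independent group comparison written")

    stage <- "replicability analysis"
    repl <- replicability_analysis(assoc[[1]], corrected[[1]],
                                   density = grid$start,
                                   n_sets = config$n_sets, m = config$m_repl,
                                   seed = config$stage_seeds$replicability,
                                   swaps_per_edge = config$swaps_per_edge)
    paths$replicability <- file.path(out_dir, "replicability.json")
    jsonlite::write_json(list(seed = repl$seed, density = repl$density,
                              n_sets = repl$n_sets, m = repl$m,
                              anova = repl$anova, levene = repl$levene),
                         paths$replicability, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    log_line(log_path, "replicability analysis written")

    stage <- "skewness correlation"
    skew <- skewness_correlation(bc$dmin_table)
    paths$skewness <- file.path(out_dir, "skewness_correlation.json")
    jsonlite::write_json(list(seed = config$stage_seeds$bootstrap,
                              density = grid$start, results = skew),
                         paths$skewness, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    log_line(log_path, "skewness correlation written")

    stage <- "configuration dump"
    paths$config <- file.path(out_dir, "config_resolved.json")
    cfg_out <- config
    cfg_out$grid <- grid[c("start", "step", "stop", "windows")]
    cfg_out$simulate <- unclass(config$simulate)
    jsonlite::write_json(unclass(cfg_out), paths$config, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, force = TRUE)
    log_line(log_path, "pipeline complete")

    list(groups = groups, corrected = corrected, assoc = assoc,
         d_min = d_min, grid = grid, curves = curves, bootstrap = bc,
         model_comparison = dep, group_comparison = grp,
         replicability = repl, skewness = skew, paths = paths)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}
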