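new_metric_curve <- function(densities, values, metric, model = "none",
                             group_label = NA_character_) {
  stopifnot(length(densities) == length(values), !anyNA(values))
  structure(list(densities = densities, values = values, metric = metric,
                 model = model, group_label = group_label),
            class = "metric_curve")
}

# Indices of grid points falling inside a window c(lo, hi); NULL = all.
window_index <- function(densities, window) {
  if (is.null(window)) return(seq_along(densities))
  stopifnot(length(window) == 2L, window[1] <= window[2])
  idx <- which(densities >= window[1] - 1e-9 & densities <= window[2] + 1e-9)
  if (length(idx) == 0L) stop("window contains no grid densities")
  idx
}

# Fast cumulative raw-metric curves over a density grid: edges are ranked
# once and added incrementally (nestedness), CC by dense matrix products,
# CPL by igraph BFS. Used inside resampling loops.
raw_metric_curves <- function(r, densities, compute_cpl = TRUE) {
  n <- nrow(r)
  n_pairs <- n * (n - 1) / 2
  rk <- edge_ranking(r)
  Es <- pmin(round_half_up(densities * n_pairs), n_pairs)
  adj <- matrix(0, n, n)
  cc <- numeric(length(densities))
  cpl <- rep(NA_real_, length(densities))
  prev <- 0L
  for (k in seq_along(densities)) {
    E <- Es[k]
    if (E > prev) {
      idx <- (prev + 1L):E
      adj[cbind(rk$i[idx], rk$j[idx])] <- 1
      adj[cbind(rk$j[idx], rk$i[idx])] <- 1
      prev <- E
    }
    cc[k] <- cc_from_adjacency(adj)
    if (compute_cpl) cpl[k] <- as.numeric(characteristic_path_length(adj))
  }
  list(CC = cc, CPL = cpl)
}

#' Metric-versus-density curve for one network and null model
#'
#' Samples a network metric over the densities of a grid. Raw metrics
#' (`"CC"`, `"CPL"`) need no null model; normalized metrics (`"CC_norm"`,
#' `"CPL_norm"`, `"SW"`) generate one null ensemble per density.
#'
#' @param A an `association_matrix`
#' @param grid a [density_grid()]
#' @param metric one of `"CC"`, `"CPL"`, `"CC_norm"`, `"CPL_norm"`, `"SW"`
#' @param model null model for normalized metrics (`"TOP"`, `"HQS"`,
#'   `"COR"`)
#' @param m null networks per density
#' @param seed integer seed
#' @param data `corrected_rgv` backing `A`; required for `model = "COR"`
#' @param group_label optional label carried on the curve
#' @param swaps_per_edge TOP swap budget
#' @return a `metric_curve`
#' @export
metric_curve <- function(A, grid = density_grid(), metric = "CC",
                         model = c("none", "TOP", "HQS", "COR"), m = 20L,
                         seed = 1L, data = NULL, group_label = NA_character_,
                         swaps_per_edge = 10) {
  model <- match.arg(model)
  metric <- match.arg(metric, c("CC", "CPL", "CC_norm", "CPL_norm", "SW"))
  densities <- grid$densities
  if (metric %in% c("CC", "CPL")) {
    raw <- raw_metric_curves(A$r, densities, compute_cpl = metric == "CPL")
    return(new_metric_curve(densities, raw[[metric]], metric, "none", group_label))
  }
  if (model == "none") stop("normalized metrics require a null model")
  if (model == "COR" && is.null(data))
    stop("COR null ensembles require the corrected data behind the association matrix")
  vals <- numeric(length(densities))
  for (k in seq_along(densities)) {
    G <- threshold_by_density(A, densities[k])
    target <- switch(model, TOP = G, HQS = A, COR = data)
    ens <- null_ensemble(target, model = model, m = m,
                         seed = derive_seed(seed, k), density = densities[k],
                         swaps_per_edge = swaps_per_edge)
    sw <- small_world_params(G, ens)
    vals[k] <- switch(metric, CC_norm = sw$gamma, CPL_norm = sw$lambda,
                      SW = sw$sigma_sw)
  }
  new_metric_curve(densities, vals, metric, model, group_label)
}

#' All three normalized small-world curves in one ensemble pass
#'
#' Computes `CC_norm`, `CPL_norm` and `SW` curves for one association
#' matrix and null model, generating a single null ensemble per density
#' (the three metrics share the same nulls, as they do in the study design).
#'
#' @inheritParams metric_curve
#' @param swaps_per_edge TOP swap budget
#' @return named list of three `metric_curve` objects
#' @export
small_world_curves <- function(A, grid = density_grid(),
                               model = c("TOP", "HQS", "COR"), m = 20L,
                               seed = 1L, data = NULL,
                               group_label = NA_character_,
                               swaps_per_edge = 10) {
  model <- match.arg(model)
  if (model == "COR" && is.null(data))
    stop("COR null ensembles require the corrected data behind the association matrix")
  densities <- grid$densities
  vals <- matrix(NA_real_, 3L, length(densities),
                 dimnames = list(c("CC_norm", "CPL_norm", "SW"), NULL))
  for (k in seq_along(densities)) {
    G <- threshold_by_density(A, densities[k])
    target <- switch(model, TOP = G, HQS = A, COR = data)
    ens <- null_ensemble(target, model = model, m = m,
                         seed = derive_seed(seed, k), density = densities[k],
                         swaps_per_edge = swaps_per_edge)
    sw <- small_world_params(G, ens)
    vals[, k] <- c(sw$gamma, sw$lambda, sw$sigma_sw)
  }
  out <- lapply(rownames(vals), function(met)
    new_metric_curve(densities, vals[met, ], met, model, group_label))
  names(out) <- rownames(vals)
  out
}

#' Area between two metric curves (FDA statistic)
#'
#' The functional-data-analysis area statistic: the sum over grid points of
#' absolute differences between two metric-versus-density curves,
#' `A = sum_i |y2(x_i) - y1(x_i)|`, optionally restricted to a density
#' window. The signed sum is returned alongside for direction reporting.
#'
#' @param c1,c2 `metric_curve` objects on identical grids, or plain numeric
#'   vectors of equal length (then supply `densities` to use a window)
#' @param window optional `c(lo, hi)` density sub-range
#' @param densities grid densities when `c1`, `c2` are plain vectors
#' @return list with `area` (>= 0) and `signed_area` (`sum(y2 - y1)`)
#' @export
fda_area <- function(c1, c2, window = NULL, densities = NULL) {
  if (inherits(c1, "metric_curve")) {
    densities <- c1$densities
    if (!inherits(c2, "metric_curve") ||
        length(c2$densities) != length(densities) ||
        any(abs(c2$densities - densities) > 1e-9))
      stop("mismatched grids")
    y1 <- c1$values; y2 <- c2$values
  } else {
    y1 <- c1; y2 <- c2
    if (length(y1) != length(y2)) stop("mismatched grids")
  }
  idx <- if (is.null(densities)) seq_along(y1) else window_index(densities, window)
  if (!is.null(window) && is.null(densities))
    stop("a window requires grid densities")
  d <- y2[idx] - y1[idx]
  list(area = sum(abs(d)), signed_area = sum(d), window = window)
}

#' Bootstrap resamples of the association matrix
#'
#' Draws subjects with replacement (same n) and recomputes the Pearson
#' association matrix. Note that sampling with replacement inflates
#' correlations relative to the original matrix; this does not affect
#' comparisons made across null models on the same bootstrap samples.
#' A draw yielding a zero-variance region is redrawn (bounded).
#'
#' @param data a `corrected_rgv`
#' @param n_boot number of bootstrap samples
#' @param seed integer seed; sample `b` uses `derive_seed(seed, b)`
#' @return list of `association_matrix`, each carrying the subject index
#'   draw and its seed as attributes
#' @export
bootstrap_association <- function(data, n_boot = 300L, seed = 1L) {
  stopifnot(n_boot >= 1L)
  values <- data$residuals
  n <- nrow(values)
  lapply(seq_len(n_boot), function(b) {
    s <- derive_seed(seed, b)
    idx <- bootstrap_draw(values, s)
    A <- association_matrix(values[idx, , drop = FALSE])
    attr(A, "subject_idx") <- idx
    attr(A, "seed") <- s
    A
  })
}

# One bootstrap subject draw, redrawn (bounded) if any region would have
# zero variance in the resample.
bootstrap_draw <- function(values, seed, max_tries = 10L) {
  n <- nrow(values)
  for (t in seq_len(max_tries)) {
    idx <- with_seed(derive_seed(seed, t - 1L), sample.int(n, n, replace = TRUE))
    v <- apply(values[idx, , drop = FALSE], 2L, stats::var)
    if (all(v > 0)) return(idx)
  }
  stop("could not draw a bootstrap sample without zero-variance regions")
}

#' Per-bootstrap normalized metric curves for several null models
#'
#' The workhorse behind the dependent-samples model comparison: for each
#' bootstrap resample of the subjects, builds the association matrix,
#' thresholds it across the grid, generates null ensembles for each
#' requested model, and records normalized clustering, normalized path
#' length and small-world index curves. At the first grid density (D_min)
#' it also records each bootstrap network's degree skewness and, when TOP
#' is among the models, the clustering of its TOP nulls — the inputs of the
#' skewness correlation analysis.
#'
#' @param data a `corrected_rgv`
#' @param grid a [density_grid()]
#' @param models subset of `c("TOP", "HQS", "COR")`
#' @param m null networks per ensemble
#' @param n_boot bootstrap samples (study default 300)
#' @param seed integer seed
#' @param swaps_per_edge TOP swap budget
#' @param group_label optional label stored on the result
#' @return a `bootstrap_curves` object: `curves[[model]][[metric]]` are
#'   `n_boot` x `length(grid$densities)` matrices; `dmin_table` is the
#'   per-bootstrap table at the first density
#' @export
bootstrap_model_curves <- function(data, grid = density_grid(),
                                   models = c("TOP", "HQS", "COR"), m = 20L,
                                   n_boot = 300L, seed = 1L,
                                   swaps_per_edge = 10,
                                   group_label = NA_character_) {
  models <- match.arg(models, c("TOP", "HQS", "COR"), several.ok = TRUE)
  values <- data$residuals
  densities <- grid$densities
  G_len <- length(densities)
  metrics <- c("CC_norm", "CPL_norm", "SW")
  curves <- lapply(models, function(mod) {
    lapply(metrics, function(met) matrix(NA_real_, n_boot, G_len))
  })
  names(curves) <- models
  for (mod in models) names(curves[[mod]]) <- metrics
  dmin_rows <- vector("list", n_boot)
  for (b in seq_len(n_boot)) {
    seed_b <- derive_seed(seed, b)
    idx <- bootstrap_draw(values, seed_b)
    boot_values <- values[idx, , drop = FALSE]
    A_b <- association_matrix(boot_values)
    boot_data <- structure(list(residuals = boot_values), class = "corrected_rgv")
    row <- list(bootstrap = b, group = group_label)
    for (k in seq_len(G_len)) {
      G <- threshold_by_density(A_b, densities[k])
      if (k == 1L) row$skewness <- as.numeric(degree_skewness(G))
      for (mi in seq_along(models)) {
        mod <- models[mi]
        target <- switch(mod, TOP = G, HQS = A_b, COR = boot_data)
        ens <- null_ensemble(target, model = mod, m = m,
                             seed = derive_seed(seed_b, k * 10L + mi),
                             density = densities[k],
                             swaps_per_edge = swaps_per_edge)
        sw <- small_world_params(G, ens)
        curves[[mod]][["CC_norm"]][b, k] <- sw$gamma
        curves[[mod]][["CPL_norm"]][b, k] <- sw$lambda
        curves[[mod]][["SW"]][b, k] <- sw$sigma_sw
        if (k == 1L) {
          row[[paste0("cc_norm_", tolower(mod))]] <- sw$gamma
          row[[paste0("sw_", tolower(mod))]] <- sw$sigma_sw
          if (mod == "TOP") row$c_null_top <- ens$C_null_mean
        }
      }
    }
    dmin_rows[[b]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  structure(list(grid = grid, models = models, m = m, n_boot = n_boot,
                 seed = seed, curves = curves,
                 dmin_table = do.call(rbind, dmin_rows),
                 group_label = group_label),
            class = "bootstrap_curves")
}

new_fda_result <- function(area, signed_area, window, n_resamples, p_value,
                           null_dist, seed, statistic) {
  structure(list(area = area, signed_area = signed_area, window = window,
                 n_resamples = n_resamples, p_value = p_value,
                 null_quantiles = stats::quantile(null_dist,
                                                  c(0.5, 0.9, 0.95, 0.99)),
                 seed = seed, statistic = statistic,
                 p_convention = "(count >= observed + 1) / (n_resamples + 1)"),
            class = "fda_result")
}

#' @export
print.fda_result <- function(x, ...) {
  cat(sprintf("FDA area = %.4f (signed %.4f)%s; p = %.4f (%d resamples)\n",
              x$area, x$signed_area,
              if (is.null(x$window)) "" else sprintf(" in window [%.2f, %.2f]",
                                                     x$window[1], x$window[2]),
              x$p_value, x$n_resamples))
  invisible(x)
}

#' Dependent-samples comparison of two null models' curves
#'
#' Tests whether two null models yield different normalized-metric curves on
#' the same bootstrap samples. The observed statistic is the FDA area
#' between the two models' mean curves; the null distribution is built by
#' randomly swapping the two model labels within each bootstrap sample and
#' recomputing the statistic (study default 5000 shuffles); the p-value is
#' the add-one percentile position of the observed statistic.
#'
#' @param bc a [bootstrap_model_curves()] result (both models must share
#'   its bootstrap samples)
#' @param model1,model2 the two models to compare
#' @param metric `"CC_norm"`, `"CPL_norm"` or `"SW"`
#' @param n_perm label shuffles (default 5000)
#' @param window optional density window
#' @param seed integer seed
#' @param statistic `"mean_curve"` (L1 area between mean curves, default)
#'   or `"signed_area"` (absolute signed area of the mean difference curve)
#' @return an `fda_result`
#' @export
dependent_model_test <- function(bc, model1, model2, metric = "SW",
                                 n_perm = 5000L, window = NULL, seed = 1L,
                                 statistic = c("mean_curve", "signed_area")) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(bc, "bootstrap_curves"),
            model1 %in% bc$models, model2 %in% bc$models)
  if (n_perm < 100L) warning("n_perm < 100: p-value estimate is unstable")
  Y1 <- bc$curves[[model1]][[metric]]
  Y2 <- bc$curves[[model2]][[metric]]
  idx <- window_index(bc$grid$densities, window)
  D <- (Y2 - Y1)[, idx, drop = FALSE]
  n_boot <- nrow(D)
  stat_fun <- switch(statistic,
                     mean_curve = function(M) rowSums(abs(M)),
                     signed_area = function(M) abs(rowSums(M)))
  mbar <- colMeans(D)
  observed <- switch(statistic,
                     mean_curve = sum(abs(mbar)),
                     signed_area = abs(sum(mbar)))
  null_dist <- with_seed(seed, {
    S <- matrix(sample(c(-1, 1), n_perm * n_boot, replace = TRUE),
                n_perm, n_boot)
    stat_fun(S %*% D / n_boot)
  })
  p <- (sum(null_dist >= observed - 1e-12) + 1) / (n_perm + 1)
  new_fda_result(area = sum(abs(mbar)), signed_area = sum(mbar),
                 window = window, n_resamples = n_perm, p_value = p,
                 null_dist = null_dist, seed = seed, statistic = statistic)
}

#' Bonferroni adjustment across model pairs / metrics
#'
#' @param p numeric vector of p-values
#' @return adjusted p-values
#' @export
adjust_bonferroni <- function(p) stats::p.adjust(p, method = "bonferroni")

# Curves for one subject-by-region value matrix under the chosen metric,
# given fixed null normalizer curves (reuse mode) or NULL for raw metrics.
group_curve_values <- function(values, densities, metric, Cn = NULL, Ln = NULL) {
  need_cpl <- metric %in% c("CPL", "CPL_norm", "SW")
  raw <- raw_metric_curves(stats::cor(values), densities, compute_cpl = need_cpl)
  switch(metric,
         CC = raw$CC,
         CPL = raw$CPL,
         CC_norm = raw$CC / Cn,
         CPL_norm = raw$CPL / Ln,
         SW = (raw$CC / Cn) / (raw$CPL / Ln))
}

#' Independent-samples group comparison of metric curves
#'
#' Tests a between-group difference in a metric-versus-density curve with a
#' subject-relabeling permutation test (study default 1000 repetitions):
#' each permutation reassigns subjects to pseudo-groups of the original
#' sizes, rebuilds both association matrices, rethresholds across the grid
#' and recomputes the curves; the observed FDA area between the group curves
#' is placed on the resulting permutation distribution (add-one p-value).
#'
#' For normalized metrics two modes are available. `null_mode = "reuse"`
#' (default, approximate) normalizes every curve — observed and permuted —
#' by fixed null-mean curves computed once from the pooled data, so only raw
#' curves are recomputed per permutation. `null_mode = "regenerate"`
#' regenerates null ensembles for each pseudo-group in every permutation
#' (faithful but far more expensive).
#'
#' @param data1,data2 `corrected_rgv` objects for the two groups (disjoint
#'   subject sets)
#' @param grid a [density_grid()]
#' @param metric `"CC"`, `"CPL"`, `"CC_norm"`, `"CPL_norm"` or `"SW"`
#' @param model null model for normalized metrics
#' @param n_perm permutations (default 1000)
#' @param window optional density window
#' @param seed integer seed
#' @param m null networks per ensemble
#' @param null_mode `"reuse"` or `"regenerate"`
#' @param swaps_per_edge TOP swap budget
#' @return an `fda_result`; `signed_area > 0` means group 2 above group 1
#' @export
independent_group_test <- function(data1, data2, grid = density_grid(),
                                   metric = "CC",
                                   model = c("none", "TOP", "HQS", "COR"),
                                   n_perm = 1000L, window = NULL, seed = 1L,
                                   m = 20L, null_mode = c("reuse", "regenerate"),
                                   swaps_per_edge = 10) {
  model <- match.arg(model)
  null_mode <- match.arg(null_mode)
  metric <- match.arg(metric, c("CC", "CPL", "CC_norm", "CPL_norm", "SW"))
  v1 <- data1$residuals; v2 <- data2$residuals
  n1 <- nrow(v1); n2 <- nrow(v2)
  if (n1 < 3L || n2 < 3L) stop("each group needs at least 3 subjects")
  densities <- grid$densities
  idx <- window_index(densities, window)
  normalized <- metric %in% c("CC_norm", "CPL_norm", "SW")
  if (normalized && model == "none")
    stop("normalized metrics require a null model")
  pooled <- rbind(v1, v2)

  if (!normalized || null_mode == "reuse") {
    Cn <- Ln <- NULL
    if (normalized) {
      A_pool <- association_matrix(pooled)
      pool_data <- structure(list(residuals = pooled), class = "corrected_rgv")
      Cn <- Ln <- numeric(length(densities))
      for (k in seq_along(densities)) {
        G <- threshold_by_density(A_pool, densities[k])
        target <- switch(model, TOP = G, HQS = A_pool, COR = pool_data)
        ens <- null_ensemble(target, model = model, m = m,
                             seed = derive_seed(seed, 900L + k),
                             density = densities[k],
                             swaps_per_edge = swaps_per_edge)
        Cn[k] <- ens$C_null_mean; Ln[k] <- ens$L_null_mean
      }
    }
    curve_of <- function(values) group_curve_values(values, densities, metric, Cn, Ln)
  } else {
    curve_of <- function(values, stream = 0L) {
      A <- association_matrix(values)
      dat <- structure(list(residuals = values), class = "corrected_rgv")
      vals <- numeric(length(densities))
      for (k in seq_along(densities)) {
        G <- threshold_by_density(A, densities[k])
        target <- switch(model, TOP = G, HQS = A, COR = dat)
        ens <- null_ensemble(target, model = model, m = m,
                             seed = derive_seed(seed, stream * 1000L + k),
                             density = densities[k],
                             swaps_per_edge = swaps_per_edge)
        sw <- small_world_params(G, ens)
        vals[k] <- switch(metric, CC_norm = sw$gamma, CPL_norm = sw$lambda,
                          SW = sw$sigma_sw)
      }
      vals
    }
  }

  if (n_perm < 100L) warning("n_perm < 100: p-value estimate is unstable")
  observed_c1 <- curve_of(v1)
  observed_c2 <- curve_of(v2)
  obs <- fda_area(observed_c1[idx], observed_c2[idx])
  null_dist <- numeric(n_perm)
  for (t in seq_len(n_perm)) {
    perm <- with_seed(derive_seed(seed, t), sample.int(n1 + n2))
    p1 <- pooled[perm[seq_len(n1)], , drop = FALSE]
    p2 <- pooled[perm[n1 + seq_len(n2)], , drop = FALSE]
    c1 <- if (normalized && null_mode == "regenerate") curve_of(p1, stream = t)
          else curve_of(p1)
    c2 <- if (normalized && null_mode == "regenerate") curve_of(p2, stream = t)
          else curve_of(p2)
    null_dist[t] <- sum(abs(c2[idx] - c1[idx]))
  }
  p <- (sum(null_dist >= obs$area - 1e-12) + 1) / (n_perm + 1)
  out <- new_fda_result(area = obs$area, signed_area = obs$signed_area,
                        window = window, n_resamples = n_perm, p_value = p,
                        null_dist = null_dist, seed = seed,
                        statistic = if (normalized) paste0("fda_", null_mode)
                                    else "fda")
  out$metric <- metric; out$model <- model
  out
}

#' Replicability of null-ensemble parameters
#'
#' Generates `n_sets` independent ensembles of `m` null networks per model
#' for one target network and asks (i) whether the per-set mean `C_null`
#' and `L_null` differ between sets within a model (one-way ANOVA over
#' sets), and (ii) whether the dispersion of the per-member values differs
#' between models (Levene's test).
#'
#' @param A an `association_matrix`
#' @param data a `corrected_rgv` (needed when `"COR"` is among the models)
#' @param density target density (typically D_min)
#' @param models subset of `c("TOP", "HQS", "COR")`
#' @param n_sets number of ensemble sets (study default 50)
#' @param m ensemble size (study default 20)
#' @param seed integer seed
#' @param swaps_per_edge TOP swap budget
#' @return a list with the long per-member `table`, per-model `anova`
#'   results (F and p for C_null and L_null), and `levene` results (W and p
#'   across models)
#' @export
replicability_analysis <- function(A, data = NULL, density = 0.22,
                                   models = c("TOP", "HQS", "COR"),
                                   n_sets = 50L, m = 20L, seed = 1L,
                                   swaps_per_edge = 10) {
  stopifnot(n_sets >= 2L, m >= 2L)
  models <- match.arg(models, c("TOP", "HQS", "COR"), several.ok = TRUE)
  if ("COR" %in% models && is.null(data))
    stop("COR ensembles require the corrected data")
  G <- threshold_by_density(A, density)
  rows <- list()
  for (mi in seq_along(models)) {
    mod <- models[mi]
    target <- switch(mod, TOP = G, HQS = A, COR = data)
    for (s in seq_len(n_sets)) {
      ens <- null_ensemble(target, model = mod, m = m,
                           seed = derive_seed(seed, mi * 10000L + s),
                           density = density, swaps_per_edge = swaps_per_edge)
      rows[[length(rows) + 1L]] <- data.frame(
        model = mod, set = s, member = seq_len(m),
        C_null = ens$C_null_values, L_null = ens$L_null_values,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  anova_res <- lapply(stats::setNames(models, models), function(mod) {
    sub <- tab[tab$model == mod, ]
    out <- list()
    for (met in c("C_null", "L_null")) {
      y <- sub[[met]]
      if (stats::var(y) == 0) {
        out[[met]] <- list(F = NA_real_, p = NA_real_, degenerate = TRUE)
      } else {
        fit <- stats::oneway.test(y ~ factor(sub$set), var.equal = TRUE)
        out[[met]] <- list(F = unname(fit$statistic), p = fit$p.value,
                           degenerate = FALSE)
      }
    }
    out
  })
  levene_res <- lapply(stats::setNames(c("C_null", "L_null"),
                                       c("C_null", "L_null")), function(met) {
    y <- tab[[met]]
    if (stats::var(y) == 0 || length(unique(tab$model)) < 2L)
      return(list(W = NA_real_, p = NA_real_, degenerate = TRUE))
    lt <- car::leveneTest(y ~ factor(tab$model))
    list(W = lt[1, "F value"], p = lt[1, "Pr(>F)"], degenerate = FALSE)
  })
  list(table = tab, anova = anova_res, levene = levene_res,
       density = density, n_sets = n_sets, m = m, seed = seed)
}

#' Correlation between degree skewness and between-model metric differences
#'
#' Pearson correlations between the degree-distribution skewness of
#' bootstrap networks (at D_min) and (i) the per-network differences in
#' normalized clustering and small-world index between TOP and the other
#' null models, and (ii) the clustering coefficient of the corresponding
#' TOP null networks.
#'
#' @param tab the `dmin_table` of a [bootstrap_model_curves()] result (rows
#'   from several groups may be stacked with `rbind`)
#' @return data.frame with one row per comparison: `comparison`, `r`,
#'   `p_value`, `n`
#' @export
skewness_correlation <- function(tab) {
  stopifnot(is.data.frame(tab), "skewness" %in% colnames(tab))
  if (nrow(tab) < 10L) stop("at least 10 networks are required")
  if (stats::sd(tab$skewness) == 0) stop("degree skewness is constant across networks")
  targets <- list()
  add_diff <- function(name, a, b) {
    if (all(c(a, b) %in% colnames(tab))) targets[[name]] <<- tab[[a]] - tab[[b]]
  }
  add_diff("cc_norm_top_minus_hqs", "cc_norm_top", "cc_norm_hqs")
  add_diff("cc_norm_top_minus_cor", "cc_norm_top", "cc_norm_cor")
  add_diff("sw_top_minus_hqs", "sw_top", "sw_hqs")
  add_diff("sw_top_minus_cor", "sw_top", "sw_cor")
  if ("c_null_top" %in% colnames(tab)) targets[["c_null_top"]] <- tab$c_null_top
  if (length(targets) == 0L) stop("no comparable metric columns found")
  rows <- lapply(names(targets), function(nm) {
    y <- targets[[nm]]
    if (stats::sd(y) == 0)
      stop(sprintf("metric '%s' is constant across networks; correlation undefined", nm))
    ct <- stats::cor.test(tab$skewness, y)
    data.frame(comparison = nm, r = unname(ct$estimate),
               p_value = ct$p.value, n = nrow(tab),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
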