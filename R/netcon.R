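#' Density grid and analysis windows
#'
#' The default grid `[0.22, 0.02, 0.50]` with four windows
#' `[0.22,0.30] [0.30,0.38] [0.38,0.46] [0.46,0.50]` is the standard
#' setting for structural correlation networks: below ~0.22 group networks
#' tend to fragment, above 0.5 they become increasingly random and edges are
#' less likely biological.
#'
#' @param start,step,stop densities in (0, 1]
#' @param windows list of `c(lo, hi)` sub-ranges, all within `[start, stop]`
#' @return a `density_grid` with a `densities` vector
#' @export
density_grid <- function(start = 0.22, step = 0.02, stop = 0.50,
                         windows = list(c(0.22, 0.30), c(0.30, 0.38),
                                        c(0.38, 0.46), c(0.46, 0.50))) {
  stopifnot(start > 0, stop <= 1, start <= stop, step > 0)
  densities <- seq(start, stop, by = step)
  for (w in windows) {
    stopifnot(length(w) == 2L, w[1] <= w[2])
    if (w[1] < start - 1e-9 || w[2] > stop + 1e-9)
      stop("window outside the grid range")
  }
  structure(list(start = start, step = step, stop = stop,
                 densities = densities, windows = windows),
            class = "density_grid")
}

#' Pearson association matrix of corrected regional volumes
#'
#' @param data a `corrected_rgv` (or a plain subject-by-region matrix)
#' @return an `association_matrix`: list with `r` (region-by-region Pearson
#'   correlations), `cov` (the covariance twin used by the HQS null),
#'   `n_subjects`, `region_names`
#' @export
association_matrix <- function(data) {
  values <- if (is.matrix(data)) data else data$residuals %||% data$values
  stopifnot(is.matrix(values))
  if (nrow(values) < 3L) stop("at least 3 subjects are required")
  sds <- apply(values, 2L, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(values)[sds == 0] %||% which(sds == 0)
    stop("zero-variance region(s): ", paste(bad, collapse = ", "))
  }
  r <- stats::cor(values)
  out <- list(r = r, cov = stats::cov(values), n_subjects = nrow(values),
              region_names = colnames(values))
  class(out) <- "association_matrix"
  out
}

# Off-diagonal pairs of a symmetric matrix ranked by signed value
# (largest first), ties broken by lexicographic (i, j) node-index pair.
# Returns i, j, value in rank order.
edge_ranking <- function(r) {
  ut <- upper.tri(r)
  ii <- row(r)[ut]; jj <- col(r)[ut]; vals <- r[ut]
  ord <- order(-vals, ii, jj)
  list(i = ii[ord], j = jj[ord], value = vals[ord])
}

new_binary_network <- function(adjacency, threshold_kind, threshold_value,
                               provenance, region_names = NULL) {
  n <- nrow(adjacency)
  structure(list(adjacency = adjacency,
                 density = sum(adjacency) / (n * (n - 1)),
                 threshold_kind = threshold_kind,
                 threshold_value = threshold_value,
                 provenance = provenance,
                 region_names = region_names %||% rownames(adjacency)),
            class = "binary_network")
}

# Internal: threshold a symmetric matrix at density d. Keeps the
# round(d * n(n-1)/2) strongest (signed) entries; half-away-from-zero
# rounding; nested in d by construction.
threshold_matrix_density <- function(r, d, provenance = "empirical",
                                     region_names = NULL) {
  stopifnot(d > 0, d <= 1)
  n <- nrow(r)
  n_pairs <- n * (n - 1) / 2
  E <- round_half_up(d * n_pairs)
  if (E == 0) stop("requested density yields zero edges after rounding")
  rk <- edge_ranking(r)
  adj <- matrix(0L, n, n)
  keep <- seq_len(E)
  adj[cbind(rk$i[keep], rk$j[keep])] <- 1L
  adj[cbind(rk$j[keep], rk$i[keep])] <- 1L
  dimnames(adj) <- list(region_names, region_names)
  new_binary_network(adj, "density", d, provenance, region_names)
}

#' Threshold an association matrix at a fixed network density
#'
#' Retains the `round(d * n(n-1)/2)` region pairs with the largest signed
#' correlation; edge sets are nested across densities from the same matrix.
#' Ties are broken deterministically (higher r first, then lexicographic
#' node-index pair).
#'
#' @param A an `association_matrix` (or plain symmetric matrix)
#' @param d target density in (0, 1]
#' @return a `binary_network` with the achieved density recorded
#' @export
threshold_by_density <- function(A, d) {
  r <- if (is.matrix(A)) A else A$r
  nm <- if (is.matrix(A)) rownames(A) else A$region_names
  threshold_matrix_density(r, d, "empirical", nm)
}

#' Threshold an association matrix at a fixed correlation value
#'
#' Edge present iff `r[i, j] > r0`. The achieved density is recorded; an
#' empty graph is allowed (with a warning).
#'
#' @param A an `association_matrix` (or plain symmetric matrix)
#' @param r0 correlation threshold in (-1, 1)
#' @return a `binary_network`
#' @export
threshold_by_correlation <- function(A, r0) {
  stopifnot(r0 > -1, r0 < 1)
  r <- if (is.matrix(A)) A else A$r
  nm <- if (is.matrix(A)) rownames(A) else A$region_names
  adj <- (r > r0) * 1L
  diag(adj) <- 0L
  storage.mode(adj) <- "integer"
  dimnames(adj) <- list(nm, nm)
  if (sum(adj) == 0) warning("correlation threshold yields an empty graph")
  new_binary_network(adj, "correlation", r0, "empirical", nm)
}

as_igraph <- function(G) {
  adj <- if (is.matrix(G)) G else G$adjacency
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
}

is_connected_network <- function(G) {
  igraph::is_connected(as_igraph(G))
}

#' Minimum density at which all groups' networks are connected
#'
#' Scans the grid densities in increasing order and returns the smallest at
#' which every association matrix thresholds to a single connected
#' component. Because edge sets are nested in density, connectivity is
#' monotone and the first hit is the minimum.
#'
#' @param matrices a list of `association_matrix` objects (or one matrix)
#' @param grid a [density_grid()]
#' @return the minimum connecting density (one of `grid$densities`)
#' @export
minimum_connected_density <- function(matrices, grid = density_grid()) {
  if (inherits(matrices, "association_matrix") || is.matrix(matrices))
    matrices <- list(matrices)
  stopifnot(length(matrices) >= 1L)
  for (d in grid$densities) {
    ok <- vapply(matrices,
                 function(A) is_connected_network(threshold_by_density(A, d)),
                 logical(1))
    if (all(ok)) return(d)
  }
  ncomp <- vapply(matrices, function(A) {
    igraph::count_components(as_igraph(threshold_by_density(A, grid$stop)))
  }, numeric(1))
  stop(sprintf(
    "no grid density connects all matrices; most fragmented: matrix %d (%d components at density %.2f)",
    which.max(ncomp), max(ncomp), grid$stop))
}

#' @export
print.binary_network <- function(x, ...) {
  cat(sprintf("binary_network (%s): %d nodes, %d edges, density %.4f (%s threshold %.3f)\n",
              x$provenance, nrow(x$adjacency), sum(x$adjacency) / 2,
              x$density, x$threshold_kind, x$threshold_value))
  invisible(x)
}
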