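#' Topology-randomized (TOP) null network
#'
#' Connected degree-preserving randomization by repeated double-edge swaps;
#' every swap that would create a self-loop, duplicate edge, or disconnect
#' the graph is rejected, so the output has the same node count, edge count
#' and exact degree sequence as the input and stays simple and connected.
#'
#' If the input graph is itself disconnected (possible for networks
#' thresholded below their connecting density), swaps still never split a
#' component — they can only preserve or merge components — and the output's
#' connectivity is recorded in its `connected` attribute.
#'
#' @param G a simple `binary_network`
#' @param seed integer seed
#' @param swaps_per_edge accepted-swap budget per edge (default 10)
#' @return a `binary_network` with provenance `"TOP"`
#' @export
top_null <- function(G, seed = 1L, swaps_per_edge = 10) {
  adj <- get_adjacency(G)
  storage.mode(adj) <- "integer"
  if (is.matrix(G))
    G <- new_binary_network(adj, "density", NA_real_, "empirical",
                            rownames(adj))
  n <- nrow(adj)
  E <- sum(adj) / 2
  if (E == 0) stop("graph has no edges")
  if (E == n * (n - 1) / 2) {
    warning("complete graph has no rewirable edge pair; returning input unchanged")
    out <- G
    out$provenance <- "TOP"
    return(out)
  }
  target <- as.integer(round(swaps_per_edge * E))
  res <- with_seed(seed, rewire_connected_cpp(adj, target, 40L * target))
  if (res$accepted == 0) {
    warning("no rewirable edge pair found; returning input unchanged")
    out <- G
    out$provenance <- "TOP"
    return(out)
  }
  if (res$accepted < 0.5 * target)
    warning(sprintf("swap acceptance below floor: %d of %d budgeted swaps",
                    res$accepted, target))
  adj_new <- res$adjacency
  dimnames(adj_new) <- dimnames(adj)
  out <- new_binary_network(adj_new, G$threshold_kind %||% "density",
                            G$threshold_value %||% NA_real_, "TOP",
                            if (is.matrix(G)) rownames(G) else G$region_names)
  attr(out, "connected") <- is_connected_network(out)
  out
}

#' Moment constants of the Hirschberger-Qi-Steuer construction
#'
#' From the observed covariance matrix, computes the mean diagonal entry
#' `dbar`, the mean `e` and variance `v` of the off-diagonal entries, and
#' the Gram-factor constants `m_f = max(2, round((dbar^2 - e^2) / v))`,
#' `mu = sqrt(e / m_f)`, `sigma^2 = sqrt(mu^4 + v / m_f) - mu^2`. With these,
#' `C = B B'` with i.i.d. `Normal(mu, sigma^2)` entries in the n-by-m_f
#' factor matrix `B` matches `e`, `v` and `dbar` in expectation.
#'
#' @param A an `association_matrix` (or plain covariance matrix)
#' @return an `hqs_moments` list
#' @export
hqs_moments <- function(A) {
  S <- if (is.matrix(A)) A else A$cov
  off <- S[upper.tri(S)]
  dbar <- mean(diag(S))
  e <- mean(off)
  v <- stats::var(off)
  if (!is.finite(e) || e <= 0)
    stop("HQS undefined for non-positive mean covariance")
  if (!is.finite(v) || v <= 0)
    stop("HQS undefined for zero off-diagonal covariance variance")
  m_f <- max(2L, as.integer(round_half_up((dbar^2 - e^2) / v)))
  mu <- sqrt(e / m_f)
  sigma2 <- sqrt(mu^4 + v / m_f) - mu^2
  structure(list(dbar = dbar, e = e, v = v, m_f = m_f, mu = mu,
                 sigma = sqrt(sigma2)),
            class = "hqs_moments")
}

#' Draw a random covariance matrix matched to the observed moments (HQS)
#'
#' @param A an `association_matrix` (or plain covariance matrix)
#' @param seed integer seed
#' @return an n-by-n positive-semidefinite covariance matrix whose
#'   off-diagonal mean/variance and diagonal mean match the observed ones in
#'   expectation
#' @export
hqs_null_covariance <- function(A, seed = 1L) {
  mom <- hqs_moments(A)
  n <- nrow(if (is.matrix(A)) A else A$cov)
  with_seed(seed, {
    B <- matrix(stats::rnorm(n * mom$m_f, mean = mom$mu, sd = mom$sigma),
                n, mom$m_f)
    tcrossprod(B)
  })
}

#' HQS null network at a fixed density
#'
#' Draws an HQS random covariance matrix, converts it to a correlation
#' matrix, and thresholds by density (rank-based), matching the density of
#' the network of interest. Connectedness is not guaranteed; fragmentation
#' is flagged via the `connected` attribute.
#'
#' @param A an `association_matrix`
#' @param d target density
#' @param seed integer seed
#' @return a `binary_network` with provenance `"HQS"`
#' @export
hqs_null_network <- function(A, d, seed = 1L) {
  C <- hqs_null_covariance(A, seed)
  r <- stats::cov2cor(C)
  out <- threshold_matrix_density(r, d, "HQS",
                                  if (is.matrix(A)) rownames(A) else A$region_names)
  attr(out, "connected") <- is_connected_network(out)
  out
}

#' COR null network: correlation of subject-wise permuted data
#'
#' Each subject's region values are independently permuted (destroying the
#' across-subject correlation structure while preserving every subject's
#' value multiset), the Pearson association matrix is recomputed, and the
#' result is thresholded at the target density. Connectedness is not
#' guaranteed; fragmentation is flagged.
#'
#' @param data a `corrected_rgv`
#' @param d target density
#' @param seed integer seed
#' @return a `binary_network` with provenance `"COR"`
#' @export
cor_null <- function(data, d, seed = 1L) {
  values <- if (is.matrix(data)) data else data$residuals
  if (nrow(values) < 3L) stop("at least 3 subjects are required")
  perm <- with_seed(seed, {
    t(apply(values, 1L, sample))
  })
  dimnames(perm) <- dimnames(values)
  r <- stats::cor(perm)
  out <- threshold_matrix_density(r, d, "COR", colnames(values))
  attr(out, "permuted_values") <- perm
  attr(out, "connected") <- is_connected_network(out)
  out
}

#' Generate an ensemble of null networks
#'
#' Generates `m` null networks of one family with per-member derived seeds
#' and records the ensemble means of the clustering coefficient and
#' characteristic path length used for small-world normalization.
#'
#' @param target for `model = "TOP"` a connected `binary_network`; for
#'   `"HQS"` an `association_matrix`; for `"COR"` a `corrected_rgv`
#' @param model one of `"TOP"`, `"HQS"`, `"COR"`
#' @param m ensemble size (default 20)
#' @param seed integer seed; member `i` uses `derive_seed(seed, i)`
#' @param density target density; required for HQS/COR, taken from the
#'   target network for TOP
#' @param fragment_policy what to do with disconnected members: `"keep"`
#'   (default; path length is then a connected-pairs-only mean),
#'   `"discard"` (redraw with a fresh derived seed, bounded retries), or
#'   `"error"`
#' @param swaps_per_edge TOP swap budget per edge
#' @param max_redraws total redraw budget under `"discard"`
#' @return a `null_ensemble`: members, per-member `C_null_values` /
#'   `L_null_values`, their means, `n_fragmented`, the `seed`
#' @export
null_ensemble <- function(target, model = c("TOP", "HQS", "COR"), m = 20L,
                          seed = 1L, density = NULL,
                          fragment_policy = c("keep", "discard", "error"),
                          swaps_per_edge = 10, max_redraws = 10L * m) {
  model <- match.arg(model)
  fragment_policy <- match.arg(fragment_policy)
  stopifnot(m >= 1L)
  if (model == "TOP") {
    stopifnot(inherits(target, "binary_network"))
    density <- density %||% target$density
  } else if (is.null(density)) {
    stop("density must be given for HQS/COR ensembles")
  }
  gen <- switch(model,
    TOP = function(s) top_null(target, seed = s, swaps_per_edge = swaps_per_edge),
    HQS = function(s) hqs_null_network(target, density, seed = s),
    COR = function(s) cor_null(target, density, seed = s))

  members <- vector("list", m)
  n_redraws <- 0L
  stream <- m  # redraw seeds continue past the member streams
  for (i in seq_len(m)) {
    g <- gen(derive_seed(seed, i))
    if (fragment_policy != "keep") {
      while (!(attr(g, "connected") %||% is_connected_network(g))) {
        if (fragment_policy == "error")
          stop(sprintf("%s null member %d is fragmented", model, i))
        n_redraws <- n_redraws + 1L
        if (n_redraws > max_redraws)
          stop(sprintf("redraw budget exhausted: %d redraws, fragmentation rate %.2f",
                       n_redraws, n_redraws / (n_redraws + i)))
        stream <- stream + 1L
        g <- gen(derive_seed(seed, stream))
      }
    }
    members[[i]] <- g
  }
  C_vals <- vapply(members, clustering_coefficient, numeric(1))
  L_vals <- vapply(members, function(g) as.numeric(characteristic_path_length(g)),
                   numeric(1))
  fragged <- vapply(members, function(g) {
    !(attr(g, "connected") %||% is_connected_network(g))
  }, logical(1))
  structure(list(model = model, members = members,
                 C_null_values = C_vals, L_null_values = L_vals,
                 C_null_mean = mean(C_vals), L_null_mean = mean(L_vals),
                 n_fragmented = sum(fragged), n_redraws = n_redraws,
                 density = density, fragment_policy = fragment_policy,
                 seed = seed),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("null_ensemble: %d %s nulls at density %.3f; C_null=%.4f L_null=%.4f (%d fragmented, policy %s)\n",
              length(x$members), x$model, x$density, x$C_null_mean,
              x$L_null_mean, x$n_fragmented, x$fragment_policy))
  invisible(x)
}
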