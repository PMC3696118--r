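# Readers/writers for the pipeline's tabular and network artifacts.
# Dialect: comma-delimited, header row, UTF-8; subjects as rows with an
# identifier column, regions as named columns.

#' Write a morphometry dataset as delimited tables
#'
#' Writes the subject-by-region value table and a sibling covariate table
#' keyed by subject identifier.
#'
#' @param data a `morphometry_dataset`
#' @param values_path,covariates_path output CSV paths
#' @export
write_morphometry_table <- function(data, values_path, covariates_path = NULL) {
  df <- data.frame(subject = rownames(data$values), data$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, values_path, row.names = FALSE)
  if (!is.null(covariates_path))
    utils::write.csv(data$covariates, covariates_path, row.names = FALSE)
  invisible(values_path)
}

#' Read a morphometry table (and optional covariates) from CSV
#'
#' @param values_path CSV with a `subject` identifier column and one numeric
#'   column per region
#' @param covariates_path optional CSV with a `subject` column and covariate
#'   columns
#' @return a `morphometry_dataset`-shaped list
#' @export
read_morphometry_table <- function(values_path, covariates_path = NULL) {
  df <- utils::read.csv(values_path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (!"subject" %in% colnames(df))
    stop("missing header: expected a 'subject' column in ", values_path)
  region_names <- colnames(df)[colnames(df) != "subject"]
  if (anyDuplicated(region_names))
    stop("duplicate region names: ",
         paste(unique(region_names[duplicated(region_names)]), collapse = ", "))
  vals <- as.matrix(df[, region_names, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(!apply(df[, region_names, drop = FALSE], 1L,
                        function(r) all(!is.na(suppressWarnings(as.numeric(r))))))
    stop("non-numeric cell(s) in row(s): ", paste(bad, collapse = ", "))
  }
  if (anyNA(vals)) {
    bad <- which(apply(vals, 1L, anyNA))
    stop("missing/non-numeric cell(s) in row(s): ", paste(bad, collapse = ", "))
  }
  rownames(vals) <- df$subject
  covs <- NULL
  if (!is.null(covariates_path)) {
    covs <- utils::read.csv(covariates_path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (!"subject" %in% colnames(covs))
      stop("missing header: expected a 'subject' column in ", covariates_path)
    covs <- covs[match(df$subject, covs$subject), , drop = FALSE]
    if (anyNA(covs$subject))
      stop("covariate table does not cover all subjects")
  }
  structure(list(values = vals, region_names = region_names,
                 subject_ids = df$subject, covariates = covs),
            class = "morphometry_dataset")
}

#' Write a binary network as an edge list
#'
#' Two name columns, one row per undirected edge; region names preserved.
#'
#' @param G a `binary_network`
#' @param path output CSV path
#' @export
write_network <- function(G, path) {
  adj <- G$adjacency
  nm <- G$region_names %||% as.character(seq_len(nrow(adj)))
  ut <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
  df <- data.frame(from = nm[ut[, 1]], to = nm[ut[, 2]],
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an edge list into a binary network
#'
#' @param path CSV with `from`, `to` columns
#' @param region_names full node-name vector (edge lists omit isolated
#'   nodes, so the node set must be supplied)
#' @return a `binary_network`
#' @export
read_network <- function(path, region_names) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("from", "to") %in% colnames(df)))
    stop("missing header: expected 'from' and 'to' columns in ", path)
  n <- length(region_names)
  adj <- matrix(0L, n, n, dimnames = list(region_names, region_names))
  i <- match(df$from, region_names); j <- match(df$to, region_names)
  if (anyNA(i) || anyNA(j))
    stop("edge list names not in region_names (rows ",
         paste(which(is.na(i) | is.na(j)), collapse = ", "), ")")
  adj[cbind(i, j)] <- 1L
  adj[cbind(j, i)] <- 1L
  new_binary_network(adj, "density", NA_real_, "empirical", region_names)
}

#' Write a square labeled association matrix as CSV
#'
#' @param A an `association_matrix`
#' @param path output CSV path
#' @export
write_association <- function(A, path) {
  df <- data.frame(region = A$region_names, A$r, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("region", A$region_names)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write metric curves in long format
#'
#' Columns: `density`, `metric`, `model`, `group`, `value`.
#'
#' @param curves a list of `metric_curve` objects (or one)
#' @param path output CSV path
#' @export
write_curves <- function(curves, path) {
  if (inherits(curves, "metric_curve")) curves <- list(curves)
  rows <- lapply(curves, function(cv) {
    data.frame(density = cv$densities, metric = cv$metric, model = cv$model,
               group = cv$group_label, value = cv$values,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
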