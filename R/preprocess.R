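#' Remove nuisance-covariate effects from regional volumes
#'
#' Per region, ordinary least squares of volume on an intercept plus the
#' named covariates; the residuals replace the raw values ("corrected RGV").
#' The intercept is always included, so residual columns have zero mean and
#' are orthogonal to every covariate column.
#'
#' @param data a `morphometry_dataset` (or any list with `values` and
#'   `covariates`)
#' @param covariate_names character vector of covariate columns to remove;
#'   may be empty, in which case columns are simply mean-centered
#' @return a `corrected_rgv`: list with `residuals` (same shape and dimnames
#'   as `data$values`), `covariate_names_removed`, `subject_ids`,
#'   `region_names`
#' @export
correct_regional_volumes <- function(data, covariate_names = c("age", "sex", "tbv")) {
  values <- if (is.matrix(data)) data else data$values
  stopifnot(is.matrix(values), !anyNA(values))
  n <- nrow(values)
  if (n < 3L) stop("at least 3 subjects are required")
  if (length(covariate_names) > 0L) {
    covs <- data$covariates
    missing_covs <- setdiff(covariate_names, colnames(covs))
    if (length(missing_covs) > 0L)
      stop("covariates not present in dataset: ",
           paste(missing_covs, collapse = ", "))
    if (length(covariate_names) > n - 2L)
      stop("more covariates than subjects - 2: regression is unidentifiable")
    X <- cbind(`(Intercept)` = 1, as.matrix(covs[, covariate_names, drop = FALSE]))
  } else {
    X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("rank-deficient covariate design; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  res <- qr.resid(qx, values)
  dimnames(res) <- dimnames(values)
  out <- list(residuals = res,
              covariate_names_removed = covariate_names,
              subject_ids = rownames(values) %||% data$subject_ids,
              region_names = colnames(values) %||% data$region_names)
  class(out) <- "corrected_rgv"
  out
}

#' @export
print.corrected_rgv <- function(x, ...) {
  cat(sprintf("corrected_rgv: %d subjects x %d regions (covariates removed: %s)\n",
              nrow(x$residuals), ncol(x$residuals),
              if (length(x$covariate_names_removed)) paste(x$covariate_names_removed, collapse = ", ") else "none"))
  invisible(x)
}
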