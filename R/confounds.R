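#' Build a per-example covariate matrix from subject records
#'
#' Covariates (medication load, substance history) are measured per subject,
#' while classification examples are per (subject, condition): each subject's
#' covariate row is duplicated across that subject's examples so that rows
#' align one-to-one with the feature matrix.  Condition labels never enter
#' the covariate matrix — that would remove the signal of interest.
#'
#' @param features a `feature_matrix` (supplies row order).
#' @param covariates data frame with `subject_id` plus covariate columns, or
#'   `NULL` for intercept-only (pure centering, the healthy-control default
#'   where no covariates are recorded).
#' @param columns covariate columns to use.
#' @return A `covariate_matrix`: numeric matrix aligned with `features$rows`,
#'   with an attribute recording the labels.  An intercept is appended later
#'   by [residual_forming_matrix()]/[residualize()], not here.
#' @export
covariate_matrix <- function(features, covariates = NULL,
                             columns = c("medication_load", "substance_history")) {
  stopifnot(inherits(features, "feature_matrix"))
  n <- nrow(features$rows)
  if (is.null(covariates)) {
    C <- matrix(numeric(0), n, 0)
    attr(C, "labels") <- character(0)
    class(C) <- c("covariate_matrix", class(C))
    return(C)
  }
  stopifnot("subject_id" %in% names(covariates))
  columns <- intersect(columns, names(covariates))
  idx <- match(features$rows$subject_id, covariates$subject_id)
  if (any(is.na(idx))) stop("covariate table is missing subjects")
  C <- as.matrix(covariates[idx, columns, drop = FALSE])
  if (any(!is.finite(C))) stop("non-finite covariate values")
  rownames(C) <- NULL
  attr(C, "labels") <- columns
  class(C) <- c("covariate_matrix", class(C))
  C
}

#' Residual-forming (annihilator) matrix of a covariate design
#'
#' The orthogonal projector R = I - C (C'C)^+ C' onto the complement of the
#' covariate column space, computed with a pseudo-inverse so collinear
#' covariates are handled.  An intercept column is always appended to C
#' first, so applying R at minimum centers each data column.
#'
#' @param C numeric matrix (examples x covariates); zero covariate columns
#'   are allowed (intercept-only).
#' @return Symmetric idempotent matrix with `R %*% cbind(1, C) == 0`.
#' @export
residual_forming_matrix <- function(C) {
  if (is.null(C) || nrow(C) == 0) stop("empty covariate matrix")
  n <- nrow(C)
  Cfull <- cbind(intercept = 1, unclass(C))
  if (n < ncol(Cfull)) stop("fewer examples than covariate columns")
  diag(n) - Cfull %*% pseudo_solve(crossprod(Cfull)) %*% t(Cfull)
}

# Moore-Penrose pseudo-inverse of a symmetric PSD matrix via eigendecomposition.
pseudo_solve <- function(A, tol = 1e-10) {
  e <- eigen(A, symmetric = TRUE)
  keep <- e$values > tol * max(e$values, 0)
  if (!any(keep)) return(matrix(0, nrow(A), ncol(A)))
  e$vectors[, keep, drop = FALSE] %*%
    (t(e$vectors[, keep, drop = FALSE]) / e$values[keep])
}

#' Remove covariate-explained variance from a feature matrix
#'
#' Confound control by dummy-variable regression: feature columns are
#' replaced by their residuals after regression on the covariates (plus
#' intercept).  Two estimation scopes are supported:
#' \describe{
#'   \item{`whole_sample`}{the residual-forming matrix of the full covariate
#'     matrix is applied to all rows at once — the pre-cross-validation usage
#'     in which downstream predictive probabilities "have already controlled
#'     for" the confounds.}
#'   \item{`train_only`}{regression coefficients are estimated on the
#'     training rows only and subtracted from all rows, so no information
#'     flows from test to training folds.  This is the default inside
#'     cross-validation.}
#' }
#'
#' @param features a `feature_matrix`.
#' @param covariates a matrix from [covariate_matrix()] (or any aligned
#'   numeric matrix), or `NULL` for intercept-only centering.
#' @param mode `"train_only"` or `"whole_sample"`.
#' @param train row indices of the training set (required for `train_only`
#'   when it is a proper subset).
#' @return A `feature_matrix` with residualized `values`.
#' @export
residualize <- function(features, covariates = NULL,
                        mode = c("train_only", "whole_sample"),
                        train = seq_len(nrow(features$values))) {
  stopifnot(inherits(features, "feature_matrix"))
  mode <- match.arg(mode)
  n <- nrow(features$values)
  if (is.null(covariates)) covariates <- matrix(numeric(0), n, 0)
  if (nrow(covariates) != n) stop("covariate rows are not aligned with features")
  Cfull <- cbind(1, unclass(covariates))
  X <- features$values
  if (mode == "whole_sample") {
    R <- residual_forming_matrix(covariates)
    out <- R %*% X
  } else {
    Ct <- Cfull[train, , drop = FALSE]
    B <- pseudo_solve(crossprod(Ct)) %*% crossprod(Ct, X[train, , drop = FALSE])
    out <- X - Cfull %*% B
  }
  new_feature_matrix(out, features$rows, features$mask, features$voxel_index)
}
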