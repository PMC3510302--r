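#' Gaussian process classifier options
#'
#' Linear-kernel binary GP classification with a probit likelihood and
#' Laplace approximation.  The Gram matrix is `amplitude * X %*% t(X) + bias`,
#' optionally trace-normalized first (`K0 <- K0 * n / trace(K0)`), which
#' makes the fixed amplitude grid scale-free with respect to the number of
#' voxels and the noise level.  The amplitude is selected by maximizing the
#' Laplace-approximate log marginal likelihood over `amplitude_grid`.
#'
#' @param bias non-negative kernel offset (default 0: homogeneous linear
#'   kernel).
#' @param normalize trace-normalize the linear Gram matrix (default TRUE).
#' @param amplitude_grid candidate amplitudes (default `2^(-6:6)`).
#' @param tol Newton convergence tolerance on the log-posterior objective.
#' @param maxit maximum Newton iterations.
#' @export
gpc_opts <- function(bias = 0, normalize = TRUE, amplitude_grid = 2^(-6:6),
                     tol = 1e-6, maxit = 100) {
  stopifnot(bias >= 0, all(amplitude_grid > 0), tol > 0, maxit >= 1)
  list(bias = bias, normalize = normalize,
       amplitude_grid = sort(amplitude_grid), tol = tol, maxit = maxit)
}

#' Train a binary Gaussian process classifier
#'
#' Finds the Laplace posterior mode of the latent function by Newton
#' iteration (stable `B = I + W^(1/2) K W^(1/2)` parameterization) for each
#' amplitude on the grid, keeps the evidence-maximizing amplitude, and caches
#' the factorization needed for prediction.
#'
#' @param X training features: a `feature_matrix` or plain numeric matrix
#'   (examples x voxels).
#' @param y labels in {+1, -1} (class 1 = +1); logical/0-1 vectors and
#'   2-level factors are coerced (first level / TRUE / 1 -> +1).
#' @param opts a [gpc_opts()] list.
#' @return A `gpc_model` with the latent posterior mode, dual coefficients
#'   `alpha`, cached Cholesky factor, selected amplitude, and per-amplitude
#'   log marginal likelihoods.
#' @export
gpc_train <- function(X, y, opts = gpc_opts()) {
  fm <- NULL
  if (inherits(X, "feature_matrix")) { fm <- X; X <- X$values }
  X <- as.matrix(X)
  y <- coerce_labels(y)
  if (length(y) != nrow(X)) stop("label length does not match rows")
  if (length(unique(y)) < 2) stop("training labels contain a single class")
  K0 <- tcrossprod(X)
  norm_factor <- 1
  if (opts$normalize) {
    tr <- sum(diag(K0))
    if (tr > 0) norm_factor <- nrow(X) / tr
    K0 <- K0 * norm_factor
  }
  res <- cpp_gpc_grid(K0, y, opts$amplitude_grid, opts$bias,
                      opts$tol, opts$maxit)
  fit <- res$fit
  if (!fit$converged)
    stop("Laplace Newton iteration did not converge after ",
         fit$iterations, " iterations")
  structure(list(
    train_features = X, feature_matrix = fm, labels = y,
    alpha = as.numeric(fit$alpha), latent_mode = as.numeric(fit$f),
    sqrtW = as.numeric(fit$sqrtW), L = fit$L,
    amplitude = opts$amplitude_grid[res$best_index],
    log_marginals = as.numeric(res$log_marginals),
    log_marginal = fit$log_marginal,
    bias = opts$bias, norm_factor = norm_factor, opts = opts,
    iterations = fit$iterations), class = "gpc_model")
}

coerce_labels <- function(y) {
  if (is.factor(y)) y <- ifelse(y == levels(y)[1], 1, -1)
  else if (is.logical(y)) y <- ifelse(y, 1, -1)
  else if (all(y %in% c(0, 1))) y <- ifelse(y == 1, 1, -1)
  y <- as.numeric(y)
  if (!all(y %in% c(-1, 1))) stop("labels must be coercible to {+1, -1}")
  y
}

#' @export
print.gpc_model <- function(x, ...) {
  cat(sprintf(paste0("gpc_model: %d examples x %d features, amplitude %.4g",
                     " (evidence %.3f), %d Newton iterations\n"),
              nrow(x$train_features), ncol(x$train_features),
              x$amplitude, x$log_marginal, x$iterations))
  invisible(x)
}

#' Predictive class-1 probabilities for test patterns
#'
#' Computes the latent predictive mean and variance from the cached Laplace
#' factorization and maps them through the probit likelihood's closed-form
#' Gaussian integral `pnorm(mean / sqrt(1 + var))`.  Probabilities are
#' strictly inside (0, 1); a test point with zero kernel row (orthogonal to
#' all training points, zero bias) gets exactly 0.5, the prior.
#'
#' @param model a `gpc_model`.
#' @param newdata numeric matrix (rows = test patterns), vector, or
#'   `feature_matrix`.
#' @return Numeric vector of class-1 probabilities with attributes
#'   `latent_mean` and `latent_var`.
#' @export
gpc_predict <- function(model, newdata) {
  stopifnot(inherits(model, "gpc_model"))
  if (inherits(newdata, "feature_matrix")) newdata <- newdata$values
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(model$train_features))
    stop("feature dimension mismatch: ", ncol(newdata), " vs ",
         ncol(model$train_features))
  scale <- model$amplitude * model$norm_factor
  Kstar <- scale * tcrossprod(newdata, model$train_features) + model$bias
  kss <- scale * rowSums(newdata^2) + model$bias
  pr <- cpp_gpc_predict(Kstar, kss, model$alpha, model$sqrtW, model$L)
  p <- as.numeric(pr$probability)
  attr(p, "latent_mean") <- as.numeric(pr$latent_mean)
  attr(p, "latent_var") <- as.numeric(pr$latent_var)
  p
}

#' Save and restore a trained classifier
#'
#' Single-archive serialization with a format version tag; loading checks
#' the tag and refuses archives written by an incompatible layout.
#'
#' @param model a `gpc_model`.
#' @param path archive path (conventionally `.rds`).
#' @export
save_gpc_model <- function(model, path) {
  stopifnot(inherits(model, "gpc_model"))
  saveRDS(list(format = "gpcmvpa-gpc/1", model = unclass(model)), path)
  invisible(path)
}

#' @rdname save_gpc_model
#' @export
load_gpc_model <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "gpcmvpa-gpc/1"))
    stop("unrecognized model archive format: ", x$format)
  structure(x$model, class = "gpc_model")
}

#' Voxelwise discriminating weights of a linear-kernel GP classifier
#'
#' The primal weight vector `w = amplitude * norm_factor * t(X) %*% alpha`
#' equivalent to the dual representation: for any test pattern x, the latent
#' predictive mean equals `w . x + bias * sum(alpha)`.  A large |weight|
#' marks a voxel with a strong contribution to the discrimination boundary
#' (not a univariate activation difference); positive weights are evidence
#' for class 1.
#'
#' @param model a `gpc_model`.
#' @return Numeric weight vector (one per feature).
#' @export
gpc_weights <- function(model) {
  stopifnot(inherits(model, "gpc_model"))
  as.numeric(model$amplitude * model$norm_factor *
               crossprod(model$train_features, model$alpha))
}

#' Back-project classifier weights into volume space
#'
#' @param model a `gpc_model` trained on a `feature_matrix` (or supply one).
#' @param features the training `feature_matrix` (defaults to the one stored
#'   in the model), providing the mask and voxel index.
#' @return 3-D array of signed weights, zero off-mask.
#' @export
weight_map <- function(model, features = model$feature_matrix) {
  if (is.null(features))
    stop("model was not trained on a feature_matrix; pass one explicitly")
  features_to_volume(features, gpc_weights(model))
}
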