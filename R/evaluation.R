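#' Cross-validation configuration
#'
#' @param residualize_mode `"train_only"` (confound regression refit inside
#'   each fold; default, leakage-free) or `"whole_sample"` (residual-forming
#'   matrix applied once before cross-validation).
#' @param gpc classifier options from [gpc_opts()].
#' @param n_permutations permutations for the significance test (0 = skip).
#' @param seed RNG seed for the permutation draws.
#' @export
cv_config <- function(residualize_mode = c("train_only", "whole_sample"),
                      gpc = gpc_opts(), n_permutations = 0, seed = 1) {
  list(residualize_mode = match.arg(residualize_mode), gpc = gpc,
       n_permutations = as.integer(n_permutations), seed = as.integer(seed))
}

#' Balanced accuracy
#'
#' Arithmetic mean of the true-positive rate (class-1 examples classified
#' correctly) and true-negative rate (class-2 examples classified
#' correctly) — the "mean classification accuracy" reported for within-group
#' decoding.
#'
#' @param tp_rate,tn_rate fractions in [0, 1].
#' @export
balanced_accuracy <- function(tp_rate, tn_rate) {
  if (any(tp_rate < 0 | tp_rate > 1) || any(tn_rate < 0 | tn_rate > 1))
    stop("rates must lie in [0, 1]")
  (tp_rate + tn_rate) / 2
}

# Fold contexts for leave-one-unit-out CV with precomputed kernels.
# Contexts depend on features/covariates/fold split but never on labels, so
# permutation testing reuses them and refits only the Laplace mode.
build_fold_contexts <- function(features, covariates, folds, opts, mode) {
  if (mode == "whole_sample")
    features <- residualize(features, covariates, "whole_sample")
  lapply(folds, function(fold) {
    n <- nrow(features$values)
    train <- setdiff(seq_len(n), fold)
    X <- if (mode == "train_only")
      residualize(features, covariates, "train_only", train = train)$values
    else features$values
    Xtr <- X[train, , drop = FALSE]
    Xte <- X[fold, , drop = FALSE]
    K0 <- tcrossprod(Xtr)
    f <- 1
    if (opts$normalize) {
      tr <- sum(diag(K0))
      if (tr > 0) f <- length(train) / tr
    }
    list(train = train, test = fold, K0 = K0 * f,
         Kc0 = tcrossprod(Xte, Xtr) * f, kss0 = rowSums(Xte^2) * f)
  })
}

# Run all folds for one labeling; returns class-1 probabilities in row order
# of the original feature matrix (NA for rows never held out).
run_folds <- function(contexts, y, opts) {
  n <- max(vapply(contexts, function(cx) max(cx$test), 0L))
  prob <- rep(NA_real_, n)
  fold_of <- rep(NA_integer_, n)
  for (k in seq_along(contexts)) {
    cx <- contexts[[k]]
    ytr <- y[cx$train]
    res <- cpp_gpc_grid(cx$K0, ytr, opts$amplitude_grid, opts$bias,
                        opts$tol, opts$maxit)
    fit <- res$fit
    amp <- opts$amplitude_grid[res$best_index]
    pr <- cpp_gpc_predict(amp * cx$Kc0 + opts$bias,
                          amp * cx$kss0 + opts$bias,
                          fit$alpha, fit$sqrtW, fit$L)
    prob[cx$test] <- as.numeric(pr$probability)
    fold_of[cx$test] <- k
  }
  list(prob = prob, fold = fold_of)
}

# Classification rule: probability > 0.5 is class 1, ties (exactly 0.5) go
# to class 2.
rates_from_probs <- function(prob, y) {
  pred <- ifelse(prob > 0.5, 1, -1)
  tp <- mean(pred[y == 1] == 1)
  tn <- mean(pred[y == -1] == -1)
  c(tp_rate = tp, tn_rate = tn, accuracy = (tp + tn) / 2)
}

#' Permutation test of a cross-validated accuracy
#'
#' Exchangeability-respecting label permutation: labels are flipped jointly
#' within randomly chosen units (a subject's two condition examples for
#' within-group decoding; a matched pair's two group members for
#' between-group decoding — in both cases a flip negates the unit's +/-1
#' labels).  The cross-validation is re-run in full for each permutation and
#' the p-value uses the add-one estimator
#' `p = (1 + #(permuted >= observed)) / (1 + n_permutations)`, which can
#' never be zero.
#'
#' @param accuracy_fn function mapping a label vector to an accuracy.
#' @param y observed labels in {+1, -1}.
#' @param units factor/vector marking exchangeability units (same length as
#'   `y`); each unit's labels flip together with probability 1/2.
#' @param n_permutations number of permutations (>= 1).
#' @param seed RNG seed.
#' @return List with `observed`, `permuted` (vector), `p_value`.
#' @export
permutation_test <- function(accuracy_fn, y, units, n_permutations = 1000,
                             seed = 1) {
  stopifnot(n_permutations >= 1, length(units) == length(y))
  units <- as.factor(units)
  if (nlevels(units) < 2)
    warning("fewer than two exchangeability units: permutations are degenerate")
  observed <- accuracy_fn(y)
  restore <- set_local_seed(seed)
  on.exit(restore())
  permuted <- vapply(seq_len(n_permutations), function(i) {
    flip <- stats::runif(nlevels(units)) < 0.5
    accuracy_fn(y * ifelse(flip[as.integer(units)], -1, 1))
  }, numeric(1))
  list(observed = observed, permuted = permuted,
       p_value = (1 + sum(permuted >= observed)) / (1 + n_permutations))
}

#' Within-group stimulus decoding by leave-one-subject-out cross-validation
#'
#' For one group and one binary stimulus contrast, each fold holds out both
#' of one subject's examples (one per class) and predicts them with a GP
#' classifier trained on all remaining subjects, optionally after confound
#' residualization.  Class 1 is the first contrast condition (probability
#' > 0.5); accuracy is the balanced accuracy.  With `n_permutations > 0` a
#' subject-level label-flip permutation test is run (the full CV is repeated
#' per permutation, reusing the precomputed fold kernels).
#'
#' @param features a `feature_matrix` for one group (other rows are ignored
#'   if `group` is given).
#' @param contrast length-2 character: (class-1 condition, class-2
#'   condition), e.g. `c("intense_happy", "neutral")`.
#' @param covariates per-subject covariate data frame (see
#'   [covariate_matrix()]) or `NULL`.
#' @param config a [cv_config()] list.
#' @param group restrict to this group label (default: all rows).
#' @return A `within_group_result`: predictions (one per held-out example),
#'   `accuracy`, `tp_rate`, `tn_rate`, `p_value`, permutation settings.
#' @export
loso_within_group <- function(features, contrast, covariates = NULL,
                              config = cv_config(), group = NULL) {
  stopifnot(inherits(features, "feature_matrix"), length(contrast) == 2)
  keep <- features$rows$condition %in% contrast
  if (!is.null(group)) keep <- keep & features$rows$group == group
  sub <- subset_features(features, keep)
  rows <- sub$rows
  tab <- table(rows$subject_id, rows$condition)
  if (any(tab != 1))
    stop("every subject must contribute exactly one example per condition")
  subjects <- unique(rows$subject_id)
  y <- ifelse(rows$condition == contrast[1], 1, -1)
  covC <- covariate_matrix(sub, covariates)
  folds <- lapply(subjects, function(s) which(rows$subject_id == s))
  contexts <- build_fold_contexts(sub, covC, folds, config$gpc,
                                  config$residualize_mode)
  obs <- run_folds(contexts, y, config$gpc)
  r <- rates_from_probs(obs$prob, y)
  p_value <- NA_real_
  if (config$n_permutations > 0) {
    acc_fn <- function(yy) rates_from_probs(run_folds(contexts, yy,
                                                      config$gpc)$prob,
                                            yy)[["accuracy"]]
    pt <- permutation_test(acc_fn, y, rows$subject_id,
                           config$n_permutations, config$seed)
    p_value <- pt$p_value
  }
  structure(list(
    group = if (is.null(group)) unique(rows$group) else group,
    contrast = contrast,
    predictions = data.frame(subject_id = rows$subject_id,
                             condition = rows$condition,
                             true_class = y,
                             probability_class1 = obs$prob,
                             fold_index = obs$fold,
                             stringsAsFactors = FALSE),
    accuracy = r[["accuracy"]], tp_rate = r[["tp_rate"]],
    tn_rate = r[["tn_rate"]], p_value = p_value,
    n_permutations = config$n_permutations, seed = config$seed),
    class = "within_group_result")
}

#' @export
print.within_group_result <- function(x, ...) {
  cat(sprintf("within-group decoding [%s] %s vs %s\n",
              paste(x$group, collapse = "/"), x$contrast[1], x$contrast[2]))
  cat(sprintf("  accuracy %.2f (TP %.2f, TN %.2f), p = %s\n", x$accuracy,
              x$tp_rate, x$tn_rate,
              ifelse(is.na(x$p_value), "NA", format(x$p_value, digits = 3))))
  invisible(x)
}

#' Direct group discrimination by leave-one-pair-out cross-validation
#'
#' Discriminates two groups from their activation patterns to a single
#' condition.  Each fold leaves out one matched pair (one subject per group);
#' the classifier is trained on the remaining pairs.  Class 1 is group A, so
#' sensitivity is the fraction of group-A subjects classified correctly and
#' specificity the fraction of group-B subjects.  The permutation test swaps
#' group labels within randomly chosen pairs.
#'
#' @param featuresA,featuresB `feature_matrix` objects for the two groups.
#' @param condition the stimulus condition whose patterns are compared.
#' @param pairing integer matrix/data frame with columns (index in A, index
#'   in B) defining the matched pairs; default pairs subjects by position
#'   (the study matched on age and gender; matching is an input here).
#' @param covariates optional per-subject covariate data frame spanning both
#'   groups.
#' @param config a [cv_config()] list.
#' @return A `between_group_result` with `sensitivity`, `specificity`,
#'   balanced `accuracy`, `p_value`, and per-fold predictions.
#' @export
lopo_between_group <- function(featuresA, featuresB, condition,
                               pairing = NULL, covariates = NULL,
                               config = cv_config()) {
  A <- subset_features(featuresA, featuresA$rows$condition == condition)
  B <- subset_features(featuresB, featuresB$rows$condition == condition)
  nA <- nrow(A$values); nB <- nrow(B$values)
  if (is.null(pairing)) {
    if (nA != nB) stop("unequal group sizes require an explicit pairing")
    pairing <- cbind(seq_len(nA), seq_len(nB))
  }
  pairing <- as.matrix(pairing)
  stopifnot(ncol(pairing) == 2,
            !anyDuplicated(pairing[, 1]), !anyDuplicated(pairing[, 2]))
  if (ncol(A$values) != ncol(B$values)) stop("feature dimension mismatch")
  comb <- new_feature_matrix(rbind(A$values, B$values),
                             rbind(A$rows, B$rows), A$mask, A$voxel_index)
  y <- c(rep(1, nA), rep(-1, nB))
  n_pairs <- nrow(pairing)
  folds <- lapply(seq_len(n_pairs),
                  function(k) c(pairing[k, 1], nA + pairing[k, 2]))
  covC <- covariate_matrix(comb, covariates)
  contexts <- build_fold_contexts(comb, covC, folds, config$gpc,
                                  config$residualize_mode)
  obs <- run_folds(contexts, y, config$gpc)
  r <- rates_from_probs(obs$prob, y)
  p_value <- NA_real_
  if (config$n_permutations > 0) {
    pair_unit <- integer(nA + nB)
    for (k in seq_len(n_pairs)) pair_unit[folds[[k]]] <- k
    acc_fn <- function(yy) rates_from_probs(run_folds(contexts, yy,
                                                      config$gpc)$prob,
                                            yy)[["accuracy"]]
    pt <- permutation_test(acc_fn, y, pair_unit, config$n_permutations,
                           config$seed)
    p_value <- pt$p_value
  }
  structure(list(
    group_pair = c(unique(A$rows$group), unique(B$rows$group)),
    condition = condition,
    sensitivity = r[["tp_rate"]], specificity = r[["tn_rate"]],
    accuracy = r[["accuracy"]], p_value = p_value,
    n_folds = n_pairs,
    predictions = data.frame(subject_id = comb$rows$subject_id,
                             group = comb$rows$group, true_class = y,
                             probability_class1 = obs$prob,
                             fold_index = obs$fold,
                             stringsAsFactors = FALSE),
    n_permutations = config$n_permutations, seed = config$seed),
    class = "between_group_result")
}

#' @export
print.between_group_result <- function(x, ...) {
  cat(sprintf("between-group decoding %s vs %s on %s\n",
              x$group_pair[1], x$group_pair[2], x$condition))
  cat(sprintf("  sensitivity %.2f, specificity %.2f, accuracy %.2f, p = %s\n",
              x$sensitivity, x$specificity, x$accuracy,
              ifelse(is.na(x$p_value), "NA", format(x$p_value, digits = 3))))
  invisible(x)
}

#' Bonferroni-adjust a set of p-values
#'
#' Convenience for the family of direct-discrimination classifiers (3 group
#' pairs x 3 conditions).
#' @param p numeric p-values.
#' @param method passed to [stats::p.adjust()] (default `"bonferroni"`).
#' @export
adjust_pvalues <- function(p, method = "bonferroni") stats::p.adjust(p, method)
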