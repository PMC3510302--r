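#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities parameterized by the response peak delay
#' and the undershoot delay (the densities' modes, in seconds), with the
#' undershoot scaled by `1/peak_undershoot_ratio` — the SPM-style canonical
#' shape (peak 6 s, undershoot 16 s, ratio 6).  The returned response is zero
#' at t = 0 and normalized to unit peak amplitude.
#'
#' @param time_grid non-negative, increasing times in seconds.
#' @param peak_delay mode of the response gamma (seconds, default 6).
#' @param undershoot_delay mode of the undershoot gamma (seconds, default 16).
#' @param peak_undershoot_ratio peak-to-undershoot amplitude ratio (default 6);
#'   `Inf` or 0 disables the undershoot, leaving a single non-negative gamma.
#' @param dispersion time dispersion of both gammas (rate = 1/dispersion).
#' @return numeric vector, same length as `time_grid`.
#' @export
canonical_hrf <- function(time_grid, peak_delay = 6, undershoot_delay = 16,
                          peak_undershoot_ratio = 6, dispersion = 1) {
  if (length(time_grid) == 0) stop("empty time grid")
  if (any(time_grid < 0) || any(diff(time_grid) <= 0))
    stop("time_grid must be non-negative and increasing")
  rate <- 1 / dispersion
  g <- function(delay) stats::dgamma(time_grid, shape = 1 + delay * rate,
                                     rate = rate)
  u_scale <- if (is.infinite(peak_undershoot_ratio) ||
                 peak_undershoot_ratio == 0) 0 else 1 / peak_undershoot_ratio
  h <- g(peak_delay) - u_scale * g(undershoot_delay)
  h / max(abs(h))
}

new_design_matrix <- function(values, column_labels, tr, conditions) {
  colnames(values) <- column_labels
  structure(list(values = values, column_labels = column_labels, tr = tr,
                 conditions = conditions), class = "design_matrix")
}

#' Build the event-related design matrix
#'
#' One regressor per condition — the condition's stimulus boxcar convolved
#' with the canonical HRF on a fine microtime grid, then sampled at scan
#' onsets — plus optional motion/nuisance columns and an intercept.
#'
#' @param schedule an `event_schedule`.
#' @param tr repetition time (seconds).
#' @param n_scans number of scans; defaults to covering the schedule.
#' @param motion optional numeric matrix (`n_scans` rows) appended verbatim
#'   as covariates of no interest.
#' @param conditions regressor order; defaults to [gpcmvpa_conditions()]
#'   restricted to conditions present.
#' @param dt microtime resolution (seconds, default 0.1).
#' @param hrf_args list of overrides passed to [canonical_hrf()].
#' @return A `design_matrix` with `values` (`n_scans` x regressors),
#'   `column_labels`, `tr`, `conditions`.
#' @export
build_design_matrix <- function(schedule, tr, n_scans = NULL, motion = NULL,
                                conditions = NULL, dt = 0.1,
                                hrf_args = list()) {
  stopifnot(inherits(schedule, "event_schedule"), tr > 0)
  ev <- schedule$events
  if (is.null(n_scans)) n_scans <- ceiling(schedule$total_duration / tr)
  if (nrow(ev) > 0 && max(ev$onset + ev$duration) > n_scans * tr)
    stop("events fall outside the scan window")
  if (is.null(conditions)) {
    conditions <- intersect(gpcmvpa_conditions(), unique(ev$condition))
    if (length(conditions) == 0) conditions <- unique(ev$condition)
    if (length(conditions) == 0) conditions <- gpcmvpa_conditions()
  }
  t_hi <- seq(0, n_scans * tr, by = dt)
  hrf <- do.call(canonical_hrf, c(list(time_grid = t_hi), hrf_args))
  scan_idx <- round((0:(n_scans - 1)) * tr / dt) + 1L
  cols <- vapply(conditions, function(cn) {
    box <- numeric(length(t_hi))
    for (i in which(ev$condition == cn)) {
      on <- ev$onset[i]
      box[t_hi >= on & t_hi < on + ev$duration[i]] <- 1
    }
    reg <- stats::convolve(box, rev(hrf), type = "open")[seq_along(t_hi)] * dt
    reg[scan_idx]
  }, numeric(n_scans))
  labels <- conditions
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (nrow(motion) != n_scans) stop("motion matrix must have n_scans rows")
    cols <- cbind(cols, motion)
    labels <- c(labels, paste0("motion", seq_len(ncol(motion))))
  }
  cols <- cbind(cols, 1)
  labels <- c(labels, "(intercept)")
  if (n_scans < length(labels))
    stop("fewer scans than regressors")
  new_design_matrix(cols, labels, tr, conditions)
}

#' Fit the voxelwise general linear model
#'
#' Ordinary least squares per voxel; condition coefficient volumes are
#' extracted by column label.  No autocorrelation model or high-pass filter
#' is applied (hooks for both are deliberately absent from this minimal
#' fitter).
#'
#' @param timeseries 4-D array (x, y, z, time).
#' @param design a `design_matrix` whose rows match the time dimension.
#' @return Named list: one 3-D coefficient array per condition.
#' @export
fit_glm <- function(timeseries, design) {
  stopifnot(is.array(timeseries), length(dim(timeseries)) == 4,
            inherits(design, "design_matrix"))
  X <- design$values
  d <- dim(timeseries)
  if (d[4] != nrow(X)) stop("time dimension does not match design rows")
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stop("design matrix is rank deficient (rank ", qx$rank, " < ", ncol(X), ")")
  Y <- matrix(timeseries, prod(d[1:3]), d[4])   # voxels x time
  beta <- qr.coef(qx, t(Y))                     # regressors x voxels
  out <- lapply(design$conditions, function(cn)
    array(beta[match(cn, design$column_labels), ], dim = d[1:3]))
  names(out) <- design$conditions
  out
}

new_feature_matrix <- function(values, rows, mask, voxel_index) {
  stopifnot(nrow(values) == nrow(rows), ncol(values) == length(voxel_index))
  structure(list(values = values, rows = rows, mask = mask,
                 voxel_index = voxel_index), class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d examples x %d voxels (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$rows$group), collapse = ", ")))
  invisible(x)
}

#' Extract whole-brain feature vectors from condition beta volumes
#'
#' One row per (subject, condition): the masked voxel values of that
#' subject's condition coefficient volume, read in ascending linear-index
#' order (1-based, native axis order, recorded in `voxel_index`).  There is
#' no feature selection: every in-mask voxel is a feature.
#'
#' @param records list of `subject_record`s sharing one grid.
#' @param mask logical/0-1 3-D array; default: voxels with nonzero variance
#'   across all requested volumes.
#' @param conditions conditions to extract (default all three).
#' @return A `feature_matrix` with `values`, row metadata `rows`
#'   (`subject_id`, `condition`, `group`), `mask`, `voxel_index`.
#' @export
extract_features <- function(records, mask = NULL,
                             conditions = gpcmvpa_conditions()) {
  stopifnot(length(records) > 0)
  grid_shape <- dim(records[[1]]$betas[[1]])
  vols <- list()
  rows <- list()
  for (r in records) {
    stopifnot(inherits(r, "subject_record"))
    for (cn in conditions) {
      if (is.null(r$betas[[cn]]))
        stop("subject ", r$subject_id, " is missing condition ", cn)
      v <- r$betas[[cn]]
      if (!identical(dim(v), grid_shape))
        stop("subject ", r$subject_id, " volume grid mismatch")
      vols[[length(vols) + 1L]] <- as.numeric(v)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = r$subject_id, condition = cn, group = r$group,
        stringsAsFactors = FALSE)
    }
  }
  full <- do.call(rbind, vols)
  if (is.null(mask)) {
    v <- apply(full, 2, stats::var)
    mask <- array(v > 0, dim = grid_shape)
  } else {
    if (!identical(dim(mask), grid_shape)) stop("mask grid mismatch")
    mask <- array(as.logical(mask != 0), dim = grid_shape)
  }
  voxel_index <- which(mask)
  vals <- full[, voxel_index, drop = FALSE]
  if (any(!is.finite(vals))) stop("non-finite feature values")
  new_feature_matrix(vals, do.call(rbind, rows), mask, voxel_index)
}

#' Scatter a feature row back into volume space
#'
#' Inverse of the masking in [extract_features()]: off-mask voxels are zero.
#' @param x a `feature_matrix`.
#' @param row_values numeric vector of length `ncol(x$values)`.
#' @export
features_to_volume <- function(x, row_values) {
  stopifnot(inherits(x, "feature_matrix"),
            length(row_values) == length(x$voxel_index))
  vol <- array(0, dim = dim(x$mask))
  vol[x$voxel_index] <- row_values
  vol
}

#' Subset a feature matrix by row
#' @param x a `feature_matrix`.
#' @param i row indices or logical vector.
#' @export
subset_features <- function(x, i) {
  new_feature_matrix(x$values[i, , drop = FALSE],
                     x$rows[i, , drop = FALSE], x$mask, x$voxel_index)
}
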