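test_that("canonical_hrf has the documented shape", {
  tg <- seq(0, 32, by = 0.01)
  h <- canonical_hrf(tg)
  expect_equal(h[1], 0)
  expect_equal(max(h), 1)                       # unit peak normalization
  expect_lt(abs(tg[which.max(h)] - 6), 0.5)     # peak near 6 s
  expect_lt(min(h), 0)                          # undershoot present
  h0 <- canonical_hrf(tg, peak_undershoot_ratio = 0)
  expect_true(all(h0 >= 0))                     # single-gamma limit
  expect_true(all(canonical_hrf(tg, peak_undershoot_ratio = Inf) >= 0))
  expect_error(canonical_hrf(numeric(0)), "empty")
  expect_error(canonical_hrf(c(1, 0.5)), "increasing")
})

test_that("build_design_matrix convolves events with the HRF", {
  # empty schedule: all condition columns zero
  empty <- gpcmvpa:::new_event_schedule(
    data.frame(onset = numeric(0), duration = numeric(0),
               condition = character(0)), total_duration = 20, seed = 0L)
  d0 <- build_design_matrix(empty, tr = 2, n_scans = 10)
  expect_true(all(d0$values[, d0$conditions] == 0))
  expect_equal(d0$values[, "(intercept)"], rep(1, 10), ignore_attr = TRUE)

  # single 2 s event at onset 0: column equals HRF convolved boxcar,
  # checked against a direct discrete convolution at the microtime grid
  one <- gpcmvpa:::new_event_schedule(
    data.frame(onset = 0, duration = 2, condition = "neutral"),
    total_duration = 40, seed = 0L)
  dm <- build_design_matrix(one, tr = 2, n_scans = 20, dt = 0.1)
  t_hi <- seq(0, 40, by = 0.1)
  hrf <- canonical_hrf(t_hi)
  box <- as.numeric(t_hi < 2)
  direct <- sapply(seq(0, 38, by = 2), function(ts) {
    i_ts <- which.min(abs(t_hi - ts))
    idx <- seq_len(i_ts)
    sum(box[idx] * hrf[i_ts - idx + 1]) * 0.1
  })
  expect_equal(unname(dm$values[, "neutral"]), direct, tolerance = 1e-8)

  # 20 events/condition: three distinct correlated-but-not-identical columns
  sch <- generate_paradigm(seed = 2)
  dd <- build_design_matrix(sch, tr = 2)
  cc <- cor(dd$values[, dd$conditions])
  expect_true(all(cc[upper.tri(cc)] < 1))

  # motion columns appended verbatim
  mo <- matrix(rnorm(40), 20, 2)
  dmm <- build_design_matrix(one, tr = 2, n_scans = 20, motion = mo)
  expect_equal(unname(dmm$values[, c("motion1", "motion2")]), mo)

  late <- gpcmvpa:::new_event_schedule(
    data.frame(onset = 30, duration = 2, condition = "neutral"),
    total_duration = 40, seed = 0L)
  expect_error(build_design_matrix(late, tr = 2, n_scans = 10),
               "outside the scan window")
})

test_that("fit_glm recovers betas and satisfies OLS identities", {
  sch <- generate_paradigm(n_per_condition = 6, seed = 1)
  des <- build_design_matrix(sch, tr = 2)
  n_scans <- nrow(des$values)
  set.seed(3)
  shape <- c(3, 3, 3)
  betas <- lapply(1:3, function(i) array(rnorm(27), shape))
  names(betas) <- des$conditions
  Y <- sapply(seq_len(27), function(v)
    des$values[, 1:3] %*% sapply(betas, `[`, v))
  ts <- array(t(Y), c(shape, n_scans))
  fit <- fit_glm(ts, des)
  for (cn in des$conditions) expect_equal(fit[[cn]], betas[[cn]])

  # residual orthogonality to every design column
  noisy <- ts + array(rnorm(length(ts)), dim(ts))
  fitn <- fit_glm(noisy, des)
  co <- qr.coef(qr(des$values), t(matrix(noisy, 27, n_scans)))
  resid <- t(matrix(noisy, 27, n_scans)) - des$values %*% co
  expect_lt(max(abs(crossprod(des$values, resid))), 1e-8)

  # intercept shift invariance
  fits <- fit_glm(noisy + 5, des)
  for (cn in des$conditions) expect_equal(fits[[cn]], fitn[[cn]])

  # pure-noise beta estimates are unbiased across seeds
  errs <- sapply(1:100, function(s) {
    set.seed(s)
    nz <- array(rnorm(27 * n_scans), c(shape, n_scans))
    mean(unlist(fit_glm(nz, des)[des$conditions]))
  })
  expect_lt(abs(mean(errs)), 2 * sd(errs) / sqrt(100))

  # duplicated condition column: rank error
  bad <- des
  bad$values <- cbind(des$values, des$values[, 1])
  bad$column_labels <- c(des$column_labels, "dup")
  expect_error(fit_glm(ts, bad), "rank deficient")
  expect_error(fit_glm(ts[, , , 1:3], des), "time dimension")
})

test_that("extract_features is a bijection between mask voxels and columns", {
  g <- null_group(n_subjects = 18, subject_variability = 0)
  rec <- generate_cohort(list(g), c(8, 8, 8), seed = 7)
  mask <- array(FALSE, c(8, 8, 8))
  mask[sample(512, 500)] <- TRUE
  fm <- extract_features(rec, mask = mask,
                         conditions = c("intense_happy", "neutral"))
  expect_equal(dim(fm$values), c(36L, 500L))
  expect_equal(nrow(fm$rows), 36L)
  expect_equal(sort(unique(fm$rows$condition)),
               c("intense_happy", "neutral"))

  # scatter-back reproduces the masked volume
  vol <- features_to_volume(fm, fm$values[1, ])
  orig <- rec[[1]]$betas[[fm$rows$condition[1]]]
  expect_equal(vol[mask], orig[mask])
  expect_true(all(vol[!mask] == 0))

  # single-voxel mask preserves values exactly
  m1 <- array(FALSE, c(8, 8, 8)); m1[2, 3, 4] <- TRUE
  f1 <- extract_features(rec, mask = m1)
  expect_equal(ncol(f1$values), 1L)
  expect_equal(f1$values[1, 1], rec[[1]]$betas$neutral[2, 3, 4])

  # default mask: nonzero-variance voxels
  fmd <- extract_features(rec)
  expect_equal(ncol(fmd$values), sum(fmd$mask))

  # errors: grid mismatch, missing condition
  bad <- rec
  bad[[1]]$betas$neutral <- array(0, c(4, 4, 4))
  expect_error(extract_features(bad), "grid mismatch")
  bad2 <- rec
  bad2[[2]]$betas$mild_happy <- NULL
  expect_error(extract_features(bad2), "missing condition")
})
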