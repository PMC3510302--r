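test_that("balanced_accuracy is the mean of the two rates", {
  expect_equal(balanced_accuracy(0.72, 0.50), 0.61)
  expect_equal(balanced_accuracy(0.83, 0.67), 0.75)
  expect_equal(balanced_accuracy(1, 1), 1)
  expect_error(balanced_accuracy(1.2, 0.5), "\\[0, 1\\]")
  expect_error(balanced_accuracy(0.5, -0.1), "\\[0, 1\\]")
})

test_that("LOSO decoding: structure, leakage guard, separable limit", {
  g <- separable_group(n_subjects = 6)
  rec <- generate_cohort(list(g), c(8, 8, 8), seed = 3)
  fm <- extract_features(rec)
  res <- loso_within_group(fm, c("intense_happy", "neutral"))

  # bookkeeping: one prediction per (subject, condition), n per class
  expect_equal(nrow(res$predictions), 12L)
  expect_equal(sum(res$predictions$true_class == 1), 6L)
  expect_equal(res$accuracy, (res$tp_rate + res$tn_rate) / 2)
  # fold construction: each subject's rows share one fold, held out once
  by_subj <- split(res$predictions$fold_index, res$predictions$subject_id)
  expect_true(all(vapply(by_subj, function(f) length(unique(f)) == 1, TRUE)))
  expect_equal(sort(unique(res$predictions$fold_index)), 1:6)

  # noiseless separable group: perfect accuracy, all confident
  expect_equal(res$accuracy, 1)
  expect_true(all((res$predictions$probability_class1 > 0.5) ==
                    (res$predictions$true_class == 1)))

  # relabeling the contrast swaps TP and TN, accuracy unchanged
  swp <- loso_within_group(fm, c("neutral", "intense_happy"))
  expect_equal(swp$tp_rate, res$tn_rate)
  expect_equal(swp$tn_rate, res$tp_rate)
  expect_equal(swp$accuracy, res$accuracy)

  # missing condition errors
  bad <- subset_features(fm, -1)
  expect_error(loso_within_group(bad, c("intense_happy", "neutral")),
               "exactly one example")
})

test_that("residualize modes and covariates run inside LOSO", {
  g <- group_spec("UD", 6, medication_mean = 1.4, medication_sd = 1.1,
                  substance_prob = 0.4)
  rec <- generate_cohort(list(g), c(6, 6, 6), seed = 8)
  fm <- extract_features(rec)
  cov <- data.frame(subject_id = sapply(rec, `[[`, "subject_id"),
                    medication_load = sapply(rec, `[[`, "medication_load"),
                    substance_history = sapply(rec, `[[`, "substance_history"))
  r1 <- loso_within_group(fm, c("intense_happy", "neutral"), cov,
                          cv_config("train_only"))
  r2 <- loso_within_group(fm, c("intense_happy", "neutral"), cov,
                          cv_config("whole_sample"))
  for (r in list(r1, r2)) {
    expect_true(all(r$predictions$probability_class1 > 0 &
                      r$predictions$probability_class1 < 1))
    expect_equal(r$accuracy, (r$tp_rate + r$tn_rate) / 2)
  }
})

test_that("permutation test: add-one formula, determinism, extremes", {
  # closed-form extremes through a deterministic accuracy function
  y <- rep(c(1, -1), 6)
  units <- rep(1:6, each = 2)
  pt_hi <- permutation_test(function(yy) if (identical(yy, y)) 1 else 0,
                            y, units, n_permutations = 99, seed = 1)
  expect_equal(pt_hi$p_value, 1 / 100)  # observed beats all permutations
  pt_lo <- permutation_test(function(yy) if (identical(yy, y)) 0 else 1,
                            y, units, n_permutations = 99, seed = 1)
  expect_equal(pt_lo$p_value, 1)        # observed below all permutations
  expect_gt(pt_hi$p_value, 0)           # add-one: never zero

  # reproducible under seed
  acc <- function(yy) mean(yy == y)
  a <- permutation_test(acc, y, units, 50, seed = 7)
  b <- permutation_test(acc, y, units, 50, seed = 7)
  expect_identical(a$permuted, b$permuted)

  expect_warning(permutation_test(acc, y, rep(1, 12), 5, seed = 1),
                 "degenerate")
})

test_that("LOSO permutation p-value is significant for separable data", {
  g <- separable_group(n_subjects = 6)
  rec <- generate_cohort(list(g), c(6, 6, 6), seed = 5)
  fm <- extract_features(rec)
  res <- loso_within_group(fm, c("intense_happy", "neutral"),
                           config = cv_config(n_permutations = 49, seed = 2))
  expect_equal(res$accuracy, 1)
  expect_lte(res$p_value, 0.1)
  expect_gt(res$p_value, 0)
})

test_that("LOPO between-group decoding: folds, separable limit, null", {
  gA <- separable_group("A", 5)              # patterns on the unique pools
  gB <- group_spec("B", 5,                   # patterns on the shared pool:
                   pattern_amplitude = c(neutral = 1, mild_happy = 1,
                                         intense_happy = 1),
                   pattern_overlap = 1, subject_variability = 0,
                   noise_sd = 0)             # disjoint from A, noiseless
  rec <- generate_cohort(list(gA, gB), c(8, 8, 8), seed = 6)
  fm <- extract_features(rec)
  fA <- subset_features(fm, fm$rows$group == "A")
  fB <- subset_features(fm, fm$rows$group == "B")
  res <- lopo_between_group(fA, fB, "intense_happy")
  expect_equal(res$n_folds, 5L)
  expect_equal(nrow(res$predictions), 10L)
  # noiseless groups with distinct fixed patterns: perfectly separable
  expect_equal(res$sensitivity, 1)
  expect_equal(res$specificity, 1)
  expect_equal(res$accuracy, 1)
  # no subject appears in train and test of the same fold: structural
  for (k in seq_len(res$n_folds)) {
    held <- res$predictions$subject_id[res$predictions$fold_index == k]
    expect_length(held, 2L)
    expect_equal(length(unique(res$predictions$group[
      res$predictions$fold_index == k])), 2L)
  }
  expect_error(lopo_between_group(fA, subset_features(fB, 1:8),
                                  "intense_happy"),
               "unequal group sizes")
})

test_that("LOPO on identical-spec groups is at chance (null calibration)", {
  accs <- vapply(1:20, function(i) {
    gs <- list(group_spec("A", 10), group_spec("B", 10))
    rec <- generate_cohort(gs, c(12, 12, 12), seed = 400 + i)
    fm <- extract_features(rec)
    lopo_between_group(subset_features(fm, fm$rows$group == "A"),
                       subset_features(fm, fm$rows$group == "B"),
                       "intense_happy")$accuracy
  }, numeric(1))
  half_width <- 1.96 * sqrt(0.25 / (20 * 20))
  expect_lt(abs(mean(accs) - 0.5), half_width)
})

test_that("LOSO is calibrated at chance on null cohorts (empirical-SE yardstick)", {
  # LOSO predictions are correlated across folds (shared training data), so
  # the cohort is the independent replication unit: compare the mean of 100
  # cohort accuracies to 0.5 using the empirical standard error.
  accs <- vapply(1:100, function(i) {
    rec <- generate_cohort(list(null_group()), c(12, 12, 12),
                           seed = 100000 + i)
    loso_within_group(extract_features(rec),
                      c("intense_happy", "neutral"))$accuracy
  }, numeric(1))
  se <- sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 0.5), 3 * se)
  # and the per-cohort spread is overdispersed relative to the binomial
  # model for 36 independent predictions (documented property)
  expect_gt(sd(accs), sqrt(0.25 / 36))
})

test_that("Bonferroni adjustment caps the 9-classifier family", {
  p <- c(0.02, 0.3, 0.8, rep(0.5, 6))
  expect_equal(adjust_pvalues(p)[1], min(1, 0.02 * 9))
  expect_true(all(adjust_pvalues(p) >= p))
})
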