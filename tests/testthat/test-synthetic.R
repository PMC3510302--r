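test_that("generate_paradigm produces a valid, reproducible schedule", {
  s <- generate_paradigm(n_per_condition = 20, stim_duration = 2,
                         isi_mean = 4.9, seed = 1)
  ev <- s$events
  expect_equal(nrow(ev), 60)
  expect_equal(unname(table(ev$condition)[gpcmvpa_conditions()]),
               rep(20L, 3), ignore_attr = TRUE)
  expect_true(all(diff(ev$onset) > 0))
  # non-overlap: next onset >= previous end
  expect_true(all(diff(ev$onset) >= ev$duration[-nrow(ev)]))
  expect_true(all(ev$onset + ev$duration <= s$total_duration))
  # bit-for-bit reproducibility under the seed
  expect_identical(generate_paradigm(seed = 1)$events, ev)
  expect_false(identical(generate_paradigm(seed = 2)$events, ev))

  s1 <- generate_paradigm(n_per_condition = 1, seed = 0)
  expect_equal(nrow(s1$events), 3)
  expect_true(all(diff(s1$events$onset) > 0))

  expect_error(generate_paradigm(n_per_condition = 0), "positive|>= 1")
  expect_error(generate_paradigm(stim_duration = 0), "positive")
  expect_error(generate_paradigm(isi_mean = -1), "positive")
})

test_that("ISI sampler hits the stated 4.9 s mean (Monte Carlo)", {
  isis <- unlist(lapply(1:2000, function(seed) {
    ev <- generate_paradigm(seed = seed)$events
    diff(ev$onset) - ev$duration[-nrow(ev)]
  }))
  expect_gt(length(isis), 100000)
  expect_lt(abs(mean(isis) - 4.9) / 4.9, 0.01)
  # exponential variant has the same mean
  isis_e <- unlist(lapply(1:2000, function(seed) {
    ev <- generate_paradigm(seed = seed, isi_dist = "exponential")$events
    diff(ev$onset) - ev$duration[-nrow(ev)]
  }))
  expect_lt(abs(mean(isis_e) - 4.9) / 4.9, 0.02)
})

test_that("generate_cohort honours group specs and the seed", {
  g <- null_group(n_subjects = 3)
  rec <- generate_cohort(list(g), c(6, 6, 6), seed = 9)
  expect_length(rec, 3)
  expect_identical(rec, generate_cohort(list(g), c(6, 6, 6), seed = 9))
  expect_named(rec[[1]]$betas, gpcmvpa_conditions())
  expect_identical(dim(rec[[1]]$betas$neutral), c(6L, 6L, 6L))
  expect_error(generate_cohort(list()), "at least one")
  expect_error(group_spec("X", n_subjects = 1), ">= 2")
  expect_error(group_spec("X", pattern_overlap = 1.5), "\\[0, 1\\]")
})

test_that("noiseless disjoint patterns are shared across subjects and orthogonal", {
  g <- separable_group(n_subjects = 3)
  rec <- generate_cohort(list(g), c(8, 8, 8), seed = 4)
  b1 <- rec[[1]]$betas
  for (r in rec[-1]) {
    expect_equal(r$betas$intense_happy, b1$intense_happy)
    expect_equal(r$betas$neutral, b1$neutral)
  }
  expect_equal(sum(b1$intense_happy * b1$neutral), 0)
  expect_equal(sum(b1$intense_happy * b1$mild_happy), 0)
})

test_that("happy-vs-neutral contrast scales with pattern amplitude (sample-mean oracle)", {
  mk <- function(label, amp, seed) {
    g <- group_spec(label, 50,
                    pattern_amplitude = c(neutral = 0.5, mild_happy = 0.5,
                                          intense_happy = amp),
                    pattern_overlap = 0, subject_variability = 0,
                    noise_sd = 1)
    generate_cohort(list(g), c(8, 8, 8), seed = seed)
  }
  contrast_norm <- function(rec) {
    d <- Reduce(`+`, lapply(rec, function(r)
      r$betas$intense_happy - r$betas$neutral)) / length(rec)
    sqrt(sum(d^2))
  }
  expect_gt(contrast_norm(mk("A", 1.0, 11)), contrast_norm(mk("B", 0.2, 12)))
})

test_that("expected condition-pattern distance is monotone non-increasing in overlap", {
  dist_at <- function(overlap, seed) {
    g <- group_spec("G", 2,
                    pattern_amplitude = c(neutral = 1, mild_happy = 1,
                                          intense_happy = 1),
                    pattern_overlap = overlap, subject_variability = 0,
                    noise_sd = 0)
    r <- generate_cohort(list(g), c(8, 8, 8), seed = seed)[[1]]
    sqrt(sum((r$betas$intense_happy - r$betas$neutral)^2))
  }
  seeds <- 1:25
  d0 <- mean(sapply(seeds, function(s) dist_at(0, s)))
  d5 <- mean(sapply(seeds, function(s) dist_at(0.5, s)))
  d1 <- mean(sapply(seeds, function(s) dist_at(1, s)))
  expect_gt(d0, d5)
  expect_gt(d5, d1)
})

test_that("simulate_timeseries round-trips through the GLM and has calibrated noise", {
  g <- group_spec("G", 2, subject_variability = 0, noise_sd = 0)
  rec <- generate_cohort(list(g), c(5, 5, 5), seed = 2)[[1]]
  sch <- generate_paradigm(n_per_condition = 5, seed = 3)
  ts <- simulate_timeseries(rec, sch, tr = 2, noise_sd = 0)
  des <- build_design_matrix(sch, tr = 2, n_scans = dim(ts)[4])
  bh <- fit_glm(ts, des)
  for (cn in gpcmvpa_conditions())
    expect_equal(bh[[cn]], rec$betas[[cn]], tolerance = 1e-10)

  # pure noise: all-zero betas, unit noise
  rec0 <- rec
  for (cn in names(rec0$betas)) rec0$betas[[cn]][] <- 0
  ts0 <- simulate_timeseries(rec0, sch, tr = 2, noise_sd = 1, seed = 8)
  expect_lt(abs(mean(ts0)), 0.02)
  expect_lt(abs(sd(ts0) - 1), 0.02)

  expect_error(simulate_timeseries(rec, sch, tr = 2, n_scans = 3),
               "does not fit")
})

test_that("GLM estimates are unbiased under noise (repeated-simulation oracle)", {
  g <- group_spec("G", 2, subject_variability = 0, noise_sd = 0)
  rec <- generate_cohort(list(g), c(4, 4, 4), seed = 5)[[1]]
  sch <- generate_paradigm(n_per_condition = 8, seed = 6)
  des <- build_design_matrix(sch, tr = 2)
  errs <- sapply(1:100, function(seed) {
    ts <- simulate_timeseries(rec, sch, tr = 2, noise_sd = 0.5, seed = seed)
    bh <- fit_glm(ts, des)
    mean(sapply(gpcmvpa_conditions(),
                function(cn) mean(bh[[cn]] - rec$betas[[cn]])))
  })
  se <- sd(errs) / sqrt(length(errs))
  expect_lt(abs(mean(errs)), 2 * se + 1e-12)
})

test_that("cohort and events round-trip through disk formats", {
  g <- null_group(n_subjects = 2, subject_variability = 0)
  rec <- generate_cohort(list(g), c(5, 5, 5), seed = 3)
  dir <- withr::local_tempdir()
  write_cohort(rec, dir)
  back <- read_cohort(dir)
  expect_equal(back[[1]]$betas$neutral, rec[[1]]$betas$neutral,
               tolerance = 1e-6)  # float32 storage
  expect_equal(back[[2]]$medication_load, rec[[2]]$medication_load)

  sch <- generate_paradigm(n_per_condition = 3, seed = 1)
  f <- file.path(dir, "events.tsv")
  write_events(sch, f)
  sch2 <- read_events(f)
  expect_equal(sch2$events, sch$events)

  # NIfTI round trip at float32 precision
  v <- array(rnorm(60), c(3, 4, 5))
  p <- file.path(dir, "v.nii")
  write_nifti(v, p)
  v2 <- read_nifti(p)
  expect_equal(dim(v2), dim(v))
  expect_lt(max(abs(v2 - v)), 1e-6)
  expect_equal(attr(v2, "voxel_size"), c(3, 3, 3))
})
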