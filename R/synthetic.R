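#' @useDynLib gpcmvpa, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Stimulus conditions of the emotional-faces paradigm
#'
#' The three facial-expression intensities, in the fixed order used
#' throughout the package: neutral, mild happy (50% morph), intense happy
#' (100% emotion).
#' @export
gpcmvpa_conditions <- function() c("neutral", "mild_happy", "intense_happy")

new_event_schedule <- function(events, total_duration, seed) {
  structure(list(events = events, total_duration = total_duration,
                 seed = seed), class = "event_schedule")
}

#' Generate a randomized event-related paradigm
#'
#' Builds one run of the three-condition emotional-faces design: `n_per_condition`
#' trials of each condition in uniformly random order, each stimulus shown for
#' `stim_duration` seconds, separated by inter-stimulus intervals with mean
#' `isi_mean` seconds.  A Poisson count in deciseconds (`Poisson(10 * isi_mean) / 10`)
#' gives sub-second granularity at the stated mean; an exponential sampler with
#' the same mean is available via `isi_dist`.
#'
#' @param n_per_condition trials per condition (default 20).
#' @param stim_duration stimulus duration in seconds (default 2).
#' @param isi_mean mean inter-stimulus interval in seconds (default 4.9).
#' @param seed integer RNG seed; fixing it fixes the schedule exactly.
#' @param isi_dist `"poisson"` (deciseconds, default) or `"exponential"`.
#' @return An `event_schedule`: a data frame of events (`onset`, `duration`,
#'   `condition`, seconds, strictly increasing and non-overlapping) plus
#'   `total_duration` (end of last trial + one mean ISI of trailing rest) and
#'   the seed.
#' @export
generate_paradigm <- function(n_per_condition = 20, stim_duration = 2,
                              isi_mean = 4.9, seed = 1,
                              isi_dist = c("poisson", "exponential")) {
  if (n_per_condition < 1 || stim_duration <= 0 || isi_mean <= 0)
    stop("n_per_condition must be >= 1 and durations positive")
  isi_dist <- match.arg(isi_dist)
  n <- 3L * as.integer(n_per_condition)
  withr_seed <- set_local_seed(seed)
  on.exit(withr_seed())
  condition <- sample(rep(gpcmvpa_conditions(), n_per_condition))
  isi <- switch(isi_dist,
    poisson = stats::rpois(n, 10 * isi_mean) / 10,
    exponential = stats::rexp(n, 1 / isi_mean))
  onset <- cumsum(c(0, stim_duration + isi[-n]))
  events <- data.frame(onset = onset, duration = stim_duration,
                       condition = condition, stringsAsFactors = FALSE)
  new_event_schedule(events,
                     total_duration = onset[n] + stim_duration + isi_mean,
                     seed = as.integer(seed))
}

#' @export
print.event_schedule <- function(x, ...) {
  cat(sprintf("event_schedule: %d events over %.1f s\n",
              nrow(x$events), x$total_duration))
  print(table(x$events$condition))
  invisible(x)
}

# Seed handling: save and restore .Random.seed so generators are pure
# functions of their seed argument.
set_local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  }
}

#' Specify one synthetic subject group
#'
#' The generator's two scientific knobs mirror the two candidate mechanisms
#' for degraded within-group decodability: `pattern_overlap` (shared support
#' between the condition-specific spatial patterns — overlapping patterns are
#' harder to separate) and `subject_variability` (between-subject perturbation
#' of the group pattern — heterogeneous patterns generalize poorly across
#' leave-one-subject-out folds).
#'
#' @param label group label, conventionally `"HC"`, `"UD"` or `"BD"`.
#' @param n_subjects number of subjects (>= 2; the study design uses 18).
#' @param pattern_amplitude named numeric: effect size (signal units) of each
#'   condition's spatial pattern.
#' @param pattern_overlap fraction in [0,1] of support shared between
#'   condition patterns.
#' @param subject_variability SD of the per-subject pattern perturbation.
#' @param noise_sd SD of additive voxel noise on each beta volume.
#' @param medication_mean,medication_sd truncated-normal parameters for the
#'   medication-load covariate (patient-group means 1.4 and 2.5 by default
#'   elsewhere; 0 for controls).
#' @param substance_prob probability of a positive substance-history flag.
#' @return A `group_spec` object.
#' @export
group_spec <- function(label, n_subjects = 18,
                       pattern_amplitude = c(neutral = 0.5, mild_happy = 0.5,
                                             intense_happy = 1),
                       pattern_overlap = 0.2, subject_variability = 0.2,
                       noise_sd = 1, medication_mean = 0, medication_sd = 1,
                       substance_prob = 0) {
  if (n_subjects < 2) stop("n_subjects must be >= 2")
  if (pattern_overlap < 0 || pattern_overlap > 1)
    stop("pattern_overlap must lie in [0, 1]")
  if (subject_variability < 0 || noise_sd < 0 || medication_sd < 0)
    stop("standard deviations must be >= 0")
  stopifnot(all(gpcmvpa_conditions() %in% names(pattern_amplitude)))
  structure(list(label = label, n_subjects = as.integer(n_subjects),
                 pattern_amplitude = pattern_amplitude,
                 pattern_overlap = pattern_overlap,
                 subject_variability = subject_variability,
                 noise_sd = noise_sd, medication_mean = medication_mean,
                 medication_sd = medication_sd,
                 substance_prob = substance_prob),
            class = "group_spec")
}

#' Default three-group study design
#'
#' Healthy comparison (HC), unipolar depressed (UD), and bipolar depressed
#' (BD) groups of 18 subjects each, with graded happy-vs-neutral pattern
#' separability (HC > UD > BD) produced by jointly decreasing happy-pattern
#' amplitude and increasing pattern overlap and subject variability, and
#' patient-group covariate distributions matching the study's demographics
#' (medication load 1.4 +/- 1.1 in UD, 2.5 +/- 1.5 in BD; substance history
#' in roughly a quarter of patients).
#' @param n_subjects subjects per group (default 18).
#' @export
default_groups <- function(n_subjects = 18) {
  list(
    group_spec("HC", n_subjects,
               pattern_amplitude = c(neutral = 0.6, mild_happy = 0.8,
                                     intense_happy = 1.0),
               pattern_overlap = 0.1, subject_variability = 0.15,
               noise_sd = 1),
    group_spec("UD", n_subjects,
               pattern_amplitude = c(neutral = 0.6, mild_happy = 0.45,
                                     intense_happy = 0.65),
               pattern_overlap = 0.35, subject_variability = 0.3,
               noise_sd = 1, medication_mean = 1.4, medication_sd = 1.1,
               substance_prob = 4 / 18),
    group_spec("BD", n_subjects,
               pattern_amplitude = c(neutral = 0.6, mild_happy = 0.35,
                                     intense_happy = 0.45),
               pattern_overlap = 0.55, subject_variability = 0.45,
               noise_sd = 1, medication_mean = 2.5, medication_sd = 1.5,
               substance_prob = 5 / 18))
}

# Cohort-level pattern pool: a shared candidate support S plus one unique
# candidate support per condition (all disjoint), with fixed U(0.5, 1.5)
# unit magnitudes per (voxel, condition).  Drawn once per cohort so that all
# groups express the *same* underlying condition networks: two groups with
# identical specs get identical patterns (and are indistinguishable up to
# noise), while groups differing in amplitude/overlap express the networks
# more or less separably.
make_pattern_pool <- function(grid_shape, support_frac = 0.1) {
  n_vox <- prod(grid_shape)
  conds <- gpcmvpa_conditions()
  m <- max(2L, min(round(support_frac * n_vox),
                   floor(n_vox / (length(conds) + 1))))
  idx <- sample.int(n_vox, (length(conds) + 1L) * m)
  shared <- idx[seq_len(m)]
  uniq <- lapply(seq_along(conds), function(k) idx[k * m + seq_len(m)])
  names(uniq) <- conds
  vals_shared <- matrix(stats::runif(m * length(conds), 0.5, 1.5), m,
                        length(conds), dimnames = list(NULL, conds))
  vals_uniq <- matrix(stats::runif(m * length(conds), 0.5, 1.5), m,
                      length(conds), dimnames = list(NULL, conds))
  list(m = m, shared = shared, uniq = uniq,
       vals_shared = vals_shared, vals_uniq = vals_uniq,
       grid_shape = grid_shape)
}

# Instantiate one group's condition patterns from the cohort pool: a
# fraction `overlap` of each condition's m-voxel support comes from the
# shared pool (common to all conditions), the rest from the condition's
# unique pool, scaled by the group's amplitude.
make_group_patterns <- function(pool, amplitudes, overlap) {
  n_vox <- prod(pool$grid_shape)
  n_shared <- round(overlap * pool$m)
  patterns <- list()
  for (cn in names(pool$uniq)) {
    p <- numeric(n_vox)
    if (n_shared > 0) {
      i <- seq_len(n_shared)
      p[pool$shared[i]] <- amplitudes[[cn]] * pool$vals_shared[i, cn]
    }
    if (n_shared < pool$m) {
      j <- seq_len(pool$m - n_shared)
      p[pool$uniq[[cn]][j]] <- amplitudes[[cn]] * pool$vals_uniq[j, cn]
    }
    patterns[[cn]] <- array(p, dim = pool$grid_shape)
  }
  patterns
}

#' Generate a synthetic cohort of subjects with condition beta volumes
#'
#' A cohort-level pool of sparse condition networks (~10% of the grid per
#' condition) is drawn once and shared by all groups, so groups express the
#' same underlying networks: a group's condition pattern takes a
#' `pattern_overlap` fraction of its support from the condition-shared pool
#' (overlapping patterns are less separable) and the rest from the
#' condition's unique pool, scaled by the group's `pattern_amplitude`.
#' Groups generated from identical specs therefore have identical patterns
#' and differ only in noise.  Each subject's beta volume is the group
#' pattern plus an independent Gaussian per-subject perturbation (SD
#' `subject_variability`) plus white voxel noise (SD `noise_sd`).
#' Covariates are sampled per group: medication load from a normal truncated
#' at zero, substance history as a Bernoulli flag.
#'
#' @param groups list of [group_spec] objects (see [default_groups()]).
#' @param grid_shape integer length-3 voxel grid (default 12^3, a desk-scale
#'   stand-in for a whole-brain 3 mm grid).
#' @param seed integer seed; output is a deterministic function of it.
#' @param support_frac fraction of grid voxels in each condition's support.
#' @return List of `subject_record` objects with fields `subject_id`, `group`,
#'   `medication_load`, `substance_history`, and `betas` (named list of 3-D
#'   arrays, one per condition).
#' @export
generate_cohort <- function(groups, grid_shape = c(12, 12, 12), seed = 1,
                            support_frac = 0.1) {
  if (length(groups) == 0) stop("need at least one group_spec")
  if (inherits(groups, "group_spec")) groups <- list(groups)
  stopifnot(all(vapply(groups, inherits, TRUE, "group_spec")),
            length(grid_shape) == 3, all(grid_shape >= 4))
  restore <- set_local_seed(seed)
  on.exit(restore())
  conds <- gpcmvpa_conditions()
  n_vox <- prod(grid_shape)
  pool <- make_pattern_pool(grid_shape, support_frac)
  records <- list()
  for (g in groups) {
    patterns <- make_group_patterns(pool, g$pattern_amplitude,
                                    g$pattern_overlap)
    for (s in seq_len(g$n_subjects)) {
      betas <- list()
      for (cn in conds) {
        vol <- patterns[[cn]]
        if (g$subject_variability > 0)
          vol <- vol + stats::rnorm(n_vox, sd = g$subject_variability)
        if (g$noise_sd > 0)
          vol <- vol + stats::rnorm(n_vox, sd = g$noise_sd)
        betas[[cn]] <- array(vol, dim = grid_shape)
      }
      med <- if (g$medication_mean > 0 || g$medication_sd > 0) {
        m <- stats::rnorm(1, g$medication_mean, g$medication_sd)
        max(0, m)
      } else 0
      records[[length(records) + 1L]] <- structure(list(
        subject_id = sprintf("%s_%02d", g$label, s),
        group = g$label,
        medication_load = med,
        substance_history = as.integer(stats::runif(1) < g$substance_prob),
        betas = betas), class = "subject_record")
    }
  }
  records
}

#' Simulate a BOLD time series from a subject's beta volumes
#'
#' Forward model of the first-level GLM: the voxelwise time series is the sum
#' over conditions of (beta volume) x (HRF-convolved condition boxcar),
#' sampled at the scan times, plus white Gaussian noise.  The generative
#' design matrix is exactly the one [build_design_matrix()] produces for the
#' same schedule, so a noiseless simulation round-trips through [fit_glm()].
#'
#' @param subject a `subject_record`.
#' @param schedule an `event_schedule`.
#' @param tr repetition time in seconds (default 2, the acquisition TR).
#' @param noise_sd SD of additive scanner noise.
#' @param seed integer seed for the noise.
#' @param n_scans number of volumes; defaults to `ceiling(total_duration / tr)`.
#' @return 4-D array (x, y, z, time).
#' @export
simulate_timeseries <- function(subject, schedule, tr = 2, noise_sd = 0,
                                seed = 1, n_scans = NULL) {
  stopifnot(inherits(subject, "subject_record"),
            inherits(schedule, "event_schedule"), tr > 0)
  if (is.null(n_scans)) n_scans <- ceiling(schedule$total_duration / tr)
  ev_end <- max(schedule$events$onset + schedule$events$duration)
  if (ev_end > n_scans * tr)
    stop("schedule does not fit within n_scans * tr")
  design <- build_design_matrix(schedule, tr = tr, n_scans = n_scans)
  conds <- design$conditions
  grid_shape <- dim(subject$betas[[1]])
  n_vox <- prod(grid_shape)
  B <- vapply(conds, function(cn) as.numeric(subject$betas[[cn]]),
              numeric(n_vox))            # n_vox x n_cond
  Y <- design$values[, conds, drop = FALSE] %*% t(B)   # n_scans x n_vox
  if (noise_sd > 0) {
    restore <- set_local_seed(seed)
    on.exit(restore())
    Y <- Y + stats::rnorm(length(Y), sd = noise_sd)
  }
  array(t(Y), dim = c(grid_shape, n_scans))
}

#' Write a cohort to disk (NIfTI volumes + covariate CSV)
#'
#' One `<subject_id>_<condition>.nii.gz` per beta volume and a
#' `participants.csv` with `subject_id`, `group`, `medication_load`,
#' `substance_history`.
#' @param records list of `subject_record`s.
#' @param dir output directory (created if needed).
#' @export
write_cohort <- function(records, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (r in records)
    for (cn in names(r$betas))
      write_nifti(r$betas[[cn]], file.path(dir, paste0(r$subject_id, "_", cn, ".nii.gz")))
  cov <- data.frame(
    subject_id = vapply(records, `[[`, "", "subject_id"),
    group = vapply(records, `[[`, "", "group"),
    medication_load = vapply(records, `[[`, 0, "medication_load"),
    substance_history = vapply(records, `[[`, 0L, "substance_history"))
  utils::write.csv(cov, file.path(dir, "participants.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @param conditions condition names expected on disk.
#' @export
read_cohort <- function(dir, conditions = gpcmvpa_conditions()) {
  cov <- utils::read.csv(file.path(dir, "participants.csv"),
                         stringsAsFactors = FALSE)
  lapply(seq_len(nrow(cov)), function(i) {
    betas <- lapply(conditions, function(cn) {
      v <- read_nifti(file.path(dir, paste0(cov$subject_id[i], "_", cn, ".nii.gz")))
      attr(v, "voxel_size") <- NULL
      v
    })
    names(betas) <- conditions
    structure(list(subject_id = cov$subject_id[i], group = cov$group[i],
                   medication_load = cov$medication_load[i],
                   substance_history = cov$substance_history[i],
                   betas = betas), class = "subject_record")
  })
}
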