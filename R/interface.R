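#' Threshold a discriminating weight map
#'
#' Keeps voxels whose absolute weight reaches `fraction` of the maximum
#' absolute weight (ties at the cutoff are retained, so `fraction = 1` keeps
#' the maximal voxels); all other voxels are zeroed.  Signs and magnitudes of
#' surviving voxels are untouched: positive weights are evidence for class 1,
#' negative for class 2.
#'
#' @param weights 3-D numeric array of signed weights.
#' @param fraction cutoff fraction in (0, 1]; the conventional display value
#'   is 0.3 (30% of the maximum weight).
#' @return Thresholded array of the same shape.
#' @export
threshold_map <- function(weights, fraction = 0.3) {
  stopifnot(is.array(weights), fraction > 0, fraction <= 1)
  mx <- max(abs(weights))
  if (mx == 0) {
    warning("all-zero weight map: thresholding returns an empty map")
    return(weights)
  }
  out <- weights
  out[abs(weights) < fraction * mx] <- 0
  out
}

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis.  Serializes to and
#' from a flat `key: value` text file so runs are reproducible from a single
#' artifact.
#'
#' @param groups list of [group_spec()]s (default [default_groups()]).
#' @param grid_shape simulation grid (default 12^3).
#' @param contrasts list of length-2 condition vectors, class 1 first.
#' @param residualize_mode see [cv_config()].
#' @param gpc see [gpc_opts()].
#' @param n_permutations permutations per classifier (default 1000).
#' @param alpha second-level significance level.
#' @param map_threshold weight-map display cutoff fraction.
#' @param seed master seed; all stage seeds derive from it.
#' @param out_dir optional output directory; when set, stages persist
#'   their tables as they complete.
#' @export
pipeline_config <- function(groups = default_groups(),
                            grid_shape = c(12, 12, 12),
                            contrasts = list(c("intense_happy", "neutral"),
                                             c("mild_happy", "neutral")),
                            residualize_mode = "train_only",
                            gpc = gpc_opts(), n_permutations = 1000,
                            alpha = 0.05, map_threshold = 0.3, seed = 1,
                            out_dir = NULL) {
  stopifnot(map_threshold > 0, map_threshold <= 1)
  structure(list(groups = groups, grid_shape = grid_shape,
                 contrasts = contrasts, residualize_mode = residualize_mode,
                 gpc = gpc, n_permutations = as.integer(n_permutations),
                 alpha = alpha, map_threshold = map_threshold,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full two-level analysis on a simulated cohort
#'
#' Stages: simulate the cohort; extract whole-brain features per group
#' (nonzero-variance mask over the whole cohort); within-group LOSO decoding
#' for every contrast and group (with permutation test and confound
#' residualization for groups that carry covariates); second-level ANOVA +
#' Newman-Keuls on the held-out predictive probabilities; between-group
#' leave-one-pair-out decoding for every group pair and condition (with
#' Bonferroni adjustment across the family); full-group discriminating
#' weight maps, thresholded for display.  Fully deterministic under
#' `config$seed`.
#'
#' @param config a [pipeline_config()].
#' @param records optionally, a pre-generated cohort (skips simulation).
#' @return A `results_bundle` list: `within`, `second_level`, `between`,
#'   `between_table`, `weight_maps`, `thresholded_maps`, `covariates`,
#'   `provenance`.
#' @export
run_pipeline <- function(config = pipeline_config(), records = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  if (is.null(records))
    records <- generate_cohort(config$groups, config$grid_shape,
                               seed = config$seed)
  covariates <- data.frame(
    subject_id = vapply(records, `[[`, "", "subject_id"),
    group = vapply(records, `[[`, "", "group"),
    medication_load = vapply(records, `[[`, 0, "medication_load"),
    substance_history = as.numeric(vapply(records, `[[`, 0L,
                                          "substance_history")),
    stringsAsFactors = FALSE)
  features <- extract_features(records)
  group_labels <- unique(features$rows$group)
  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)

  # patient groups carry covariates; controls get intercept-only centering
  cov_for <- function(g) {
    cg <- covariates[covariates$group == g, , drop = FALSE]
    if (all(cg$medication_load == 0) && all(cg$substance_history == 0)) NULL
    else cg
  }

  within <- list()
  within_rows <- data.frame()
  stage_seed <- config$seed
  for (contrast in config$contrasts) {
    for (g in group_labels) {
      stage_seed <- stage_seed + 1L
      cfg <- cv_config(config$residualize_mode, config$gpc,
                       config$n_permutations, stage_seed)
      res <- loso_within_group(features, contrast, cov_for(g), cfg, group = g)
      within[[paste(contrast[1], g, sep = ".")]] <- res
      within_rows <- rbind(within_rows, data.frame(
        contrast = paste(contrast[1], "vs", contrast[2]), group = g,
        accuracy = res$accuracy, tp_rate = res$tp_rate,
        tn_rate = res$tn_rate, p_value = res$p_value,
        stringsAsFactors = FALSE))
    }
  }
  if (!is.null(out_dir))
    utils::write.csv(within_rows, file.path(out_dir, "within_group.csv"),
                     row.names = FALSE)

  second_level <- lapply(config$contrasts, function(contrast) {
    keys <- paste(contrast[1], group_labels, sep = ".")
    second_level_report(within[keys], alpha = config$alpha)
  })
  names(second_level) <- vapply(config$contrasts, `[`, "", 1)
  if (!is.null(out_dir)) {
    sl <- do.call(rbind, lapply(second_level, `[[`, "anova_table"))
    utils::write.csv(sl, file.path(out_dir, "second_level_anova.csv"),
                     row.names = FALSE)
  }

  between <- list()
  between_rows <- data.frame()
  group_feats <- lapply(group_labels, function(g)
    subset_features(features, features$rows$group == g))
  names(group_feats) <- group_labels
  pairs <- utils::combn(group_labels, 2, simplify = FALSE)
  for (pair in pairs) {
    for (cond in gpcmvpa_conditions()) {
      stage_seed <- stage_seed + 1L
      cfg <- cv_config(config$residualize_mode, config$gpc,
                       config$n_permutations, stage_seed)
      res <- lopo_between_group(group_feats[[pair[1]]],
                                group_feats[[pair[2]]], cond, config = cfg)
      between[[paste(pair[1], pair[2], cond, sep = ".")]] <- res
      between_rows <- rbind(between_rows, data.frame(
        group_a = pair[1], group_b = pair[2], condition = cond,
        sensitivity = res$sensitivity, specificity = res$specificity,
        accuracy = res$accuracy, p_value = res$p_value,
        stringsAsFactors = FALSE))
    }
  }
  between_rows$p_adjusted <- adjust_pvalues(between_rows$p_value)
  if (!is.null(out_dir))
    utils::write.csv(between_rows, file.path(out_dir, "between_group.csv"),
                     row.names = FALSE)

  # full-group discriminating maps (one per within-group classifier)
  weight_maps <- list()
  thresholded <- list()
  for (contrast in config$contrasts) {
    for (g in group_labels) {
      key <- paste(contrast[1], g, sep = ".")
      sub <- subset_features(features,
                             features$rows$group == g &
                               features$rows$condition %in% contrast)
      yy <- ifelse(sub$rows$condition == contrast[1], 1, -1)
      cc <- covariate_matrix(sub, cov_for(g))
      sub_r <- residualize(sub, cc, "whole_sample")
      model <- gpc_train(sub_r, yy, config$gpc)
      wm <- weight_map(model, sub_r)
      weight_maps[[key]] <- wm
      thresholded[[key]] <- threshold_map(wm, config$map_threshold)
      if (!is.null(out_dir)) {
        write_nifti(wm, file.path(out_dir, paste0("weights_", key, ".nii.gz")))
        write_nifti(thresholded[[key]],
                    file.path(out_dir, paste0("weights_", key, "_thr.nii.gz")))
      }
    }
  }

  bundle <- structure(list(
    within = within, within_table = within_rows,
    second_level = second_level,
    between = between, between_table = between_rows,
    weight_maps = weight_maps, thresholded_maps = thresholded,
    covariates = covariates,
    provenance = list(seed = config$seed,
                      package_version = as.character(
                        utils::packageVersion("gpcmvpa")),
                      n_subjects = length(records),
                      grid_shape = config$grid_shape,
                      started = format(t0), finished = format(Sys.time()))),
    class = "results_bundle")
  if (!is.null(out_dir)) {
    jsonlite::write_json(
      list(within = within_rows, between = between_rows,
           second_level = lapply(second_level, `[[`, "anova_table"),
           provenance = bundle$provenance, schema_version = "1.0"),
      file.path(out_dir, "results.json"), auto_unbox = TRUE, digits = NA)
  }
  bundle
}

#' @export
print.results_bundle <- function(x, ...) {
  cat("results_bundle\n== within-group decoding ==\n")
  print(x$within_table, row.names = FALSE)
  cat("== between-group decoding ==\n")
  print(x$between_table, row.names = FALSE)
  invisible(x)
}

#' Read and write flat key-value configuration files
#'
#' A minimal YAML-dialect (`key: value`, `#` comments) covering the scalar
#' pipeline settings.  Group specifications use dotted keys
#' (`group.<label>.<field>`, with `pattern_amplitude` as three comma-separated
#' values in condition order).
#'
#' @param config a [pipeline_config()].
#' @param path file path.
#' @export
write_config <- function(config, path) {
  lines <- c(
    sprintf("grid_shape: %s", paste(config$grid_shape, collapse = ",")),
    sprintf("contrasts: %s",
            paste(vapply(config$contrasts, paste, "", collapse = "|"),
                  collapse = ";")),
    sprintf("residualize_mode: %s", config$residualize_mode),
    sprintf("n_permutations: %d", config$n_permutations),
    sprintf("alpha: %g", config$alpha),
    sprintf("map_threshold: %g", config$map_threshold),
    sprintf("seed: %d", config$seed),
    sprintf("gpc_bias: %g", config$gpc$bias),
    sprintf("gpc_normalize: %s", config$gpc$normalize))
  for (g in config$groups) {
    pre <- paste0("group.", g$label, ".")
    lines <- c(lines,
      sprintf("%sn_subjects: %d", pre, g$n_subjects),
      sprintf("%spattern_amplitude: %s", pre,
              paste(g$pattern_amplitude[gpcmvpa_conditions()], collapse = ",")),
      sprintf("%spattern_overlap: %g", pre, g$pattern_overlap),
      sprintf("%ssubject_variability: %g", pre, g$subject_variability),
      sprintf("%snoise_sd: %g", pre, g$noise_sd),
      sprintf("%smedication_mean: %g", pre, g$medication_mean),
      sprintf("%smedication_sd: %g", pre, g$medication_sd),
      sprintf("%ssubstance_prob: %g", pre, g$substance_prob))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- grep("^\\s*(#|$)", readLines(path), invert = TRUE, value = TRUE)
  kv <- regmatches(lines, regexec("^\\s*([^:]+):\\s*(.*)$", lines))
  keys <- vapply(kv, `[`, "", 2)
  vals <- trimws(vapply(kv, `[`, "", 3))
  names(vals) <- trimws(keys)
  gkeys <- grep("^group\\.", names(vals), value = TRUE)
  glabels <- unique(vapply(strsplit(gkeys, "\\."), `[`, "", 2))
  groups <- lapply(glabels, function(lab) {
    g <- function(f) vals[[paste0("group.", lab, ".", f)]]
    amp <- as.numeric(strsplit(g("pattern_amplitude"), ",")[[1]])
    names(amp) <- gpcmvpa_conditions()
    group_spec(lab, as.integer(g("n_subjects")), amp,
               as.numeric(g("pattern_overlap")),
               as.numeric(g("subject_variability")),
               as.numeric(g("noise_sd")),
               as.numeric(g("medication_mean")),
               as.numeric(g("medication_sd")),
               as.numeric(g("substance_prob")))
  })
  contrasts <- lapply(strsplit(vals[["contrasts"]], ";")[[1]],
                      function(s) strsplit(s, "\\|")[[1]])
  pipeline_config(
    groups = groups,
    grid_shape = as.integer(strsplit(vals[["grid_shape"]], ",")[[1]]),
    contrasts = contrasts,
    residualize_mode = vals[["residualize_mode"]],
    gpc = gpc_opts(bias = as.numeric(vals[["gpc_bias"]]),
                   normalize = as.logical(vals[["gpc_normalize"]])),
    n_permutations = as.integer(vals[["n_permutations"]]),
    alpha = as.numeric(vals[["alpha"]]),
    map_threshold = as.numeric(vals[["map_threshold"]]),
    seed = as.integer(vals[["seed"]]))
}
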