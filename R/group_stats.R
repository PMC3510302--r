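#' One-way analysis of variance on per-subject values
#'
#' Standard between/within sum-of-squares decomposition, used at the second
#' level to test for a group effect on the cross-validated predictive
#' probabilities.
#'
#' @param samples named list: one numeric vector of per-subject values per
#'   group (>= 2 groups, each with >= 2 values).
#' @return An `anova_result`: `F`, `df_between`, `df_within`, `p`,
#'   `group_means`, `mse` (the within-group mean square), sums of squares.
#' @export
anova_oneway <- function(samples) {
  stopifnot(is.list(samples), length(samples) >= 2)
  if (any(vapply(samples, length, 0L) < 2))
    stop("every group needs at least 2 values")
  k <- length(samples)
  n_i <- vapply(samples, length, 0L)
  N <- sum(n_i)
  all_v <- unlist(samples, use.names = FALSE)
  grand <- mean(all_v)
  means <- vapply(samples, mean, 0)
  ss_between <- sum(n_i * (means - grand)^2)
  ss_within <- sum(vapply(samples, function(v) sum((v - mean(v))^2), 0))
  df_b <- k - 1L
  df_w <- N - k
  ms_b <- ss_between / df_b
  mse <- ss_within / df_w
  Fstat <- if (mse == 0) { if (ms_b == 0) 0 else Inf } else ms_b / mse
  p <- if (is.infinite(Fstat)) 0 else stats::pf(Fstat, df_b, df_w,
                                                lower.tail = FALSE)
  structure(list(F = Fstat, df_between = df_b, df_within = df_w, p = p,
                 group_means = means, mse = mse,
                 ss_between = ss_between, ss_within = ss_within,
                 ss_total = sum((all_v - grand)^2), n = n_i),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d, %d) = %.3f, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p))
  invisible(x)
}

#' Newman-Keuls step-down post-hoc comparisons
#'
#' Compares ordered group means with studentized-range statistics
#' `q = |m_i - m_j| / sqrt(MSE / n)` against critical values whose span `r`
#' equals the number of means enclosed by the comparison.  The step-down
#' stopping rule applies: if a wider range is not significant, every
#' comparison nested inside it is declared not significant without testing.
#' Unequal group sizes fall back to the harmonic mean n with a warning.
#'
#' @param samples named list of per-group numeric vectors.
#' @param alpha familywise level for each span (default 0.05).
#' @param anova optional precomputed [anova_oneway()] result for these
#'   samples (computed if missing).
#' @return A `posthoc_result` data frame: one row per pair with `group_i`,
#'   `group_j` (means ordered so `mean_i <= mean_j`), `q`, span `r`,
#'   `critical`, approximate `p` (from the studentized-range distribution at
#'   span `r`), and the step-down `significant` decision.
#' @export
newman_keuls <- function(samples, alpha = 0.05, anova = NULL) {
  if (is.null(anova)) anova <- anova_oneway(samples)
  n_i <- vapply(samples, length, 0L)
  n <- if (length(unique(n_i)) == 1) n_i[1] else {
    warning("unequal group sizes: using harmonic mean n")
    length(n_i) / sum(1 / n_i)
  }
  ord <- order(anova$group_means)
  means <- anova$group_means[ord]
  labels <- names(samples)[ord]
  k <- length(means)
  se <- sqrt(anova$mse / n)
  pairs <- list()
  sig <- matrix(NA, k, k)  # decision cache in sorted-order indices
  # visit pairs widest span first so the blocking rule can propagate
  spans <- do.call(rbind, lapply(seq(k, 2), function(r) {
    i <- seq_len(k - r + 1)
    cbind(i = i, j = i + r - 1L, r = r)
  }))
  out <- data.frame()
  for (row in seq_len(nrow(spans))) {
    i <- spans[row, "i"]; j <- spans[row, "j"]; r <- spans[row, "r"]
    q <- if (se == 0) { if (means[j] == means[i]) 0 else Inf }
         else (means[j] - means[i]) / se
    crit <- stats::qtukey(1 - alpha, r, anova$df_within)
    p <- if (is.infinite(q)) 0 else
      stats::ptukey(q, r, anova$df_within, lower.tail = FALSE)
    # blocked if any enclosing range was non-significant
    blocked <- FALSE
    if (r < k) {
      for (ii in seq_len(i)) for (jj in j:k) {
        if ((jj - ii + 1L) > r && isFALSE(sig[ii, jj])) blocked <- TRUE
      }
    }
    decision <- if (blocked) FALSE else q > crit
    sig[i, j] <- decision
    out <- rbind(out, data.frame(
      group_i = labels[i], group_j = labels[j],
      mean_i = unname(means[i]), mean_j = unname(means[j]),
      q = q, r = r, critical = crit, p = p,
      significant = decision, blocked = blocked,
      stringsAsFactors = FALSE))
  }
  structure(out, class = c("posthoc_result", "data.frame"),
            alpha = alpha)
}

#' Second-level report: group effect on predictive probabilities
#'
#' Assembles, for each stimulus class of a contrast, the per-subject held-out
#' predictive probabilities from each group's within-group classifier into
#' one sample per group, then runs a one-way ANOVA and Newman-Keuls post-hoc
#' tests.  Probabilities of class-2 examples are reported on the class-2
#' scale (`1 - probability_class1`) so that "probability for neutral" is a
#' classifier-confidence measure comparable across groups.
#'
#' @param within_results list of `within_group_result`s for the same
#'   contrast, one per group.
#' @param alpha post-hoc level.
#' @return A `second_level_report`: per stimulus class, the
#'   `probability_samples`, `anova_result` and `posthoc_result`, plus a flat
#'   summary table.
#' @export
second_level_report <- function(within_results, alpha = 0.05) {
  stopifnot(length(within_results) >= 2,
            all(vapply(within_results, inherits, TRUE, "within_group_result")))
  contrast <- within_results[[1]]$contrast
  for (w in within_results)
    if (!identical(w$contrast, contrast))
      stop("within-group results mix different contrasts")
  groups <- vapply(within_results, function(w) w$group[1], "")
  if (anyDuplicated(groups)) stop("duplicate group in within_results")
  per_class <- list()
  summary_rows <- data.frame()
  for (ci in 1:2) {
    cls <- contrast[ci]
    samples <- lapply(within_results, function(w) {
      pr <- w$predictions
      p1 <- pr$probability_class1[pr$condition == cls]
      if (ci == 1) p1 else 1 - p1
    })
    names(samples) <- groups
    an <- anova_oneway(samples)
    nk <- newman_keuls(samples, alpha = alpha, anova = an)
    per_class[[cls]] <- list(samples = samples, anova = an, posthoc = nk)
    summary_rows <- rbind(summary_rows, data.frame(
      stimulus_class = cls, F = an$F, df_between = an$df_between,
      df_within = an$df_within, p = an$p,
      t(setNames(an$group_means, paste0("mean_", groups))),
      stringsAsFactors = FALSE))
  }
  structure(list(contrast = contrast, groups = groups,
                 per_class = per_class, anova_table = summary_rows,
                 alpha = alpha),
            class = "second_level_report")
}

#' @export
print.second_level_report <- function(x, ...) {
  cat(sprintf("second-level report: %s vs %s (%s)\n", x$contrast[1],
              x$contrast[2], paste(x$groups, collapse = ", ")))
  print(x$anova_table, row.names = FALSE)
  for (cls in names(x$per_class)) {
    cat("post-hoc (", cls, "):\n", sep = "")
    ph <- x$per_class[[cls]]$posthoc
    print(ph[, c("group_i", "group_j", "q", "r", "p", "significant")],
          row.names = FALSE)
  }
  invisible(x)
}
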