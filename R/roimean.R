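# Mean-activation-level analysis in shared ROIs, paired t-tests,
# Bonferroni adjustment, and the behavioral recall comparison.

#' Mean contrast effect over an ROI
#'
#' Arithmetic mean of the (unwhitened) contrast parameter estimates over
#' the ROI voxels — the "parametric estimate" scale, not t values.
#'
#' @param fit_contrast a `contrast_map` (or bare 3D effect array).
#' @param roi a `shared_roi`.
#' @return scalar mean effect.
#' @export
roi_mean_contrast <- function(fit_contrast, roi) {
  eff <- if (inherits(fit_contrast, "contrast_map")) fit_contrast$effect else fit_contrast
  if (!length(roi$voxel_idx)) stopf("roi_mean_contrast: empty ROI")
  if (max(roi$voxel_idx) > length(eff)) {
    stopf("roi_mean_contrast: ROI voxels outside map grid")
  }
  mean(eff[roi$voxel_idx])
}

#' Paired t-test on two matched samples
#'
#' @param a,b numeric vectors of equal length n >= 2.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`
#'   for the mean of `a - b`.
#' @return list: `t`, `p_raw`, `dof`, `mean_diff`, `alternative`.
#' @export
paired_t_test <- function(a, b, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(a) != length(b)) stopf("paired_t_test: unequal lengths")
  n <- length(a)
  if (n < 2) stopf("paired_t_test: need n >= 2")
  d <- a - b
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    # identical samples are a well-defined null (t = 0); a constant
    # nonzero difference is genuinely degenerate
    if (all(d == 0)) {
      return(list(t = 0, p_raw = if (alternative == "two.sided") 1 else 0.5,
                  dof = n - 1, mean_diff = 0, alternative = alternative))
    }
    stopf("paired_t_test: zero-variance differences (degenerate)")
  }
  tv <- mean(d) / (sd_d / sqrt(n))
  dof <- n - 1
  p <- switch(alternative,
              two.sided = 2 * stats::pt(-abs(tv), dof),
              greater = stats::pt(tv, dof, lower.tail = FALSE),
              less = stats::pt(tv, dof))
  list(t = tv, p_raw = p, dof = dof, mean_diff = mean(d),
       alternative = alternative)
}

#' Bonferroni adjustment
#'
#' @param p_values numeric vector of p values in [0, 1].
#' @param m number of comparisons, `m >= length(p_values)`.
#' @return adjusted p values, `min(1, m * p)`.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (any(p_values < 0 | p_values > 1)) stopf("bonferroni: p outside [0, 1]")
  if (m < length(p_values)) stopf("bonferroni: m < number of p values")
  pmin(1, m * p_values)
}

#' Mean-level comparison of two contrasts across shared ROIs
#'
#' For each ROI, per-subject mean contrast effects for the two contrasts
#' are compared with a paired t-test; p values are Bonferroni-adjusted
#' over the number of ROIs tested.
#'
#' @param contrasts_a,contrasts_b per-subject `contrast_map` lists (one
#'   per subject), e.g. NA>NR and NV>NR.
#' @param rois list of `shared_roi`s.
#' @param alternative passed to [paired_t_test()].
#' @return data.frame: roi, n, mean_a, mean_b, t, dof, p_raw, p_adjusted,
#'   m_comparisons, alternative.
#' @export
mean_level_table <- function(contrasts_a, contrasts_b, rois,
                             alternative = "two.sided") {
  rows <- lapply(rois, function(roi) {
    av <- vapply(contrasts_a, roi_mean_contrast, numeric(1), roi = roi)
    bv <- vapply(contrasts_b, roi_mean_contrast, numeric(1), roi = roi)
    tt <- paired_t_test(av, bv, alternative)
    data.frame(roi = roi$name, n = length(av), mean_a = mean(av),
               mean_b = mean(bv), t = tt$t, dof = tt$dof, p_raw = tt$p_raw,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_adjusted <- bonferroni(out$p_raw, nrow(out))
  out$m_comparisons <- nrow(out)
  out$alternative <- alternative
  out
}

#' Behavioral recall comparison between two tasks
#'
#' @param behavior data.frame with columns `subject`, `task`, `accuracy`
#'   (in [0, 1]); every subject must have both tasks.
#' @param tasks the two task labels to compare (default NA vs NV).
#' @return list: `means`, `sds` (named per task), `test` (paired t result).
#' @export
compare_recall <- function(behavior, tasks = c("NA", "NV")) {
  if (any(behavior$accuracy < 0 | behavior$accuracy > 1)) {
    stopf("compare_recall: accuracies outside [0, 1]")
  }
  wide <- lapply(tasks, function(tk) {
    sub <- behavior[behavior$task == tk, ]
    stats::setNames(sub$accuracy, sub$subject)
  })
  subjects <- sort(unique(behavior$subject))
  missing <- lapply(wide, function(w) setdiff(subjects, names(w)))
  if (any(lengths(missing) > 0)) {
    stopf("compare_recall: missing cells for subjects: %s",
          paste(unique(unlist(missing)), collapse = ", "))
  }
  a <- wide[[1]][as.character(subjects)]
  b <- wide[[2]][as.character(subjects)]
  list(means = stats::setNames(c(mean(a), mean(b)), tasks),
       sds = stats::setNames(c(stats::sd(a), stats::sd(b)), tasks),
       test = paired_t_test(a, b))
}
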