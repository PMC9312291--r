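# Multi-voxel pattern analysis in shared ROIs: ROI time-series
# extraction, the two-step (temporal then spatial) z-normalization,
# TR-level sample assembly with a hemodynamic shift, block-grouped
# cross-validated linear classification, and the group test against
# chance.

#' Extract an ROI's voxels x timepoints matrix from BOLD runs
#'
#' Runs are concatenated in acquisition order; run boundaries are kept in
#' the timepoint table.
#'
#' @param vols list of `volume_series` (one per run, in order).
#' @param roi a `shared_roi`.
#' @return list of class `roi_matrix`: `values` (voxels x timepoints),
#'   `voxel_idx`, `timepoints` (data.frame run_id, volume — 0-based
#'   within run).
#' @export
extract_roi_timeseries <- function(vols, roi) {
  if (!length(roi$voxel_idx)) stopf("extract_roi_timeseries: empty ROI")
  blocks <- list(); tp <- list()
  for (k in seq_along(vols)) {
    vs <- vols[[k]]
    dims <- dim(vs$data)
    V <- prod(dims[1:3])
    if (max(roi$voxel_idx) > V) stopf("extract_roi_timeseries: ROI outside grid")
    mat <- matrix(vs$data, V, dims[4])[roi$voxel_idx, , drop = FALSE]
    blocks[[k]] <- mat
    tp[[k]] <- data.frame(run_id = vs$run_id, volume = seq_len(dims[4]) - 1L)
  }
  structure(list(values = do.call(cbind, blocks), voxel_idx = roi$voxel_idx,
                 timepoints = do.call(rbind, tp), roi_name = roi$name),
            class = "roi_matrix")
}

#' Run-wise high-pass filter an ROI matrix
#'
#' Projects out the discrete-cosine drift components (periods longer than
#' `cutoff_s`) plus the run mean from every voxel's time series,
#' independently per run. Low-frequency scanner drift is a voxel-specific
#' slow pattern shared between temporally close blocks; left in place it
#' leaks class information into block-grouped cross-validation, so the
#' MVPA path filters it by default with the same cutoff as the GLM.
#'
#' @param m a `roi_matrix`.
#' @param tr repetition time (s).
#' @param cutoff_s high-pass cutoff period (s), default 128.
#' @return the `roi_matrix` with filtered values.
#' @export
highpass_roi_matrix <- function(m, tr, cutoff_s = 128) {
  for (run in unique(m$timepoints$run_id)) {
    sel <- m$timepoints$run_id == run
    D <- cbind(1, dct_basis(sum(sel), tr, cutoff_s))
    V <- m$values[, sel, drop = FALSE]
    m$values[, sel] <- V - (V %*% D) %*% solve(crossprod(D)) %*% t(D)
  }
  m
}

#' Two-step (temporal then spatial) z-normalization
#'
#' Stage 1 z-scores each voxel's time series by its own temporal mean and
#' sd; stage 2 z-scores each timepoint of the stage-1 result across
#' voxels. After stage 2 every timepoint has spatial mean 0 and sd 1, so
#' classification sees only the mean-stripped pattern.
#'
#' @param m a `roi_matrix` or bare voxels x timepoints matrix.
#' @return list of class `normalized_matrix`: `values`, `stage1_params`
#'   (per-voxel mu, sigma), `stage2_params` (per-timepoint mu, sigma),
#'   `kept_voxels` (indices into the input rows; constant voxels are
#'   dropped with a log entry).
#' @export
normalize_two_step <- function(m) {
  vals <- if (inherits(m, "roi_matrix")) m$values else as.matrix(m)
  mu_j <- rowMeans(vals)
  sd_j <- apply(vals, 1, stats::sd)
  keep <- sd_j > 0
  if (!all(keep)) {
    log_note("normalize_two_step: %d constant voxels removed", sum(!keep))
    vals <- vals[keep, , drop = FALSE]
    mu_j <- mu_j[keep]; sd_j <- sd_j[keep]
  }
  if (nrow(vals) < 2) stopf("normalize_two_step: fewer than 2 usable voxels")
  s1 <- (vals - mu_j) / sd_j
  mu_i <- colMeans(s1)
  sd_i <- apply(s1, 2, stats::sd)
  if (any(sd_i == 0)) stopf("normalize_two_step: zero spatial sd at a timepoint")
  s2 <- sweep(sweep(s1, 2, mu_i), 2, sd_i, "/")
  structure(list(values = s2,
                 stage1_params = data.frame(mu = mu_j, sigma = sd_j),
                 stage2_params = data.frame(mu = mu_i, sigma = sd_i),
                 kept_voxels = which(keep),
                 timepoints = if (inherits(m, "roi_matrix")) m$timepoints else NULL),
            class = "normalized_matrix")
}

#' Assemble TR-level classification samples from a normalized ROI matrix
#'
#' A volume becomes a sample of condition `c` when its acquisition
#' midpoint minus the hemodynamic shift falls inside a `c`-block's
#' stimulus epoch. Rest, cue and unlisted conditions are excluded.
#' Samples carry their block id so folds can be grouped by block.
#'
#' @param norm a `normalized_matrix` (with timepoints) — or a
#'   `roi_matrix`, normalized on the fly.
#' @param events session events data.frame.
#' @param tr repetition time (s).
#' @param hemodynamic_shift_s lag subtracted from acquisition midpoints
#'   before matching to block epochs (default 4 s).
#' @param conditions the two task conditions to keep.
#' @return list of class `sample_set`: `features` (samples x voxels),
#'   `labels`, `groups` (block ids), `runs`.
#' @export
assemble_samples <- function(norm, events, tr, hemodynamic_shift_s = 4,
                             conditions = c("NA", "NV")) {
  if (hemodynamic_shift_s < 0) stopf("assemble_samples: shift must be >= 0")
  if (inherits(norm, "roi_matrix")) norm <- normalize_two_step(norm)
  tp <- norm$timepoints
  if (is.null(tp)) stopf("assemble_samples: normalized matrix lacks timepoint table")
  labels <- rep(NA_character_, nrow(tp))
  groups <- rep(NA_integer_, nrow(tp))
  for (run in unique(tp$run_id)) {
    ev <- events[events$run_id == run & events$condition %in% conditions, ,
                 drop = FALSE]
    sel <- which(tp$run_id == run)
    mid <- (tp$volume[sel] + 0.5) * tr - hemodynamic_shift_s
    for (r in seq_len(nrow(ev))) {
      inb <- mid >= ev$onset[r] - 1e-9 & mid < ev$onset[r] + ev$duration[r] - 1e-9
      labels[sel[inb]] <- ev$condition[r]
      groups[sel[inb]] <- ev$block_id[r]
    }
  }
  keep <- !is.na(labels)
  for (cond in conditions) {
    if (!any(labels[keep] == cond)) {
      stopf("assemble_samples: zero samples for condition '%s'", cond)
    }
  }
  counts <- table(labels[keep])
  if (length(unique(counts)) > 1) {
    log_note("assemble_samples: unbalanced classes (%s)",
             paste(sprintf("%s=%d", names(counts), counts), collapse = ", "))
  }
  structure(list(features = t(norm$values[, keep, drop = FALSE]),
                 labels = labels[keep], groups = groups[keep],
                 runs = tp$run_id[keep], volumes = tp$volume[keep]),
            class = "sample_set")
}

#' Block-grouped k-fold cross-validated linear classification
#'
#' Folds are built at block level: the chronologically k-th block of each
#' condition goes to fold `(k - 1) %% n_folds + 1`, so all samples of a
#' block share a fold and no block straddles train and test (under the
#' default design: 8 blocks per condition -> 8 folds, one block pair per
#' fold). A linear max-margin classifier with fixed cost is trained on
#' the remaining folds and scored on the held-out fold.
#'
#' @param samples a `sample_set`.
#' @param n_folds number of folds (default 8).
#' @param seed seed controlling fold evaluation order only (results are
#'   order-invariant; kept for bit-stable logs).
#' @param cost SVM regularization constant (default 1).
#' @return list of class `mvpa_subject_result`: `fold_accuracy`,
#'   `accuracy` (mean over folds), `fold_of_block` (named map), `n_samples`.
#' @export
crossval_classify <- function(samples, n_folds = 8L, seed = 1L, cost = 1) {
  conds <- sort(unique(samples$labels))
  fold_of_block <- integer(0)
  for (cond in conds) {
    blocks <- sort(unique(samples$groups[samples$labels == cond]))
    if (length(blocks) < n_folds) {
      stopf("crossval_classify: condition '%s' has %d blocks < %d folds",
            cond, length(blocks), n_folds)
    }
    fold_of_block[as.character(blocks)] <- (seq_along(blocks) - 1L) %% n_folds + 1L
  }
  fold <- fold_of_block[as.character(samples$groups)]
  fold_order <- with_seed(child_seed(seed, "folds"), sample(n_folds))
  acc <- numeric(n_folds)
  for (i in seq_len(n_folds)) {
    f <- fold_order[i]
    test <- fold == f
    train_labels <- samples$labels[!test]
    if (length(unique(samples$labels[test])) < 2) {
      stopf("crossval_classify: fold %d holds a single class", f)
    }
    model <- linear_svm(samples$features[!test, , drop = FALSE],
                        train_labels, cost = cost)
    pred <- predict(model, samples$features[test, , drop = FALSE])
    acc[f] <- mean(pred == samples$labels[test])
  }
  structure(list(fold_accuracy = acc, accuracy = mean(acc),
                 fold_of_block = fold_of_block,
                 n_samples = length(samples$labels)),
            class = "mvpa_subject_result")
}

#' Group test of classification accuracy against chance
#'
#' One-sample t of (accuracy - chance), one-sided (greater) by default:
#' decoding is only meaningful above chance.
#'
#' @param per_subject_accuracy numeric vector of subject accuracies.
#' @param chance chance level (0.5 for two balanced classes).
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return list: `t`, `dof`, `p`, `mean`, `se`, `chance`.
#' @export
group_accuracy_test <- function(per_subject_accuracy, chance = 0.5,
                                alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  x <- per_subject_accuracy - chance
  n <- length(x)
  if (n < 2) stopf("group_accuracy_test: need n >= 2")
  s <- stats::sd(x)
  if (s == 0) {
    if (all(x == 0)) {
      return(list(t = 0, dof = n - 1,
                  p = if (alternative == "greater") 0.5 else 1,
                  mean = chance, se = 0, chance = chance,
                  alternative = alternative))
    }
    stopf("group_accuracy_test: zero variance in accuracies")
  }
  tv <- mean(x) / (s / sqrt(n))
  dof <- n - 1
  p <- if (alternative == "greater") stats::pt(tv, dof, lower.tail = FALSE)
       else 2 * stats::pt(-abs(tv), dof)
  list(t = tv, dof = dof, p = p, mean = mean(per_subject_accuracy),
       se = s / sqrt(n), chance = chance, alternative = alternative)
}

#' Per-ROI MVPA over a cohort
#'
#' Runs extraction, two-step normalization, sample assembly and
#' block-grouped cross-validation for every subject and ROI, then the
#' group test against chance with Bonferroni adjustment over ROIs.
#'
#' @param cohort an in-memory cohort from [simulate_cohort()] (or any list
#'   with `subjects[[s]]$runs`, `events`, `design`).
#' @param rois list of `shared_roi`s.
#' @param n_folds,hemodynamic_shift_s,conditions,cost,seed see the
#'   stage functions.
#' @param detrend_cutoff_s run-wise high-pass cutoff applied before
#'   normalization ([highpass_roi_matrix()]); NULL disables.
#' @return list: `table` (data.frame roi, n, mean_acc, se, t, dof, p,
#'   p_bonferroni), `per_subject` (ROI -> accuracy vector).
#' @export
mvpa_table <- function(cohort, rois, n_folds = 8L, hemodynamic_shift_s = 4,
                       conditions = c("NA", "NV"), cost = 1, seed = 1L,
                       detrend_cutoff_s = 128) {
  per_subject <- list()
  rows <- list()
  for (roi in rois) {
    accs <- vapply(seq_along(cohort$subjects), function(s) {
      rm_ <- extract_roi_timeseries(cohort$subjects[[s]]$runs, roi)
      if (!is.null(detrend_cutoff_s)) {
        rm_ <- highpass_roi_matrix(rm_, cohort$design$tr_seconds,
                                   detrend_cutoff_s)
      }
      nm <- normalize_two_step(rm_)
      ss <- assemble_samples(nm, cohort$events, cohort$design$tr_seconds,
                             hemodynamic_shift_s, conditions)
      crossval_classify(ss, n_folds, seed = child_seed(seed, roi$name, s),
                        cost = cost)$accuracy
    }, numeric(1))
    per_subject[[roi$name]] <- accs
    gt <- group_accuracy_test(accs)
    rows[[roi$name]] <- data.frame(
      roi = roi$name, n = length(accs), mean_acc = gt$mean, se = gt$se,
      t = gt$t, dof = gt$dof, p = gt$p, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab$p_bonferroni <- bonferroni(tab$p, nrow(tab))
  list(table = tab, per_subject = per_subject)
}
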