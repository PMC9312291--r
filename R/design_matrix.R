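# Design matrix construction: boxcar-convolved task regressors at
# microtime resolution, discrete-cosine drift regressors implementing the
# high-pass filter, optional motion columns, and a constant.

#' Orthonormal discrete-cosine drift basis
#'
#' Columns are the DCT-II basis functions with frequency `k/(2*T*tr)` for
#' `k = 1..K`, `K = floor(2*T*tr/cutoff)`, i.e. all non-constant cosines
#' with period longer than `cutoff` seconds.
#'
#' @param n_volumes number of time points T.
#' @param tr repetition time (s).
#' @param cutoff high-pass cutoff period (s), e.g. 128.
#' @return T x K matrix (possibly K = 0) with orthonormal columns.
#' @export
dct_basis <- function(n_volumes, tr, cutoff = 128) {
  K <- floor(2 * n_volumes * tr / cutoff)
  t_idx <- seq_len(n_volumes) - 1L
  B <- matrix(0, n_volumes, max(K, 0))
  for (k in seq_len(K)) {
    B[, k] <- sqrt(2 / n_volumes) * cos(pi * (2 * t_idx + 1) * k / (2 * n_volumes))
  }
  B
}

# Shared simulation/analysis path: boxcar events convolved with the HRF at
# microtime resolution, sampled at volume midpoints. Returns T x length(conditions).
condition_regressors <- function(events, n_volumes, tr, hrf, conditions) {
  dt <- tr / hrf$microtime_bins
  n_micro <- n_volumes * hrf$microtime_bins
  kern <- hrf_kernel(hrf, dt)
  out <- matrix(0, n_volumes, length(conditions))
  colnames(out) <- conditions
  micro_t <- (seq_len(n_micro) - 1) * dt
  sample_idx <- floor(((seq_len(n_volumes) - 1) + 0.5) * hrf$microtime_bins) + 1L
  for (j in seq_along(conditions)) {
    ev <- events[events$condition == conditions[j], , drop = FALSE]
    if (!nrow(ev)) next
    u <- numeric(n_micro)
    for (r in seq_len(nrow(ev))) {
      on <- ev$onset[r]
      off <- on + ev$duration[r]
      u[micro_t >= on - 1e-9 & micro_t < off - 1e-9] <- 1
    }
    cv <- stats::convolve(u, rev(kern), type = "open")[seq_len(n_micro)]
    out[, j] <- cv[sample_idx]
  }
  out
}

#' Build a GLM design matrix for one run
#'
#' Task conditions get boxcar-convolved HRF regressors; cue events get
#' their own regressor (the rest condition is the implicit baseline);
#' discrete-cosine drift columns implement the high-pass filter; motion
#' parameters are appended verbatim; the constant column comes last.
#'
#' @param events events data.frame for one run ([build_design()] layout).
#' @param n_volumes number of volumes T in the run.
#' @param tr repetition time (s).
#' @param hrf an `hrf` object.
#' @param highpass_cutoff_s high-pass cutoff period in seconds (drift
#'   columns for all slower frequencies); `Inf` for none.
#' @param motion optional T x 6 matrix of motion parameters.
#' @param conditions task condition names to model; default: the design's
#'   task conditions present in `events` (everything except cue/rest).
#' @param model_cue logical, model cue events as their own regressor.
#' @return list of class `design_matrix`: `values` (T x P), `column_names`,
#'   `partition` (named character: task/cue/drift/motion/constant),
#'   `tr_seconds`.
#' @export
build_design_matrix <- function(events, n_volumes, tr, hrf = default_hrf(),
                                highpass_cutoff_s = 128, motion = NULL,
                                conditions = NULL, model_cue = TRUE) {
  if (nrow(events) && max(events$onset + events$duration) > n_volumes * tr + 1e-9) {
    stopf("build_design_matrix: events extend past %d volumes x TR %g s",
          n_volumes, tr)
  }
  if (is.null(conditions)) {
    conditions <- setdiff(unique(events$condition), c("cue", "rest"))
  }
  for (cond in conditions) {
    if (!any(events$condition == cond)) {
      stopf("build_design_matrix: condition '%s' has zero events", cond)
    }
  }
  cols <- list(); part <- character(0)
  if (length(conditions)) {
    Xt <- condition_regressors(events, n_volumes, tr, hrf, conditions)
    for (j in seq_along(conditions)) {
      cols[[conditions[j]]] <- Xt[, j]
      part[conditions[j]] <- "task"
    }
  }
  if (model_cue && any(events$condition == "cue")) {
    cols[["cue"]] <- condition_regressors(events, n_volumes, tr, hrf, "cue")[, 1]
    part["cue"] <- "cue"
  }
  if (is.finite(highpass_cutoff_s)) {
    D <- dct_basis(n_volumes, tr, highpass_cutoff_s)
    for (k in seq_len(ncol(D))) {
      nm <- sprintf("drift%02d", k)
      cols[[nm]] <- D[, k]
      part[nm] <- "drift"
    }
  }
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (nrow(motion) != n_volumes) {
      stopf("build_design_matrix: motion has %d rows, expected %d",
            nrow(motion), n_volumes)
    }
    for (k in seq_len(ncol(motion))) {
      nm <- sprintf("motion%d", k)
      cols[[nm]] <- motion[, k]
      part[nm] <- "motion"
    }
  }
  cols[["constant"]] <- rep(1, n_volumes)
  part["constant"] <- "constant"
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  structure(list(values = X, column_names = colnames(X), partition = part,
                 tr_seconds = tr), class = "design_matrix")
}

#' Export a design matrix as TSV plus a JSON partition sidecar
#' @param X a `design_matrix`.
#' @param path TSV output path; the sidecar is written next to it.
#' @export
write_design_matrix <- function(X, path) {
  utils::write.table(as.data.frame(X$values), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  side <- sub("\\.tsv$", ".json", path)
  jsonlite::write_json(list(tr_seconds = X$tr_seconds,
                            partition = as.list(X$partition)),
                       side, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
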