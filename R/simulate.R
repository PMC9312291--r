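# Synthetic BOLD cohort generator.
#
# Signal model per voxel:
#   BOLD(t) = baseline
#           + sum_c (amplitude[region, c] + pattern[region, c][voxel]) * x_c(t)
#           + drift + motion leakage + AR(1) noise,
# where x_c is the same boxcar-convolved-HRF regressor the GLM uses
# (shared code path), amplitudes are percent signal change at block
# plateau (baseline 100), patterns are fixed zero-mean voxel vectors, and
# the noise is stationary AR(1) with marginal sd `white_sd`.

#' Construct a volume series container
#' @param data 4D array (x, y, z, t).
#' @param tr_seconds repetition time (s).
#' @param affine 4x4 voxel-to-world matrix.
#' @param run_id run index.
#' @return list of class `volume_series`.
#' @export
volume_series <- function(data, tr_seconds, affine = diag(4), run_id = 1L) {
  stopifnot(length(dim(data)) == 4)
  structure(list(data = data, tr_seconds = tr_seconds, affine = affine,
                 run_id = run_id), class = "volume_series")
}

#' Region-by-condition effect specification
#'
#' @param regions region names (must match atlas labels).
#' @param conditions task condition names.
#' @param amplitude regions x conditions matrix of mean BOLD amplitudes
#'   (percent signal change at block plateau), or a single number recycled.
#' @param pattern_sd regions x conditions matrix of standard deviations of
#'   the fixed zero-mean voxelwise pattern vectors, or a single number.
#' @param pattern_seed_base integer; per-region pattern seeds are derived
#'   from it so patterns are population-level (identical across subjects).
#' @return list of class `effect_spec`.
#' @export
effect_spec <- function(regions, conditions = c("NA", "NV", "NR"),
                        amplitude = 0, pattern_sd = 0,
                        pattern_seed_base = 7001L) {
  as_mat <- function(x) {
    m <- matrix(x, length(regions), length(conditions),
                dimnames = list(regions, conditions))
    m
  }
  amplitude <- if (is.matrix(amplitude)) amplitude else as_mat(amplitude)
  pattern_sd <- if (is.matrix(pattern_sd)) pattern_sd else as_mat(pattern_sd)
  if (!all(is.finite(amplitude))) stopf("effect_spec: amplitudes must be finite")
  structure(list(regions = regions, conditions = conditions,
                 amplitude = amplitude, pattern_sd = pattern_sd,
                 pattern_seed_base = as.integer(pattern_seed_base)),
            class = "effect_spec")
}

#' Noise specification
#'
#' Defaults model realistic resting noise on a percent-signal scale:
#' unit-variance AR(1) noise with lag-1 autocorrelation 0.3, slow drift
#' with temporal sd 1, and mild motion-correlated leakage.
#'
#' @param white_sd marginal standard deviation of the AR(1) noise.
#' @param ar1_rho lag-1 autocorrelation, `|rho| < 1`.
#' @param drift_amplitude temporal sd of the low-frequency drift.
#' @param n_drift_components number of sub-1/128 Hz cosine components.
#' @param motion_coupling sd of per-voxel motion-regressor couplings.
#' @return list of class `noise_spec`.
#' @export
noise_spec <- function(white_sd = 1, ar1_rho = 0.3, drift_amplitude = 1,
                       n_drift_components = 3L, motion_coupling = 0.1) {
  if (abs(ar1_rho) >= 1) stopf("noise_spec: |ar1_rho| must be < 1")
  if (any(c(white_sd, drift_amplitude, motion_coupling) < 0)) {
    stopf("noise_spec: scales must be >= 0")
  }
  structure(list(white_sd = white_sd, ar1_rho = ar1_rho,
                 drift_amplitude = drift_amplitude,
                 n_drift_components = as.integer(n_drift_components),
                 motion_coupling = motion_coupling), class = "noise_spec")
}

# Fixed zero-mean pattern vector for (region, condition); identical across
# subjects because it is seeded only by the effect spec.
region_pattern <- function(spec, region, condition, n_voxels) {
  sd <- spec$pattern_sd[region, condition]
  if (sd == 0 || n_voxels < 2) return(numeric(n_voxels))
  seed <- child_seed(spec$pattern_seed_base, "pattern", region, condition)
  p <- with_seed(seed, stats::rnorm(n_voxels, 0, sd))
  p - mean(p)
}

ar1_noise <- function(n_voxels, n_t, white_sd, rho) {
  if (white_sd == 0 || n_t == 0) return(matrix(0, n_voxels, n_t))
  w <- matrix(stats::rnorm(n_voxels * n_t), n_voxels, n_t)
  e <- matrix(0, n_voxels, n_t)
  e[, 1] <- w[, 1] * white_sd
  innov_sd <- white_sd * sqrt(1 - rho^2)
  for (t in seq_len(n_t)[-1]) {
    e[, t] <- rho * e[, t - 1] + innov_sd * w[, t]
  }
  e
}

#' Simulate one subject's BOLD runs with known ground truth
#'
#' @param design an `acquisition_design`.
#' @param events session events data.frame from [build_design()].
#' @param atlas a `label_volume`.
#' @param spec an `effect_spec` (regions must exist in the atlas).
#' @param noise a `noise_spec`.
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @param baseline baseline intensity (100 so amplitudes are percent
#'   signal change).
#' @param hrf `hrf` object used for the shared convolution path.
#' @return list with `runs` (list of `volume_series`) and `ground_truth`
#'   (true voxel beta matrix, per-region patterns, motion parameters,
#'   noise parameters, seed).
#' @export
simulate_subject <- function(design, events, atlas, spec,
                             noise = noise_spec(), seed = 1L,
                             baseline = 100, hrf = default_hrf()) {
  grid_dim <- dim(atlas$grid)
  V <- prod(grid_dim)
  n_vol <- volumes_per_run(design)
  conditions <- intersect(spec$conditions, unique(events$condition))
  # true voxelwise betas: amplitude + zero-mean pattern inside each region
  B <- matrix(0, V, length(conditions),
              dimnames = list(NULL, conditions))
  patterns <- list()
  for (region in spec$regions) {
    lab <- match(region, atlas$label_names)
    if (is.na(lab)) stopf("simulate_subject: region '%s' not in atlas", region)
    vox <- which(atlas$grid == as.integer(names(atlas$label_names)[lab]))
    patterns[[region]] <- list(voxels = vox)
    for (cond in conditions) {
      pat <- region_pattern(spec, region, cond, length(vox))
      B[vox, cond] <- spec$amplitude[region, cond] + pat
      patterns[[region]][[cond]] <- pat
    }
  }
  runs <- vector("list", design$n_runs)
  motion_list <- vector("list", design$n_runs)
  for (run in seq_len(design$n_runs)) {
    ev <- events[events$run_id == run, , drop = FALSE]
    X_task <- condition_regressors(ev, n_vol, design$tr_seconds, hrf, conditions)
    Y <- matrix(baseline, V, n_vol)
    Y <- Y + B %*% t(X_task)
    rs <- child_seed(seed, "run", run)
    with_seed(rs, {
      if (noise$drift_amplitude > 0 && n_vol > 1) {
        D <- dct_basis(n_vol, design$tr_seconds, 128)
        K <- min(noise$n_drift_components, ncol(D))
        if (K > 0) {
          coef_sd <- noise$drift_amplitude * sqrt(n_vol / K)
          A <- matrix(stats::rnorm(V * K, 0, coef_sd), V, K)
          Y <- Y + A %*% t(D[, seq_len(K), drop = FALSE])
        }
      }
      motion <- matrix(0, n_vol, 6)
      if (n_vol > 0) {
        motion <- apply(matrix(stats::rnorm(n_vol * 6, 0, 0.05), n_vol, 6),
                        2, cumsum)
        motion <- matrix(motion, n_vol, 6)
        if (noise$motion_coupling > 0) {
          G <- matrix(stats::rnorm(V * 6, 0, noise$motion_coupling), V, 6)
          Y <- Y + G %*% t(motion)
        }
      }
      Y <- Y + ar1_noise(V, n_vol, noise$white_sd, noise$ar1_rho)
    })
    motion_list[[run]] <- motion
    runs[[run]] <- volume_series(array(Y, dim = c(grid_dim, n_vol)),
                                 tr_seconds = design$tr_seconds,
                                 affine = atlas$affine, run_id = run)
  }
  list(runs = runs,
       ground_truth = list(beta = B, patterns = patterns,
                           motion = motion_list, noise = unclass(noise),
                           baseline = baseline, seed = seed))
}

#' Simulate a cohort, in memory or on disk
#'
#' Subject amplitudes are drawn around the population values of `spec`
#' with between-subject sd `between_subject_sd`; patterns are
#' population-level. With `out_dir` set, writes per-subject 4D NIfTI
#' volumes, per-run events TSVs, the atlas NIfTI, a ground-truth JSON per
#' subject and a manifest JSON with md5 checksums.
#'
#' @param n_subjects number of subjects (study default 21).
#' @param design,atlas,spec,noise see [simulate_subject()].
#' @param events optional events data.frame; built from `design` if NULL.
#' @param between_subject_sd sd of subject amplitude deviations.
#' @param seed master seed.
#' @param out_dir output directory, or NULL for in-memory cohort.
#' @param keep_volumes with `out_dir` set, also keep volumes in the return
#'   value (default FALSE to bound memory).
#' @return list with `subjects` (each: `runs`, `ground_truth`, and with
#'   `out_dir` the file paths), `events`, `design`, `atlas`, and with
#'   `out_dir` a `manifest` entry.
#' @export
simulate_cohort <- function(n_subjects = 21L, design = default_design(),
                            atlas = make_atlas(),
                            spec = effect_spec(atlas$label_names),
                            noise = noise_spec(), events = NULL,
                            between_subject_sd = 0.3, seed = 1L,
                            out_dir = NULL, keep_volumes = is.null(out_dir)) {
  if (is.null(events)) {
    built <- build_design()
    design <- built$design
    events <- built$events
  }
  to_disk <- !is.null(out_dir)
  if (to_disk) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!dir.exists(out_dir)) stopf("simulate_cohort: cannot create '%s'", out_dir)
    write_atlas(atlas, file.path(out_dir, "atlas.nii"))
    write_events_tsv(events, out_dir)
  }
  subjects <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    sspec <- spec
    if (between_subject_sd > 0) {
      dev <- with_seed(child_seed(seed, "subject_amp", s),
                       stats::rnorm(length(spec$amplitude), 0, between_subject_sd))
      sspec$amplitude <- spec$amplitude + matrix(dev, nrow(spec$amplitude))
      dimnames(sspec$amplitude) <- dimnames(spec$amplitude)
    }
    sub <- simulate_subject(design, events, atlas, sspec, noise,
                            seed = child_seed(seed, "subject", s))
    sub$subject_id <- sprintf("sub-%02d", s)
    if (to_disk) {
      sub$paths <- character(0)
      for (run in seq_along(sub$runs)) {
        p <- file.path(out_dir, sprintf("sub-%02d_run-%02d_bold.nii", s, run))
        write_nifti(sub$runs[[run]]$data, p, affine = atlas$affine,
                    pixdim = c(atlas$voxel_size_mm, design$tr_seconds),
                    description = sprintf("sub %d run %d", s, run))
        sub$paths <- c(sub$paths, p)
      }
      gt <- sub$ground_truth
      gt_path <- file.path(out_dir, sprintf("sub-%02d_truth.json", s))
      jsonlite::write_json(list(
        amplitude = sspec$amplitude, seed = gt$seed, noise = gt$noise,
        baseline = gt$baseline,
        motion = list(dims = c(dim(gt$motion[[1]]), length(gt$motion)),
                      values = as.numeric(unlist(gt$motion))),
        patterns = lapply(gt$patterns, function(p) p[names(p) != "voxels"])),
        gt_path, auto_unbox = TRUE, digits = NA)
      if (!keep_volumes) sub$runs <- NULL
    }
    subjects[[s]] <- sub
  }
  out <- list(subjects = subjects, events = events, design = design,
              atlas = atlas, seed = seed)
  if (to_disk) {
    files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                          "manifest.json"))
    manifest <- list(
      n_subjects = n_subjects, seed = seed,
      design = unclass(design),
      atlas_labels = as.list(atlas$label_names),
      voxel_size_mm = atlas$voxel_size_mm,
      files = files,
      md5 = as.list(tools::md5sum(file.path(out_dir, files))))
    names(manifest$md5) <- files
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    out$manifest <- manifest
    out$dir <- out_dir
  }
  out
}
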