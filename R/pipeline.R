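# End-to-end orchestration: simulate -> subject GLM + contrasts -> group
# inference -> conjunction -> shared ROIs -> mean-level table -> MVPA
# table. Stages are plain functions over in-memory objects so that the
# composed pipeline and individually chained stages are the same code.

#' Build a resolved pipeline configuration
#'
#' @param n_subjects cohort size (study default 21).
#' @param seed master seed; all stages derive child streams from it.
#' @param design_override named list overriding [default_design()] fields.
#' @param grid_shape,voxel_size_mm,region_specs atlas geometry.
#' @param effect `"demo"`, `"null"`, `"dissociation"` or an `effect_spec`.
#' @param noise a `noise_spec` or named list of its fields.
#' @param between_subject_sd between-subject amplitude sd.
#' @param smooth_fwhm_mm smoothing kernel for the GLM route (mm triple).
#' @param highpass_cutoff_s high-pass cutoff (s).
#' @param model_cue model cue events as a separate regressor.
#' @param voxel_p,cluster_alpha,n_permutations,connectivity thresholding.
#' @param roi_source `"conjunction"` (default) or `"atlas"`.
#' @param atlas_roi_names parcels used when `roi_source = "atlas"`.
#' @param min_roi_voxels minimum shared-ROI size.
#' @param n_folds,hemodynamic_shift_s,svm_cost MVPA settings.
#' @param mvpa_smoothed run MVPA on smoothed data (default FALSE).
#' @param meanlevel_alternative sidedness of the mean-level paired test.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_subjects = 21L, seed = 1L,
                            design_override = list(),
                            grid_shape = c(20L, 24L, 20L),
                            voxel_size_mm = c(3, 3, 3.4375),
                            region_specs = default_region_specs(),
                            effect = "demo", noise = noise_spec(),
                            between_subject_sd = 0.3,
                            smooth_fwhm_mm = c(8, 8, 8),
                            highpass_cutoff_s = 128, model_cue = TRUE,
                            voxel_p = 0.001, cluster_alpha = 0.05,
                            n_permutations = 500L, connectivity = 26,
                            roi_source = "conjunction",
                            atlas_roi_names = c("LSMA", "RSMA", "LIFG"),
                            min_roi_voxels = 5L, n_folds = 8L,
                            hemodynamic_shift_s = 4, svm_cost = 1,
                            mvpa_detrend_cutoff_s = 128,
                            mvpa_smoothed = FALSE,
                            meanlevel_alternative = "two.sided") {
  if (inherits(noise, "noise_spec")) noise <- unclass(noise)
  cfg <- as.list(environment())
  structure(cfg, class = "pipeline_config")
}

#' Preset effect specifications
#'
#' `"null"`: no effects anywhere. `"demo"`: NA/NV amplitudes above NR in
#' LSMA, RSMA and LIFG with an NA > NV mean difference in the SMA parcels
#' and pattern differences in all three. `"dissociation"`: an SMA-like
#' parcel with amplitude + pattern NA/NV differences and an IFG-like
#' parcel with a pattern-only (zero amplitude) difference — the
#' mean-level/MVPA dissociation.
#'
#' @param kind preset name.
#' @param regions region names (atlas labels).
#' @param pattern_sd sd of the condition patterns. The default 0.2 comes
#'   from a one-off calibration sweep (see the methods vignette): the
#'   smallest tested value at which the pattern-only region's MVPA group
#'   test exceeds 80 percent power at n = 21 (power was 20 percent at
#'   0.1, saturated at 0.2).
#' @return an `effect_spec`.
#' @export
preset_effects <- function(kind = c("demo", "null", "dissociation"),
                           regions = c("LSMA", "RSMA", "LIFG", "LIPL",
                                       "CONTROL"),
                           pattern_sd = 0.2) {
  kind <- match.arg(kind)
  conds <- c("NA", "NV", "NR")
  amp <- matrix(0, length(regions), 3, dimnames = list(regions, conds))
  psd <- matrix(0, length(regions), 3, dimnames = list(regions, conds))
  if (kind == "demo") {
    for (r in intersect(c("LSMA", "RSMA"), regions)) {
      amp[r, ] <- c(1.4, 0.9, 0.2)
      psd[r, c("NA", "NV")] <- pattern_sd
    }
    if ("LIFG" %in% regions) {
      amp["LIFG", ] <- c(1.0, 1.0, 0.2)
      psd["LIFG", c("NA", "NV")] <- pattern_sd
    }
    if ("LIPL" %in% regions) amp["LIPL", ] <- c(1.0, 0.3, 0.2)
  } else if (kind == "dissociation") {
    if (!all(c("LSMA", "LIFG") %in% regions)) {
      stopf("preset_effects: dissociation preset needs LSMA and LIFG parcels")
    }
    amp["LSMA", ] <- c(1.2, 0.6, 0)   # amplitude + pattern difference
    psd["LSMA", c("NA", "NV")] <- pattern_sd
    amp["LIFG", ] <- c(0.9, 0.9, 0)   # pattern-only difference
    psd["LIFG", c("NA", "NV")] <- pattern_sd
  }
  effect_spec(regions, conds, amplitude = amp, pattern_sd = psd)
}

resolve_effect <- function(cfg, atlas) {
  if (inherits(cfg$effect, "effect_spec")) return(cfg$effect)
  preset_effects(cfg$effect, regions = unname(atlas$label_names))
}

#' Subject-level stage: smoothing, GLM per run, contrast effect maps
#'
#' Fits each run separately (one pooled AR(1) rho per run, true motion
#' parameters as nuisance regressors) and averages contrast effects
#' across runs (fixed effects).
#'
#' @param cohort in-memory cohort from [simulate_cohort()].
#' @param cfg a `pipeline_config`.
#' @return list: `effects[[contrast]][[subject]]` (3D arrays),
#'   `contrast_names`, `rho` (per subject x run).
#' @export
stage_fit <- function(cohort, cfg) {
  contrasts <- list("NA>NR" = c("NA" = 1, "NR" = -1),
                    "NV>NR" = c("NV" = 1, "NR" = -1),
                    "NA>NV" = c("NA" = 1, "NV" = -1),
                    "NV>NA" = c("NV" = 1, "NA" = -1))
  n_vol <- volumes_per_run(cohort$design)
  effects <- lapply(contrasts, function(x) list())
  rho <- list()
  for (s in seq_along(cohort$subjects)) {
    sub <- cohort$subjects[[s]]
    acc <- lapply(contrasts, function(x) 0)
    rhos <- numeric(length(sub$runs))
    for (k in seq_along(sub$runs)) {
      run <- sub$runs[[k]]
      if (any(cfg$smooth_fwhm_mm > 0)) {
        run <- smooth_volume(run, cfg$smooth_fwhm_mm,
                             cohort$atlas$voxel_size_mm)
      }
      ev <- cohort$events[cohort$events$run_id == run$run_id, , drop = FALSE]
      X <- build_design_matrix(ev, n_vol, cohort$design$tr_seconds,
                               highpass_cutoff_s = cfg$highpass_cutoff_s,
                               motion = sub$ground_truth$motion[[k]],
                               conditions = cohort$design$task_names,
                               model_cue = cfg$model_cue)
      fit <- fit_glm(run, X)
      rhos[k] <- fit$rho
      for (nm in names(contrasts)) {
        cm <- compute_contrast(fit, contrasts[[nm]])
        acc[[nm]] <- acc[[nm]] + cm$effect / length(sub$runs)
      }
    }
    rho[[s]] <- rhos
    for (nm in names(contrasts)) effects[[nm]][[s]] <- acc[[nm]]
  }
  list(effects = effects, contrast_names = names(contrasts), rho = rho)
}

#' Group stage: one-sample t and cluster-FWE threshold per contrast
#' @param fits output of [stage_fit()].
#' @param cfg a `pipeline_config`.
#' @return list per contrast: `group` (`group_stat_map`), `thresholded`.
#' @export
stage_group <- function(fits, cfg) {
  out <- list()
  for (nm in fits$contrast_names) {
    g <- one_sample_group_t(fits$effects[[nm]], contrast_name = nm)
    th <- threshold_with_cluster_fwe(
      g, fits$effects[[nm]], voxel_p = cfg$voxel_p,
      cluster_alpha = cfg$cluster_alpha,
      n_permutations = cfg$n_permutations,
      seed = child_seed(cfg$seed, "fwe", nm),
      connectivity = cfg$connectivity)
    out[[nm]] <- list(group = g, thresholded = th)
  }
  out
}

#' ROI stage: conjunction of NA>NR and NV>NR, split by atlas parcel
#' @param groups output of [stage_group()] (ignored for atlas ROIs).
#' @param atlas a `label_volume`.
#' @param cfg a `pipeline_config`.
#' @return list of `shared_roi`s.
#' @export
stage_rois <- function(groups, atlas, cfg) {
  if (cfg$roi_source == "atlas") {
    rois <- lapply(cfg$atlas_roi_names, atlas_roi, atlas = atlas)
    names(rois) <- vapply(rois, `[[`, "", "name")
    return(rois)
  }
  mask <- conjunction(groups[["NA>NR"]]$thresholded,
                      groups[["NV>NR"]]$thresholded)
  segment_shared_rois(mask, atlas, cfg$min_roi_voxels)
}

#' Run the full analysis pipeline
#'
#' simulate (optional) -> subject GLM and the four contrasts -> group
#' inference per contrast -> conjunction(NA>NR, NV>NR) -> shared-ROI
#' segmentation -> mean-level table -> MVPA table. With `out_dir` set,
#' writes TSV/JSON/NIfTI artifacts, the resolved config and a log.
#'
#' @param cfg a `pipeline_config`.
#' @param cohort optional pre-simulated in-memory cohort (else simulated
#'   from `cfg`).
#' @param out_dir optional report directory.
#' @return list: `cohort`, `fits`, `groups`, `rois`, `mean_level`
#'   (data.frame or NULL if no ROIs), `mvpa` (list or NULL), `config`,
#'   `log`.
#' @export
run_pipeline <- function(cfg = pipeline_config(), cohort = NULL,
                         out_dir = NULL) {
  get_log(clear = TRUE)
  stage <- "simulate"
  res <- tryCatch({
    if (is.null(cohort)) {
      atlas <- make_atlas(cfg$grid_shape, cfg$voxel_size_mm, cfg$region_specs)
      built <- build_design(cfg$design_override)
      cohort <- simulate_cohort(
        n_subjects = cfg$n_subjects, design = built$design, atlas = atlas,
        spec = resolve_effect(cfg, atlas), noise = do.call(noise_spec, cfg$noise),
        events = built$events, between_subject_sd = cfg$between_subject_sd,
        seed = child_seed(cfg$seed, "cohort"))
    }
    stage <- "fit"
    fits <- stage_fit(cohort, cfg)
    stage <- "group"
    groups <- stage_group(fits, cfg)
    stage <- "rois"
    rois <- stage_rois(groups, cohort$atlas, cfg)
    if (!length(rois)) log_note("run_pipeline: empty conjunction, no shared ROIs")
    stage <- "meanlevel"
    mean_level <- if (length(rois)) {
      mean_level_table(fits$effects[["NA>NR"]], fits$effects[["NV>NR"]],
                       rois, cfg$meanlevel_alternative)
    } else NULL
    stage <- "mvpa"
    mvpa <- if (length(rois)) {
      mcohort <- cohort
      if (cfg$mvpa_smoothed) {
        for (s in seq_along(mcohort$subjects)) {
          mcohort$subjects[[s]]$runs <- lapply(
            mcohort$subjects[[s]]$runs, smooth_volume,
            fwhm_mm = cfg$smooth_fwhm_mm,
            voxel_size_mm = cohort$atlas$voxel_size_mm)
        }
      }
      mvpa_table(mcohort, rois, n_folds = cfg$n_folds,
                 hemodynamic_shift_s = cfg$hemodynamic_shift_s,
                 cost = cfg$svm_cost, seed = child_seed(cfg$seed, "mvpa"),
                 detrend_cutoff_s = cfg$mvpa_detrend_cutoff_s)
    } else NULL
    list(cohort = cohort, fits = fits, groups = groups, rois = rois,
         mean_level = mean_level, mvpa = mvpa, config = cfg,
         log = get_log())
  }, error = function(e) {
    stopf("pipeline failed at stage '%s': %s", stage, conditionMessage(e))
  })
  if (!is.null(out_dir)) write_report(res, out_dir)
  res
}

serialize_config <- function(cfg) {
  cfg$region_specs <- lapply(cfg$region_specs, function(s) {
    list(name = s$name, center = s$center, radius = s$radius)
  })
  if (inherits(cfg$effect, "effect_spec")) {
    # matrices flattened column-major; rebuilt against regions x conditions
    cfg$effect <- list(regions = cfg$effect$regions,
                       conditions = cfg$effect$conditions,
                       amplitude = as.numeric(cfg$effect$amplitude),
                       pattern_sd = as.numeric(cfg$effect$pattern_sd),
                       pattern_seed_base = cfg$effect$pattern_seed_base)
  }
  unclass(cfg)
}

#' Write a pipeline report directory
#'
#' Writes the resolved config (JSON), group t and threshold masks
#' (NIfTI), cluster report (TSV), ROI manifest (JSON), mean-level and
#' MVPA tables (TSV + JSON) and the run log. Every JSON carries the
#' config hash, seed and package version as provenance.
#'
#' @param res result of [run_pipeline()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_json <- jsonlite::toJSON(serialize_config(res$config),
                               auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(cfg_json, file.path(out_dir, "config.json"))
  prov <- list(config_md5 = unname(tools::md5sum(file.path(out_dir, "config.json"))),
               seed = res$config$seed,
               package_version = as.character(utils::packageVersion("blockmvpa")))
  atlas <- res$cohort$atlas
  cl_rows <- list()
  for (nm in names(res$groups)) {
    safe <- gsub(">", "_gt_", nm)
    g <- res$groups[[nm]]
    write_nifti(g$group$t, file.path(out_dir, sprintf("group_t_%s.nii", safe)),
                affine = atlas$affine, pixdim = atlas$voxel_size_mm)
    write_nifti(array(as.integer(g$thresholded$mask), dim(g$thresholded$mask)),
                file.path(out_dir, sprintf("mask_%s.nii", safe)),
                affine = atlas$affine, pixdim = atlas$voxel_size_mm,
                datatype = "uint8")
    th <- g$thresholded
    if (length(th$cluster_sizes)) {
      cl_rows[[nm]] <- data.frame(contrast = nm,
                                  cluster = seq_along(th$cluster_sizes),
                                  n_voxels = th$cluster_sizes,
                                  p_fwe = th$cluster_p)
    }
  }
  cl <- if (length(cl_rows)) do.call(rbind, cl_rows) else {
    data.frame(contrast = character(0), cluster = integer(0),
               n_voxels = integer(0), p_fwe = numeric(0))
  }
  utils::write.table(cl, file.path(out_dir, "clusters.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  roi_manifest <- lapply(res$rois, function(r) {
    world <- atlas$affine %*% rbind(t(r$voxels), 1)
    list(name = r$name, parent_label = r$parent_label,
         n_voxels = nrow(r$voxels),
         centroid_world = rowMeans(world)[1:3])
  })
  jsonlite::write_json(list(provenance = prov, rois = unname(roi_manifest)),
                       file.path(out_dir, "rois.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  if (!is.null(res$mean_level)) {
    utils::write.table(res$mean_level, file.path(out_dir, "mean_level.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(res$mvpa)) {
    utils::write.table(res$mvpa$table, file.path(out_dir, "mvpa.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(provenance = prov, table = res$mvpa$table,
                              per_subject = res$mvpa$per_subject),
                         file.path(out_dir, "mvpa.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  writeLines(c(sprintf("blockmvpa %s seed=%d", prov$package_version,
                       res$config$seed), res$log),
             file.path(out_dir, "log.txt"))
  invisible(out_dir)
}
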