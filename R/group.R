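# Group-level inference: one-sample t maps, sign-flip permutation
# cluster-level FWE thresholding, conjunction masks, and shared-ROI
# segmentation by atlas parcel.

subject_maps_matrix <- function(effect_maps) {
  # list of 3D arrays -> n x V matrix + grid dims
  dims <- dim(effect_maps[[1]])
  for (m in effect_maps) {
    if (!identical(dim(m), dims)) stopf("subject maps have mismatched grids")
  }
  M <- do.call(rbind, lapply(effect_maps, as.numeric))
  list(M = M, dims = dims)
}

group_t_from_matrix <- function(M) {
  n <- nrow(M)
  mu <- colMeans(M)
  v <- colSums(sweep(M, 2, mu)^2) / (n - 1)
  tv <- ifelse(v > 0, mu / sqrt(v / n), 0)
  nz <- sum(v == 0 & is.finite(mu))
  if (nz > 0) log_note("group t: %d zero-variance voxels set to t=0", nz)
  tv
}

#' Voxelwise one-sample group t-test over subject effect maps
#'
#' @param effect_maps list of per-subject 3D effect arrays (equal grids).
#' @param contrast_name label carried into the result.
#' @return list of class `group_stat_map`: `t` (3D), `dof` (n - 1),
#'   `n_subjects`, `contrast_name`.
#' @export
one_sample_group_t <- function(effect_maps, contrast_name = "") {
  if (length(effect_maps) < 2) stopf("one_sample_group_t: need >= 2 subjects")
  sm <- subject_maps_matrix(effect_maps)
  tv <- group_t_from_matrix(sm$M)
  structure(list(t = array(tv, sm$dims), dof = nrow(sm$M) - 1L,
                 n_subjects = nrow(sm$M), contrast_name = contrast_name),
            class = "group_stat_map")
}

neighbor_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  d <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6" = d == 1,
                 "18" = d >= 1 & rowSums(g != 0) <= 2,
                 "26" = d >= 1,
                 stopf("connectivity must be 6, 18 or 26"))
  g[keep, , drop = FALSE]
}

#' Label connected components of a 3D binary mask
#'
#' Union-find over the mask voxels under 6/18/26-connectivity.
#' @param mask 3D logical/0-1 array.
#' @param connectivity 6, 18 or 26 (default 26).
#' @return list: `labels` (3D integer array, 0 = background), `sizes`
#'   (voxel count per cluster, decreasing), `clusters` (list of linear
#'   voxel index vectors, same order as `sizes`).
#' @export
label_clusters <- function(mask, connectivity = 26) {
  dims <- dim(mask)
  idx <- which(as.logical(mask))
  labels <- array(0L, dims)
  if (!length(idx)) return(list(labels = labels, sizes = integer(0),
                                clusters = list()))
  n <- length(idx)
  coord <- arrayInd(idx, dims)
  pos <- integer(prod(dims))
  pos[idx] <- seq_len(n)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  offs <- neighbor_offsets(connectivity)
  # half the offsets suffice (symmetry)
  offs <- offs[seq_len(nrow(offs) / 2), , drop = FALSE]
  for (o in seq_len(nrow(offs))) {
    nc1 <- coord[, 1] + offs[o, 1]
    nc2 <- coord[, 2] + offs[o, 2]
    nc3 <- coord[, 3] + offs[o, 3]
    ok <- nc1 >= 1 & nc1 <= dims[1] & nc2 >= 1 & nc2 <= dims[2] &
      nc3 >= 1 & nc3 <= dims[3]
    if (!any(ok)) next
    nlin <- (nc3[ok] - 1L) * dims[1] * dims[2] + (nc2[ok] - 1L) * dims[1] + nc1[ok]
    j <- pos[nlin]
    ii <- which(ok)[j > 0]
    jj <- j[j > 0]
    for (m in seq_along(ii)) {
      ri <- find(ii[m]); rj <- find(jj[m])
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  comp <- match(roots, unique(roots))
  sizes <- tabulate(comp)
  ord <- order(sizes, decreasing = TRUE)
  rank_of <- match(seq_along(sizes), ord)
  labels[idx] <- rank_of[comp]
  clusters <- split(idx, rank_of[comp])
  clusters <- clusters[order(as.integer(names(clusters)))]
  list(labels = labels, sizes = sizes[ord], clusters = unname(clusters))
}

max_cluster_size <- function(mask, connectivity) {
  s <- label_clusters(mask, connectivity)$sizes
  if (length(s)) s[1] else 0L
}

#' Threshold a group map with sign-flip permutation cluster-level FWE
#'
#' Voxels pass at one-sided `p < voxel_p` on t(dof); clusters are formed
#' under the chosen connectivity; the null distribution of the maximum
#' cluster extent is built by randomly sign-flipping the subject effect
#' maps (exhaustively when `2^n < n_permutations`, with a warning); a
#' cluster is kept when its extent exceeds the `1 - cluster_alpha`
#' quantile of that null.
#'
#' @param group a `group_stat_map`.
#' @param subject_maps the per-subject effect maps the group map came from.
#' @param voxel_p one-sided voxelwise p threshold (default 0.001).
#' @param cluster_alpha cluster-level FWE alpha (default 0.05).
#' @param n_permutations number of sign flips (>= 100).
#' @param seed integer seed for the random flips.
#' @param connectivity 6, 18 or 26.
#' @return list of class `thresholded_map`: `mask` (3D logical),
#'   `clusters`, `cluster_sizes`, `cluster_p`, `voxel_p_threshold`,
#'   `cluster_alpha`, `n_permutations`, `null_max_cluster_sizes`,
#'   `size_threshold`, `t_threshold`.
#' @export
threshold_with_cluster_fwe <- function(group, subject_maps, voxel_p = 0.001,
                                       cluster_alpha = 0.05,
                                       n_permutations = 1000L, seed = 1L,
                                       connectivity = 26) {
  if (n_permutations < 100) stopf("threshold_with_cluster_fwe: need >= 100 permutations")
  sm <- subject_maps_matrix(subject_maps)
  n <- nrow(sm$M)
  tthr <- stats::qt(1 - voxel_p, df = group$dof)
  obs_mask <- array(group$t > tthr, sm$dims)
  obs <- label_clusters(obs_mask, connectivity)

  if (2^n < n_permutations) {
    warnf("only 2^%d = %d distinct sign flips; using exhaustive enumeration",
          n, 2^n)
    S <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
  } else {
    S <- with_seed(child_seed(seed, "signflip"), {
      rbind(rep(1, n),
            matrix(sample(c(-1, 1), (n_permutations - 1) * n, replace = TRUE),
                   n_permutations - 1, n))
    })
  }
  R <- nrow(S)
  E2 <- colMeans(sm$M^2)
  null_max <- integer(R)
  chunk <- 256L
  for (start in seq(1L, R, by = chunk)) {
    rows <- start:min(start + chunk - 1L, R)
    Mu <- (S[rows, , drop = FALSE] %*% sm$M) / n
    Vv <- sweep(-Mu^2, 2, E2, "+") * (n / (n - 1))
    Tm <- Mu / sqrt(pmax(Vv, 0) / n)
    Tm[!is.finite(Tm)] <- 0
    hits <- Tm > tthr
    any_hit <- rowSums(hits) > 0
    for (r in which(any_hit)) {
      null_max[rows[r]] <- max_cluster_size(array(hits[r, ], sm$dims),
                                            connectivity)
    }
  }
  size_thr <- stats::quantile(null_max, 1 - cluster_alpha, type = 1, names = FALSE)
  keep <- obs$sizes > size_thr
  cluster_p <- vapply(obs$sizes, function(s) mean(null_max >= s), numeric(1))
  mask <- array(FALSE, sm$dims)
  for (ci in which(keep)) mask[obs$clusters[[ci]]] <- TRUE
  structure(list(mask = mask, clusters = obs$clusters[keep],
                 cluster_sizes = obs$sizes[keep], cluster_p = cluster_p[keep],
                 all_cluster_sizes = obs$sizes, all_cluster_p = cluster_p,
                 voxel_p_threshold = voxel_p, cluster_alpha = cluster_alpha,
                 n_permutations = R, null_max_cluster_sizes = null_max,
                 size_threshold = size_thr, t_threshold = tthr),
            class = "thresholded_map")
}

#' Conjunction (intersection) of two thresholded masks
#'
#' @param a,b `thresholded_map`s or bare 3D logical arrays on one grid.
#' @return 3D logical array, the voxelwise AND.
#' @export
conjunction <- function(a, b) {
  ma <- if (inherits(a, "thresholded_map")) a$mask else a
  mb <- if (inherits(b, "thresholded_map")) b$mask else b
  if (!identical(dim(ma), dim(mb))) stopf("conjunction: grid mismatch")
  ma & mb
}

#' Split a mask into shared ROIs by atlas parcel
#'
#' Mask voxels are grouped by their atlas label; groups smaller than
#' `min_voxels` are dropped with a log entry, as are background voxels.
#'
#' @param mask 3D logical array.
#' @param atlas a `label_volume` on the same grid.
#' @param min_voxels minimum ROI size to keep.
#' @return list of `shared_roi`s: `name` ("shared-<label>"), `voxels`
#'   (n x 3 matrix of 0-based i,j,k), `voxel_idx` (1-based linear),
#'   `parent_label`.
#' @export
segment_shared_rois <- function(mask, atlas, min_voxels = 1L) {
  if (!identical(dim(mask), dim(atlas$grid))) {
    stopf("segment_shared_rois: grid mismatch")
  }
  idx <- which(as.logical(mask))
  labs <- atlas$grid[idx]
  n_bg <- sum(labs == 0L)
  if (n_bg > 0) log_note("segment_shared_rois: %d mask voxels on background excluded", n_bg)
  rois <- list()
  for (lab in sort(unique(labs[labs != 0L]))) {
    vox <- idx[labs == lab]
    name <- sprintf("shared-%s", atlas$label_names[as.character(lab)])
    if (length(vox) < min_voxels) {
      log_note("segment_shared_rois: %s dropped (%d < %d voxels)",
               name, length(vox), min_voxels)
      next
    }
    rois[[name]] <- structure(
      list(name = name, voxels = arrayInd(vox, dim(mask)) - 1L,
           voxel_idx = vox, parent_label = unname(atlas$label_names[as.character(lab)])),
      class = "shared_roi")
  }
  rois
}

#' Build a shared ROI directly from an atlas parcel
#'
#' Used when ROIs are taken from the atlas rather than from a conjunction
#' mask (e.g. null-cohort chance-level checks).
#' @param atlas a `label_volume`.
#' @param name parcel name.
#' @return a `shared_roi`.
#' @export
atlas_roi <- function(atlas, name) {
  vox <- atlas_region_voxels(atlas, name)
  lin <- vox[, 1] + (vox[, 2] - 1L) * dim(atlas$grid)[1] +
    (vox[, 3] - 1L) * dim(atlas$grid)[1] * dim(atlas$grid)[2]
  structure(list(name = sprintf("shared-%s", name), voxels = vox - 1L,
                 voxel_idx = lin, parent_label = name),
            class = "shared_roi")
}
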