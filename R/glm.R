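# Subject-level GLM: Gaussian smoothing, OLS with pooled AR(1)
# prewhitening (two-pass Cochrane-Orcutt style, one rho per run), and
# contrast t-maps.

gaussian_axis_matrix <- function(n, sigma_vox) {
  # n x n smoothing operator along one axis, reflective boundary,
  # kernel truncated at 4 sigma and sum-normalized
  if (sigma_vox <= 0) return(diag(n))
  half <- max(1L, ceiling(4 * sigma_vox))
  off <- -half:half
  k <- exp(-off^2 / (2 * sigma_vox^2))
  k <- k / sum(k)
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i + off
    # reflect: index m maps to the in-range mirror position
    j <- ifelse(j < 1, 2 - j, j)
    j <- ifelse(j > n, 2 * n - j, j)
    for (m in seq_along(j)) M[i, j[m]] <- M[i, j[m]] + k[m]
  }
  M
}

#' Gaussian-smooth a 4D volume series (per volume, separable)
#'
#' `sigma = fwhm / (2 sqrt(2 ln 2))` per axis in mm, converted to voxels
#' by the voxel size. Boundaries are reflective, which preserves the mean
#' of constant volumes exactly.
#'
#' @param vol a `volume_series` or bare 3D/4D array.
#' @param fwhm_mm numeric triple of FWHM in mm (0 = identity on that axis).
#' @param voxel_size_mm voxel sizes in mm; taken from the affine of a
#'   `volume_series` if missing.
#' @return same type as `vol`, smoothed.
#' @export
smooth_volume <- function(vol, fwhm_mm = c(8, 8, 8), voxel_size_mm = NULL) {
  is_vs <- inherits(vol, "volume_series")
  data <- if (is_vs) vol$data else vol
  if (is.null(voxel_size_mm)) {
    voxel_size_mm <- if (is_vs) sqrt(colSums(vol$affine[1:3, 1:3]^2)) else c(1, 1, 1)
  }
  if (any(fwhm_mm < 0)) stopf("smooth_volume: fwhm must be >= 0")
  dims <- dim(data)
  nd <- length(dims)
  d3 <- dims[1:3]
  nt <- if (nd == 4) dims[4] else 1L
  sig <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
  x <- matrix(data, prod(d3), nt)
  for (ax in 1:3) {
    if (sig[ax] <= 0) next
    M <- gaussian_axis_matrix(d3[ax], sig[ax])
    perm <- c(ax, setdiff(1:3, ax), 4)
    arr <- aperm(array(x, c(d3, nt)), perm)
    dm <- dim(arr)
    arr <- M %*% matrix(arr, dm[1], prod(dm[-1]))
    arr <- array(arr, dm)
    x <- matrix(aperm(arr, order(perm)), prod(d3), nt)
  }
  out <- array(x, dims)
  if (is_vs) { vol$data <- out; vol } else out
}

#' Fit the voxelwise GLM with pooled AR(1) prewhitening
#'
#' Two passes: ordinary least squares, then a single lag-1 autocorrelation
#' coefficient pooled over in-mask residuals, an AR(1) whitening transform
#' of both data and design, and a refit. With `rho = 0` the whitening is
#' the identity and the fit is exactly OLS.
#'
#' @param vol a `volume_series`, or a T x V data matrix.
#' @param X a `design_matrix`.
#' @param mask 3D logical/0-1 array (NULL = all voxels of a matrix input).
#' @param rho optional fixed AR(1) coefficient; NULL (default) pools the
#'   estimate from first-pass residuals. `rho = 0` is exactly OLS.
#' @return list of class `glm_fit`: `beta` (P x V), `sigma2` (V), `rho`,
#'   `dof`, `design`, `mask_idx`, `grid_dim`, `xtx_inv` (whitened).
#' @export
fit_glm <- function(vol, X, mask = NULL, rho = NULL) {
  if (inherits(vol, "volume_series")) {
    dims <- dim(vol$data)
    grid_dim <- dims[1:3]
    Y_all <- t(matrix(vol$data, prod(grid_dim), dims[4]))
    if (is.null(mask)) mask <- array(TRUE, grid_dim)
    mask_idx <- which(as.logical(mask))
    Y <- Y_all[, mask_idx, drop = FALSE]
  } else {
    Y <- as.matrix(vol)
    grid_dim <- NULL
    mask_idx <- seq_len(ncol(Y))
  }
  if (!length(mask_idx)) stopf("fit_glm: empty mask")
  Xm <- X$values
  if (nrow(Xm) != nrow(Y)) {
    stopf("fit_glm: %d volumes vs %d design rows", nrow(Y), nrow(Xm))
  }
  rank_check <- function(M) {
    qd <- qr(M)
    if (qd$rank < ncol(M)) {
      bad <- colnames(M)[qd$pivot[(qd$rank + 1):ncol(M)]]
      stopf("fit_glm: rank-deficient design; collinear columns: %s",
            paste(bad, collapse = ", "))
    }
    qd
  }
  ols <- function(Xw, Yw) {
    qd <- rank_check(Xw)
    beta <- qr.coef(qd, Yw)
    resid <- Yw - Xw %*% beta
    list(beta = beta, resid = resid, qd = qd)
  }
  pass1 <- ols(Xm, Y)
  if (is.null(rho)) {
    E <- pass1$resid
    num <- sum(E[-1, , drop = FALSE] * E[-nrow(E), , drop = FALSE])
    den <- sum(E^2)
    rho <- if (den > 0) num / den else 0
    rho <- max(min(rho, 0.99), -0.99)
  } else if (abs(rho) >= 1) {
    stopf("fit_glm: |rho| must be < 1")
  }
  if (abs(rho) > 1e-12) {
    Tn <- nrow(Y)
    Yw <- rbind(sqrt(1 - rho^2) * Y[1, , drop = FALSE],
                Y[-1, , drop = FALSE] - rho * Y[-Tn, , drop = FALSE])
    Xw <- rbind(sqrt(1 - rho^2) * Xm[1, , drop = FALSE],
                Xm[-1, , drop = FALSE] - rho * Xm[-Tn, , drop = FALSE])
    fit <- ols(Xw, Yw)
  } else {
    Xw <- Xm
    fit <- pass1
  }
  dof <- nrow(Y) - ncol(Xm)
  sigma2 <- colSums(fit$resid^2) / dof
  xtx_inv <- chol2inv(qr.R(fit$qd))[order(fit$qd$pivot), order(fit$qd$pivot),
                                    drop = FALSE]
  structure(list(beta = fit$beta, sigma2 = sigma2, rho = rho, dof = dof,
                 design = X, mask_idx = mask_idx, grid_dim = grid_dim,
                 xtx_inv = xtx_inv),
            class = "glm_fit")
}

#' Compute a contrast effect and t map from a GLM fit
#'
#' @param fit a `glm_fit`.
#' @param weights named numeric vector of column weights (e.g.
#'   `c("NA" = 1, "NR" = -1)`); unnamed columns get weight 0.
#' @return list of class `contrast_map`: `contrast_vector`, `effect`, `t`
#'   (3D arrays when the fit has a grid, else vectors; out-of-mask voxels
#'   NA), `dof`, `name`.
#' @export
compute_contrast <- function(fit, weights) {
  cn <- colnames(fit$design$values)
  if (!all(names(weights) %in% cn)) {
    stopf("compute_contrast: unknown columns: %s",
          paste(setdiff(names(weights), cn), collapse = ", "))
  }
  cvec <- stats::setNames(numeric(length(cn)), cn)
  cvec[names(weights)] <- weights
  if (all(cvec == 0)) stopf("compute_contrast: all-zero contrast")
  eff <- as.numeric(cvec %*% fit$beta)
  cvar <- as.numeric(cvec %*% fit$xtx_inv %*% cvec)
  se <- sqrt(fit$sigma2 * cvar)
  tv <- ifelse(se > 0, eff / se, 0)
  shape <- function(v) {
    if (is.null(fit$grid_dim)) return(v)
    out <- array(NA_real_, fit$grid_dim)
    out[fit$mask_idx] <- v
    out
  }
  nm <- paste(names(weights)[order(-weights[names(weights)])], collapse = "-")
  structure(list(contrast_vector = cvec, effect = shape(eff), t = shape(tv),
                 dof = fit$dof, name = nm),
            class = "contrast_map")
}
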