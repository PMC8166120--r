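# Seed-based connectivity: spherical ROIs in mm space, global-signal
# regression, and whole-brain Fisher-z seed-correlation maps.

#' Packaged seed definitions
#'
#' Returns the five analysis seeds (retrosplenial cortex, left/right
#' posterior hippocampus, left/right dorsal anterior insula) with their MNI
#' centre coordinates and the default 12-mm sphere diameter, as shipped in
#' `inst/extdata/seed_rois.tsv`.
#'
#' @return A tibble: `label`, `x`, `y`, `z` (mm), `diameter` (mm).
#' @export
seed_table <- function() {
  path <- system.file("extdata", "seed_rois.tsv", package = "fcgrowth")
  readr::read_tsv(path, show_col_types = FALSE)
}

# 4x4 voxel-to-mm affine of a grid: an RNifti image carries its own xform;
# a plain array uses an identity-scaled RAS affine at `voxel_size`
grid_affine <- function(grid, voxel_size = NULL) {
  if (inherits(grid, "niftiImage")) {
    return(structure(RNifti::xform(grid), dimnames = NULL))
  }
  vs <- voxel_size %||% attr(grid, "voxel_size") %||% 1
  if (length(vs) == 1) vs <- rep(vs, 3)
  rbind(cbind(diag(vs), c(0, 0, 0)), c(0, 0, 0, 1))
}

grid_dims3 <- function(grid) dim(grid)[1:3]

# voxel size in mm along each axis, from the affine
affine_voxel_size <- function(aff) sqrt(colSums(aff[1:3, 1:3]^2))

#' Build a spherical region of interest on the analysis grid
#'
#' Voxels whose centre lies within `diameter/2` mm of the seed coordinate,
#' intersected with the gray-matter mask. Membership is by voxel-centre
#' distance; there is no partial-volume weighting.
#'
#' @param seed a one-row data frame or list with `label`, `x`, `y`, `z`
#'   (mm) and `diameter` (mm, default 12).
#' @param grid a 3D array or RNifti image defining the grid (dims +
#'   affine); typically the mask itself.
#' @param gray_matter_mask 3D array/image of 0/1 (defaults to `grid` when it
#'   is a mask).
#' @return Integer matrix of voxel indices (columns i, j, k, 1-based).
#' @export
make_sphere_roi <- function(seed, grid, gray_matter_mask = grid) {
  diameter <- seed$diameter %||% 12
  aff <- grid_affine(grid)
  dims <- grid_dims3(grid)
  center <- c(seed$x, seed$y, seed$z)
  # seed centre must fall inside the grid
  vox <- solve(aff, c(center, 1))[1:3] + 1
  if (any(vox < 0.5) || any(vox > dims + 0.5))
    abort(paste0("Seed '", seed$label, "' centre lies outside the grid."))
  r <- diameter / 2
  vs <- affine_voxel_size(aff)
  halo <- ceiling(r / vs) + 1
  rng <- lapply(1:3, function(d)
    max(1, floor(vox[d] - halo[d])):min(dims[d], ceiling(vox[d] + halo[d])))
  g <- as.matrix(expand.grid(i = rng[[1]], j = rng[[2]], k = rng[[3]]))
  world <- t(aff %*% rbind(t(g) - 1, 1))[, 1:3, drop = FALSE]
  d2 <- rowSums(sweep(world, 2, center)^2)
  g <- g[d2 <= r^2 + 1e-9, , drop = FALSE]
  mask <- as.array(gray_matter_mask)
  keep <- mask[g] > 0
  g <- g[keep, , drop = FALSE]
  if (nrow(g) == 0)
    abort(paste0("Seed '", seed$label,
                 "' has an empty ROI after gray-matter masking."))
  g
}

#' Regress the global signal out of a 4D image
#'
#' Replaces every voxel's time series with the residuals of its least-squares
#' regression on an intercept and the global (within-mask) mean series. The
#' output is orthogonal to the global signal and invariant to constant
#' intensity offsets.
#'
#' @param image_4d 4D array (x, y, z, time), at least 2 volumes.
#' @param brain_mask 3D 0/1 array of in-brain voxels.
#' @return The residualized 4D array (attributes preserved).
#' @export
regress_global_signal <- function(image_4d, brain_mask) {
  dims <- dim(image_4d)
  if (length(dims) != 4 || dims[4] < 2)
    abort("`image_4d` must be a 4D array with at least 2 volumes.")
  mask <- as.array(brain_mask) > 0
  if (!all(dim(mask) == dims[1:3])) abort("Mask dimensions do not match.")
  V <- prod(dims[1:3])
  Y <- matrix(image_4d, V, dims[4])          # voxels x time
  g <- colMeans(Y[as.vector(mask), , drop = FALSE])
  if (sd(g) == 0) abort("Global signal is constant; cannot regress it out.")
  X <- cbind(1, g)
  beta <- solve(crossprod(X), crossprod(X, t(Y)))   # 2 x V
  res <- t(Y) - X %*% beta                          # time x voxels
  out <- array(t(res), dims)
  attributes(out) <- attributes(image_4d)
  out
}

#' Fisher z-transform of a correlation
#'
#' `atanh(r)`, strictly increasing and odd on (-1, 1). Correlations of
#' exactly +/-1 (degenerate series) are clamped to +/-(1 - 1e-7) before the
#' transform so that downstream maps stay finite; `|r| > 1` is an error.
#'
#' @param r correlation value(s) with `|r| <= 1`.
#' @return Fisher z value(s).
#' @examples
#' fisher_z(0.5)   # 0.5493061
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE))
    abort("Correlations must satisfy |r| <= 1.")
  eps <- 1e-7
  r <- pmin(pmax(r, -1 + eps), 1 - eps)
  atanh(r)
}

#' Whole-brain Fisher-z seed-correlation map
#'
#' Correlates the mean time series over a spherical ROI with every
#' gray-matter voxel's series (Pearson), then applies the Fisher
#' z-transform. Voxels with zero-variance series are flagged undefined
#' (`NA`), never +/-Inf; correlations of exactly +/-1 are clamped (flag 1).
#'
#' @param image_4d 4D array (x, y, z, time), at least 3 volumes.
#' @param roi voxel-index matrix from [make_sphere_roi()] (non-empty).
#' @param gray_matter_mask 3D 0/1 array of voxels to map.
#' @param subject,wave,seed_label provenance carried on the result.
#' @return An object of class `"connectivity_map"`: `z` (3D array, `NA`
#'   outside the mask and at undefined voxels), `flags` (3D integer: 0 ok,
#'   1 clamped, 2 undefined), and grid metadata.
#' @export
seed_map <- function(image_4d, roi, gray_matter_mask,
                     subject = NA_character_, wave = NA_integer_,
                     seed_label = NA_character_) {
  dims <- dim(image_4d)
  if (length(dims) != 4 || dims[4] < 3)
    abort("`image_4d` must be 4D with at least 3 volumes.")
  roi <- rbind(roi)
  if (nrow(roi) == 0) abort("ROI is empty.")
  mask <- as.array(gray_matter_mask) > 0
  V <- prod(dims[1:3])
  Y <- matrix(image_4d, V, dims[4])
  roi_lin <- roi[, 1] + (roi[, 2] - 1) * dims[1] +
    (roi[, 3] - 1) * dims[1] * dims[2]
  ref <- colMeans(Y[roi_lin, , drop = FALSE])
  if (sd(ref) == 0) abort("ROI mean series has zero variance.")
  vix <- which(as.vector(mask))
  Ym <- Y[vix, , drop = FALSE]
  cY <- Ym - rowMeans(Ym)
  cref <- ref - mean(ref)
  denom <- sqrt(rowSums(cY^2) * sum(cref^2))
  num <- as.vector(cY %*% cref)
  r <- ifelse(denom > 0, num / denom, NA_real_)
  r <- pmin(pmax(r, -1), 1)
  flags_v <- integer(length(r))
  flags_v[!is.na(r) & abs(r) >= 1 - 1e-12] <- 1L
  flags_v[is.na(r)] <- 2L
  z <- array(NA_real_, dims[1:3])
  z[vix] <- fisher_z(r)
  z[vix][flags_v == 2L] <- NA_real_
  flags <- array(0L, dims[1:3])
  flags[vix] <- flags_v
  structure(list(z = z, flags = flags, subject = subject, wave = wave,
                 seed_label = seed_label,
                 voxel_size = attr(image_4d, "voxel_size") %||% 1),
            class = "connectivity_map")
}
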