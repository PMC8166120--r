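# File interfaces: NIfTI volumes for maps/masks, TSV for tables, JSON for
# fitted models and ground truth.

# wrap a 3D/4D array as an RNifti image with isotropic voxel size (RAS,
# identity-scaled affine)
as_nifti_grid <- function(arr, voxel_size = 2) {
  img <- RNifti::asNifti(unclass(arr))
  nd <- length(dim(arr))
  pd <- rep(voxel_size, min(nd, 3))
  if (nd > 3) pd <- c(pd, rep(1, nd - 3))
  RNifti::pixdim(img) <- pd
  img
}

#' Write a simulated voxel field to disk as a NIfTI + TSV dataset
#'
#' Materializes a [generate_voxel_field()] result the way a real study
#' would arrive: one 3D NIfTI map per subject and attended wave, a manifest
#' TSV mapping (subject, wave) to file paths, a covariate TSV, the
#' ground-truth cluster mask as NIfTI, and a JSON file recording the planted
#' parameters.
#'
#' @param field a `"voxel_field"` object.
#' @param dir output directory (created if needed).
#' @return Invisibly, a list with the `manifest` and `covariates` tibbles
#'   and the paths written.
#' @export
write_voxel_field <- function(field, dir) {
  stopifnot(inherits(field, "voxel_field"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pres <- present_matrix(field$records)
  n <- nrow(field$records); Tn <- ncol(pres)
  rows <- list()
  for (i in seq_len(n)) {
    for (t in seq_len(Tn)) {
      if (!pres[i, t]) next
      vol <- array(field$data[i, t, ], field$grid_dims)
      fn <- file.path(dir, sprintf("%s_w%d.nii.gz",
                                   field$records$subject_id[i], t))
      RNifti::writeNifti(as_nifti_grid(vol, field$voxel_size), fn)
      rows[[length(rows) + 1L]] <- tibble(
        subject = field$records$subject_id[i], wave = t, path = fn)
    }
  }
  manifest <- dplyr::bind_rows(rows)
  man_path <- file.path(dir, "manifest.tsv")
  readr::write_tsv(manifest, man_path)
  cov_path <- file.path(dir, "covariates.tsv")
  readr::write_tsv(field$records, cov_path)
  mask_path <- file.path(dir, "truth_mask.nii.gz")
  RNifti::writeNifti(
    as_nifti_grid(array(as.integer(field$truth_mask), field$grid_dims),
                  field$voxel_size), mask_path)
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(
    list(truth = unclass(field$truth), seed = field$seed,
         voxel_size = field$voxel_size, grid_dims = field$grid_dims,
         truth_mask = mask_path),
    truth_path, auto_unbox = TRUE, digits = NA)
  invisible(list(manifest = manifest, covariates = field$records,
                 dir = dir, manifest_path = man_path,
                 covariates_path = cov_path, truth_mask_path = mask_path))
}

#' Write a voxelwise result set to disk
#'
#' One NIfTI volume per statistic (estimate, se, z, p, chisq, cfi, rmsea,
#' srmr, loglik, convergence/constraint flags), a run-report JSON (voxels
#' fit, converged, constrained, inadmissible), and — when a cluster set is
#' supplied — a cluster table TSV (id, voxel count, volume in mm3, minimum
#' p, peak voxel and mm coordinates) and the cluster label volume.
#'
#' @param maps a `"stat_map_set"` from [fit_voxelwise()].
#' @param dir output directory (created if needed).
#' @param clusters optional `"cluster_set"` from [cluster_correct()].
#' @return Invisibly, the paths written.
#' @export
write_stat_maps <- function(maps, dir, clusters = NULL) {
  stopifnot(inherits(maps, "stat_map_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (nm in names(maps$volumes)) {
    p <- file.path(dir, paste0(nm, ".nii.gz"))
    RNifti::writeNifti(as_nifti_grid(maps$volumes[[nm]], maps$voxel_size), p)
    paths[nm] <- p
  }
  rep_path <- file.path(dir, "run_report.json")
  jsonlite::write_json(maps$report, rep_path, auto_unbox = TRUE, digits = NA)
  paths["run_report"] <- rep_path
  if (!is.null(clusters)) {
    tab <- dplyr::select(clusters$clusters, -"members")
    tab$peak_x_mm <- (tab$peak_i - 1) * maps$voxel_size
    tab$peak_y_mm <- (tab$peak_j - 1) * maps$voxel_size
    tab$peak_z_mm <- (tab$peak_k - 1) * maps$voxel_size
    ct_path <- file.path(dir, "clusters.tsv")
    readr::write_tsv(tab, ct_path)
    paths["clusters"] <- ct_path
    lab_path <- file.path(dir, "cluster_labels.nii.gz")
    RNifti::writeNifti(as_nifti_grid(clusters$labels, maps$voxel_size),
                       lab_path)
    paths["cluster_labels"] <- lab_path
  }
  invisible(paths)
}

#' Write a Fisher-z connectivity map as NIfTI
#'
#' @param cm a `"connectivity_map"` from [seed_map()].
#' @param path output path (`.nii.gz`).
#' @return The path, invisibly.
#' @export
write_connectivity_map <- function(cm, path) {
  stopifnot(inherits(cm, "connectivity_map"))
  RNifti::writeNifti(as_nifti_grid(cm$z, cm$voxel_size), path)
  invisible(path)
}

#' Serialize a fitted growth model to JSON
#'
#' Writes the full parameter table (tilde-notation labels), fit indices and
#' flags, mirroring the layout used for per-voxel reporting tables.
#'
#' @param fit an `"lgm_fit"`.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "lgm_fit"))
  out <- list(
    estimates = fit$estimates,
    fit = fit$fit,
    logLik = fit$logLik,
    n = fit$n,
    converged = fit$converged,
    constrained = as.list(fit$constrained),
    inadmissible = fit$inadmissible,
    warnings = as.list(fit$warnings))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
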