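# voxelwise pipeline: stacking, per-voxel fits, quality masking, cluster
# correction, peak selection

library(dplyr)

small_field <- function(seed = 71, dims = c(6, 6, 6), n = 50,
                        clusters = list()) {
  cfg <- simulation_config(n_subjects = n, n_longitudinal = n,
                           grid_dims = dims, effect_clusters = clusters,
                           truth = fixture_truth(), seed = seed)
  generate_voxel_field(cfg)
}

test_that("NIfTI round trip: stacked maps equal the generated panels", {
  field <- small_field(seed = 72, dims = c(4, 4, 4), n = 20)
  dir <- withr::local_tempdir()
  out <- write_voxel_field(field, dir)
  stack <- stack_maps(out$manifest, out$covariates)
  expect_equal(dim(stack$data), dim(field$data))
  expect_equal(stack$data, field$data, tolerance = 1e-6)
  expect_equal(stack$voxel_size, 2, tolerance = 1e-6)
  # absent (subject, wave) pairs are missing outcomes at every voxel
  pres <- fcgrowth:::present_matrix(field$records)
  i_miss <- which(!pres[, 2])[1]
  expect_true(all(is.na(stack$data[i_miss, 2, ])))
})

test_that("stacking validates grids and covariate coverage", {
  field <- small_field(seed = 73, dims = c(4, 4, 4), n = 12)
  dir <- withr::local_tempdir()
  out <- write_voxel_field(field, dir)
  # a map on a different grid is rejected by file name
  bad <- out$manifest
  odd_img <- fcgrowth:::as_nifti_grid(array(0, c(5, 5, 5)), 2)
  odd_path <- file.path(dir, "odd.nii.gz")
  RNifti::writeNifti(odd_img, odd_path)
  bad$path[3] <- odd_path
  expect_error(stack_maps(bad, out$covariates), "odd.nii.gz")
  # a manifest subject without covariates is rejected
  cov2 <- out$covariates[-1, ]
  expect_error(stack_maps(out$manifest, cov2), "S001")
  # empty analysis mask warns and yields an empty stack
  expect_warning(
    st0 <- stack_maps(out$manifest, out$covariates,
                      mask = array(0, c(4, 4, 4))), "empty")
  expect_equal(length(st0$voxel_index), 0)
})

test_that("voxelwise fits equal single-table fits at every voxel", {
  field <- small_field(seed = 74, dims = c(3, 3, 3), n = 60)
  stack <- as_map_stack(field)
  maps <- fit_voxelwise(stack, seed = 1)
  spec <- maps$spec
  for (v in c(1, 9, 27)) {
    df <- fcgrowth:::voxel_data_frame(stack, v)
    ref <- apply_heywood_rule(fit_lgm(df, spec, n_starts = 1))
    expect_equal(maps$volumes$estimate[v],
                 unname(ref$params["S~mfq_fof"]), tolerance = 1e-5)
    expect_equal(maps$volumes$chisq[v], ref$fit$chisq, tolerance = 1e-3)
    expect_equal(maps$volumes$cfi[v], ref$fit$cfi, tolerance = 1e-4)
    expect_equal(maps$volumes$srmr[v], ref$fit$srmr, tolerance = 1e-3)
    expect_equal(maps$volumes$constrained[v],
                 as.numeric(length(ref$constrained) > 0))
  }
})

test_that("voxelwise output is deterministic and order-independent", {
  field <- small_field(seed = 75, dims = c(4, 4, 4), n = 40)
  stack <- as_map_stack(field)
  m1 <- fit_voxelwise(stack, seed = 3)
  m2 <- fit_voxelwise(stack, seed = 3)
  expect_identical(m1$volumes, m2$volumes)
  # permuting voxels permutes results but does not change them
  perm <- rev(seq_along(stack$voxel_index))
  stack_p <- stack
  stack_p$data <- stack$data[, , perm, drop = FALSE]
  stack_p$voxel_index <- stack$voxel_index[perm]
  m3 <- fit_voxelwise(stack_p, seed = 3)
  expect_equal(m3$volumes$estimate, m1$volumes$estimate, tolerance = 1e-10)
})

test_that("fit-quality mask uses closed thresholds and convergence", {
  dims <- c(2, 2, 2)
  maps <- structure(list(
    volumes = list(
      rmsea = array(c(0.10, 0.11, 0, 0, 0, 0, 0, 0), dims),
      cfi = array(c(0.90, 0.95, 0.89, 1, 1, 1, 1, 1), dims),
      srmr = array(c(0.10, 0.05, 0.05, 0.11, 0, 0, 0, 0), dims),
      converged = array(c(1, 1, 1, 1, 0, 1, 1, 1), dims)),
    grid_dims = dims, voxel_size = 2), class = "stat_map_set")
  qm <- fit_quality_mask(maps)
  # voxel 1 sits exactly on all three thresholds: passes (closed bounds)
  expect_equal(as.vector(qm)[1:5], c(1, 0, 0, 0, 0))
  expect_equal(as.vector(qm)[6:8], c(1, 1, 1))
  maps$volumes$srmr <- NULL
  expect_error(fit_quality_mask(maps), "srmr")
})

test_that("cluster labelling matches a plain-R flood-fill oracle", {
  flood_fill_label <- function(mask) {
    dims <- dim(mask)
    lab <- array(0L, dims)
    cur <- 0L
    nb <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
    for (s in which(mask > 0)) {
      if (lab[s] != 0L) next
      cur <- cur + 1L
      queue <- s
      lab[s] <- cur
      while (length(queue) > 0) {
        v <- queue[1]; queue <- queue[-1]
        ijk <- arrayInd(v, dims)
        for (r in 1:6) {
          nxt <- ijk + nb[r, ]
          if (any(nxt < 1) || any(nxt > dims)) next
          lin <- nxt[1] + (nxt[2] - 1) * dims[1] +
            (nxt[3] - 1) * dims[1] * dims[2]
          if (mask[lin] > 0 && lab[lin] == 0) {
            lab[lin] <- cur
            queue <- c(queue, lin)
          }
        }
      }
    }
    lab
  }
  set.seed(76)
  for (r in 1:25) {
    dims <- c(7, 7, 7)
    mask <- array(as.integer(runif(prod(dims)) < 0.25), dims)
    ours <- fcgrowth:::cpp_label_components(mask, 6L)
    oracle <- flood_fill_label(mask)
    expect_equal(max(ours), max(oracle))
    # identical partitions up to label naming
    key_ours <- as.integer(factor(as.vector(ours)[mask > 0],
                                  levels = unique(as.vector(ours)[mask > 0])))
    key_orc <- as.integer(factor(as.vector(oracle)[mask > 0],
                                 levels = unique(as.vector(oracle)[mask > 0])))
    expect_equal(key_ours, key_orc)
  }
  # 26-connectivity merges diagonal neighbours that 6-connectivity splits
  m <- array(0L, c(3, 3, 3))
  m[1, 1, 1] <- 1L; m[2, 2, 2] <- 1L
  expect_equal(max(fcgrowth:::cpp_label_components(m, 6L)), 2)
  expect_equal(max(fcgrowth:::cpp_label_components(m, 26L)), 1)
})

test_that("cluster extent thresholding enforces the minimum volume", {
  dims <- c(8, 8, 8)
  p <- array(1, dims)
  # one suprathreshold voxel: 8 mm3 at 2-mm voxels, below any sane cutoff
  p[4, 4, 4] <- 1e-6
  cs <- cluster_correct(p, voxel_p = 0.001, min_volume_mm3 = 240,
                        voxel_size = 2)
  expect_equal(nrow(cs$clusters), 0)
  # a 40-voxel block = 320 mm3 survives at 240 but not at 400
  p2 <- array(1, dims)
  p2[1:5, 1:4, 1:2] <- 1e-6
  cs2 <- cluster_correct(p2, voxel_p = 0.001, min_volume_mm3 = 240,
                         voxel_size = 2)
  expect_equal(nrow(cs2$clusters), 1)
  expect_equal(cs2$clusters$volume_mm3, 320)
  cs3 <- cluster_correct(p2, voxel_p = 0.001, min_volume_mm3 = 400,
                         voxel_size = 2)
  expect_equal(nrow(cs3$clusters), 0)
  # voxels excluded by the quality mask cannot form clusters
  qm <- array(1, dims); qm[1:5, 1:4, 1] <- 0
  cs4 <- cluster_correct(p2, quality_mask = qm, voxel_p = 0.001,
                         min_volume_mm3 = 240, voxel_size = 2)
  expect_equal(nrow(cs4$clusters), 0)
  expect_error(cluster_correct(p2, voxel_p = 0.001), "voxel size")
})

test_that("peak selection maximizes |estimate| among unconstrained voxels", {
  field <- small_field(seed = 77, dims = c(4, 4, 4), n = 60,
                       clusters = list(effect_cluster(c(2, 2, 2),
                                                      gamma = -0.3,
                                                      radius = 3.9)))
  stack <- as_map_stack(field)
  maps <- fit_voxelwise(stack, seed = 1)
  cl <- cluster_correct(maps, min_volume_mm3 = 64)
  expect_gt(nrow(cl$clusters), 0)
  pk <- select_peak(cl, maps, cluster_id = 1, refit = FALSE)
  members <- cl$clusters$members[[1]]
  est <- maps$volumes$estimate[members]
  con <- maps$volumes$constrained[members]
  best <- max(abs(est[con == 0]), na.rm = TRUE)
  expect_equal(abs(pk$estimate), best)
  pick <- maps$volumes$constrained[pk$voxel[1], pk$voxel[2], pk$voxel[3]]
  expect_equal(pick, 0)
  # the sign rule: the larger |estimate| wins regardless of sign (exhaustive
  # scan over members is the oracle above)
  pk2 <- select_peak(cl, maps, cluster_id = 1, refit = TRUE)
  expect_s3_class(pk2$fit, "lgm_fit")
  expect_s3_class(pk2$unconditional, "lgm_fit")
  expect_equal(unname(pk2$fit$params["S~mfq_fof"]), pk$estimate,
               tolerance = 1e-4)
  # unconditional slope-variance range across the cluster
  ur <- cluster_unconditional_range(maps, cl, cluster_id = 1)
  expect_equal(nrow(ur$per_voxel), nrow(members))
  expect_lte(ur$range$slope_var_min, ur$range$slope_var_max)
})
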