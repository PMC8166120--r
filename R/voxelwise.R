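# Voxelwise mass-univariate growth modelling: stack per-wave connectivity
# maps into a subjects x waves x voxels array, fit the growth model at every
# in-mask voxel, mask by fit quality, correct by cluster extent, report peaks.

#' Stack per-subject, per-wave connectivity maps into an analysis array
#'
#' Reads the NIfTI maps listed in a manifest, verifies that all share one
#' grid, and assembles a subjects x waves x in-mask-voxels array aligned
#' with the covariate table. A (subject, wave) pair absent from the manifest
#' becomes a missing outcome wave.
#'
#' @param manifest data frame with columns `subject`, `wave`, `path`.
#' @param covariates data frame with one row per subject (column
#'   `subject_id` or `subject`) holding the model covariates.
#' @param mask optional 3D array/image; `NULL` analyses every voxel.
#' @param covariate_cols covariate columns carried into the models.
#' @return An object of class `"map_stack"`.
#' @export
stack_maps <- function(manifest, covariates, mask = NULL,
                       covariate_cols = c("mfq_fof", "age_c")) {
  manifest <- as_tibble(manifest)
  covariates <- as_tibble(covariates)
  idcol <- intersect(c("subject_id", "subject"), names(covariates))[1]
  if (is.na(idcol)) abort("`covariates` needs a subject_id/subject column.")
  subjects <- covariates[[idcol]]
  missing_cov <- setdiff(unique(manifest$subject), subjects)
  if (length(missing_cov) > 0)
    abort(paste0("Subject(s) in manifest absent from covariates: ",
                 paste(missing_cov, collapse = ", ")))
  waves <- seq_len(max(manifest$wave))
  first <- RNifti::readNifti(manifest$path[1])
  dims <- dim(first)[1:3]
  aff <- grid_affine(first)
  vs <- affine_voxel_size(aff)[1]
  if (is.null(mask)) {
    voxel_index <- seq_len(prod(dims))
  } else {
    mask_arr <- as.array(mask)
    if (!all(dim(mask_arr)[1:3] == dims))
      abort("Mask grid does not match the maps.")
    voxel_index <- which(as.vector(mask_arr) > 0)
    if (length(voxel_index) == 0) {
      warn("Analysis mask is empty; returning an empty stack.")
    }
  }
  n <- length(subjects); Tn <- length(waves); V <- length(voxel_index)
  dat <- array(NA_real_, c(n, Tn, V))
  for (r in seq_len(nrow(manifest))) {
    img <- if (r == 1) first else RNifti::readNifti(manifest$path[r])
    if (!all(dim(img)[1:3] == dims) ||
        max(abs(grid_affine(img) - aff)) > 1e-4)
      abort(paste0("Grid mismatch in ", manifest$path[r]))
    i <- match(manifest$subject[r], subjects)
    t <- manifest$wave[r]
    if (V > 0) dat[i, t, ] <- as.vector(img)[voxel_index]
  }
  structure(list(data = dat, subjects = subjects, waves = waves,
                 voxel_index = voxel_index, grid_dims = dims,
                 voxel_size = vs,
                 covariates = covariates, covariate_cols = covariate_cols),
            class = "map_stack")
}

#' Convert a simulated voxel field to an analysis stack without file IO
#'
#' @param field a `"voxel_field"` from [generate_voxel_field()].
#' @param mask optional 3D mask array.
#' @param covariate_cols covariate columns carried into the models.
#' @return A `"map_stack"`, as from [stack_maps()].
#' @export
as_map_stack <- function(field, mask = NULL,
                         covariate_cols = c("mfq_fof", "age_c")) {
  stopifnot(inherits(field, "voxel_field"))
  V_all <- prod(field$grid_dims)
  if (is.null(mask)) {
    voxel_index <- seq_len(V_all)
    dat <- field$data
  } else {
    voxel_index <- which(as.vector(as.array(mask)) > 0)
    dat <- field$data[, , voxel_index, drop = FALSE]
  }
  structure(list(data = dat, subjects = field$records$subject_id,
                 waves = seq_len(dim(field$data)[2]),
                 voxel_index = voxel_index, grid_dims = field$grid_dims,
                 voxel_size = field$voxel_size,
                 covariates = field$records,
                 covariate_cols = covariate_cols),
            class = "map_stack")
}

# precomputation shared by every voxel: missingness patterns, per-wave OLS
# projectors for starts, the covariance-structure least-squares design, the
# joint-pattern template for the saturated EM, and the constant covariate
# likelihood terms
voxel_prep <- function(stack, spec) {
  dat <- stack$data
  n <- dim(dat)[1]; Tn <- dim(dat)[2]
  q <- length(spec$covariates)
  X <- as.matrix(stack$covariates[spec$covariates])
  storage.mode(X) <- "double"
  if (q > 0 && anyNA(X)) abort("Covariates must be complete.")
  obs_mat <- !is.na(dat[, , 1, drop = TRUE])
  obs_mat <- matrix(obs_mat, n, Tn)
  key <- apply(obs_mat, 1, function(r) paste(as.integer(r), collapse = ""))
  groups <- lapply(split(seq_len(n), key), function(idx) {
    obs <- which(obs_mat[idx[1], ])
    list(rows = idx, obs = obs, obs0 = as.integer(obs - 1L),
         X = X[idx, , drop = FALSE])
  })
  groups <- unname(groups)
  groups_cpp <- lapply(groups, function(g)
    list(rows = as.integer(g$rows), obs0 = g$obs0))

  rows_t <- lapply(seq_len(Tn), function(t) which(obs_mat[, t]))
  Xt <- lapply(rows_t, function(rr) cbind(1, X[rr, , drop = FALSE]))
  Pt <- lapply(Xt, function(x) solve(crossprod(x), t(x)))
  pair_idx <- list()
  pairs <- which(upper.tri(diag(Tn), diag = TRUE), arr.ind = TRUE)
  for (r in seq_len(nrow(pairs)))
    pair_idx[[r]] <- which(obs_mat[, pairs[r, 1]] & obs_mat[, pairs[r, 2]])

  Lambda <- spec$model$Lambda
  LamPinv <- solve(crossprod(Lambda), t(Lambda))
  pt <- spec$par_table
  free_psi <- pt[pt$mat == "Psi" & pt$free, ]
  free_theta <- pt[pt$mat == "Theta" & pt$free, ]
  Dm <- matrix(0, nrow(pairs), nrow(free_psi) + nrow(free_theta))
  if (nrow(free_psi) > 0) {
    for (r in seq_len(nrow(free_psi))) {
      i <- free_psi$row[r]; j <- free_psi$col[r]
      cf <- Lambda[pairs[, 1], i] * Lambda[pairs[, 2], j]
      if (i != j) cf <- cf + Lambda[pairs[, 1], j] * Lambda[pairs[, 2], i]
      Dm[, r] <- cf
    }
  }
  if (nrow(free_theta) > 0) {
    for (r in seq_len(nrow(free_theta)))
      Dm[, nrow(free_psi) + r] <-
        as.numeric(pairs[, 1] == free_theta$row[r] &
                     pairs[, 2] == free_theta$row[r])
  }
  Dpinv <- tryCatch(solve(crossprod(Dm), t(Dm)), error = function(e) NULL)

  # direct index maps from the least-squares starts into the parameter
  # vector (avoids per-voxel label matching)
  free <- pt[pt$free, ]
  map <- list(
    alpha_id = free$id[free$mat == "alpha"],
    alpha_row = free$row[free$mat == "alpha"],
    gamma_id = free$id[free$mat == "Gamma"],
    gamma_pos = cbind(free$row[free$mat == "Gamma"],
                      free$col[free$mat == "Gamma"]),
    b_id = free$id[free$mat == "B"],
    psi_id = free$id[free$mat == "Psi"],
    theta_id = free$id[free$mat == "Theta"],
    var_id = free$id[free$variance])

  # joint-pattern template for the saturated EM: outcomes then covariates
  joint <- lapply(groups, function(g) {
    obs_j <- c(g$obs, Tn + seq_len(q))
    list(obs = as.integer(obs_j - 1L), rows = g$rows, y_obs = g$obs)
  })
  x_mu <- if (q > 0) colMeans(X) else numeric(0)
  x_S <- if (q > 0) crossprod(sweep(X, 2, x_mu)) / n else matrix(0, 0, 0)
  x_var <- if (q > 0) diag(x_S) else numeric(0)
  llx <- if (q > 0) xblock_loglik(X) else 0
  ll_base_x <- if (q > 0)
    sum(vapply(seq_len(q), function(j) {
      s2 <- mean((X[, j] - mean(X[, j]))^2)
      -0.5 * n * (log(2 * pi) + log(s2) + 1)
    }, numeric(1))) else 0

  d_joint <- Tn + q
  df_base <- spec$moments - 2 * d_joint
  list(groups = groups, groups_cpp = groups_cpp, joint = joint, map = map,
       n = n, Tn = Tn, q = q, X = X,
       rows_t = rows_t, Xt = Xt, Pt = Pt, pairs = pairs,
       pair_idx = pair_idx, LamPinv = LamPinv, Dpinv = Dpinv,
       free_psi = free_psi, free_theta = free_theta,
       x_mu = x_mu, x_S = x_S, x_var = x_var,
       llx = llx, ll_base_x = ll_base_x, df_base = df_base,
       obs_mat = obs_mat)
}

# moment-based start vector for one voxel's outcome matrix (n x T)
voxel_start <- function(y, prep, spec) {
  Tn <- prep$Tn; q <- prep$q
  b0 <- numeric(Tn)
  bcov <- matrix(0, Tn, max(q, 1L))[, seq_len(q), drop = FALSE]
  R <- matrix(NA_real_, prep$n, Tn)
  for (t in seq_len(Tn)) {
    rr <- prep$rows_t[[t]]
    ct <- prep$Pt[[t]] %*% y[rr, t]
    b0[t] <- ct[1]
    if (q > 0) bcov[t, ] <- ct[-1]
    R[rr, t] <- y[rr, t] - drop(prep$Xt[[t]] %*% ct)
  }
  alpha_st <- drop(prep$LamPinv %*% b0)
  Gamma_st <- if (q > 0) prep$LamPinv %*% bcov else NULL
  cvec <- numeric(nrow(prep$pairs))
  for (r in seq_len(nrow(prep$pairs))) {
    idx <- prep$pair_idx[[r]]
    if (length(idx) < 3) { cvec[r] <- 0; next }
    a <- R[idx, prep$pairs[r, 1]]; b <- R[idx, prep$pairs[r, 2]]
    cvec[r] <- mean(a * b) - mean(a) * mean(b)
  }
  cv <- if (!is.null(prep$Dpinv)) drop(prep$Dpinv %*% cvec)
        else rep(0.05, nrow(prep$free_psi) + nrow(prep$free_theta))
  mp <- prep$map
  st <- numeric(spec$npar)
  st[mp$alpha_id] <- alpha_st[mp$alpha_row]
  if (length(mp$gamma_id) > 0) st[mp$gamma_id] <- Gamma_st[mp$gamma_pos]
  n_psi <- nrow(prep$free_psi)
  if (n_psi > 0) st[mp$psi_id] <- cv[seq_len(n_psi)]
  if (length(mp$theta_id) > 0) st[mp$theta_id] <- cv[-seq_len(n_psi)]
  floorv <- 0.05 * mean(pmax(cvec[prep$pairs[, 1] == prep$pairs[, 2]], 1e-6))
  st[mp$var_id] <- pmax(st[mp$var_id], floorv)
  names(st) <- spec$par_table$label[spec$par_table$free]
  st
}

# core single-voxel fit used by fit_voxelwise: one compiled call for the
# fit, observed-information SEs, saturated EM and baseline likelihood, then
# the iterated Heywood rule (refits through the generic engine when a
# negative variance needs constraining). Returns scalars + parameters.
fit_voxel_core <- function(y, prep, spec, spec_cache, target,
                           n_starts = 1, seed = 1) {
  st <- voxel_start(y, prep, spec)
  starts <- if (n_starts > 1) make_starts(spec, st, n_starts, seed)
            else matrix(st, ncol = 1)
  res <- cpp_voxel_pipeline(y, prep$X, spec$model, prep$groups_cpp, starts)
  if (!isTRUE(res$converged)) {
    # fall back to a conservative admissible start
    pt <- spec$par_table
    st2 <- st
    st2[pt$id[pt$free & pt$mat == "Psi" & !pt$variance]] <- 0
    st2[pt$id[pt$free & pt$variance]] <-
      pmax(st2[pt$id[pt$free & pt$variance]], 0.1)
    res <- cpp_voxel_pipeline(y, prep$X, spec$model, prep$groups_cpp,
                              matrix(st2, ncol = 1))
  }
  out <- list(converged = isTRUE(res$converged), constrained = 0L,
              inadmissible = 0L)
  if (!out$converged) {
    out[c("estimate", "se", "z", "p", "chisq", "cfi", "rmsea", "srmr",
          "loglik")] <- NA_real_
    out$params <- rep(NA_real_, spec$npar)
    return(out)
  }

  cur_spec <- spec
  par <- setNames(drop(res$par), names(st))
  ses <- drop(res$ses)
  ll_cond <- res$loglik
  ll_sat <- res$ll_sat
  sat_sigma <- res$sat_sigma
  ll_base <- res$ll_base_y + prep$ll_base_x

  # iterated boundary rule: fix CI-covering negative variances to 0, refit
  patterns <- NULL
  for (hw in seq_len(sum(spec$par_table$variance))) {
    pt <- cur_spec$par_table
    vfree <- pt$variance & pt$free
    ids <- pt$id[vfree]
    neg <- par[ids] < 0
    if (!any(neg)) break
    hi <- par[ids] + qnorm(0.975) * ses[ids]
    fixable <- neg & (is.na(hi) | hi >= 0)
    if (any(neg & !fixable)) out$inadmissible <- 1L
    if (!any(fixable)) break
    new_fix <- pt$label[vfree][fixable]
    old_vals <- setNames(pt$fixed_value[!pt$free], pt$label[!pt$free])
    cons <- c(old_vals, setNames(rep(0, length(new_fix)), new_fix))
    cons <- cons[!duplicated(names(cons))]
    cons <- cons[order(names(cons))]
    keysig <- paste(names(cons), cons, sep = "=", collapse = "|")
    if (is.null(spec_cache[[keysig]]))
      spec_cache[[keysig]] <- respec_with_constraints(spec, cons)
    new_spec <- spec_cache[[keysig]]
    st2 <- spec_par_template(new_spec)
    common <- intersect(names(st2), names(par))
    st2[common] <- par[common]
    res2 <- cpp_voxel_pipeline(y, prep$X, new_spec$model, prep$groups_cpp,
                               matrix(st2, ncol = 1), do_em = FALSE)
    if (!isTRUE(res2$converged)) break
    cur_spec <- new_spec
    par <- setNames(drop(res2$par), names(st2))
    ses <- drop(res2$ses)
    ll_cond <- res2$loglik
    out$constrained <- 1L
  }

  ll_joint <- ll_cond + prep$llx
  q <- prep$q
  dfm <- cur_spec$df
  idx <- indices_core(2 * (ll_sat - ll_joint), dfm,
                      2 * (ll_sat - ll_base), prep$df_base, prep$n)
  # SRMR against the saturated-estimate covariance
  srmr <- NA_real_
  if (is.matrix(sat_sigma) && nrow(sat_sigma) > 0) {
    impS <- tryCatch(cpp_implied_cov(as.numeric(par), cur_spec$model,
                                     prep$x_S),
                     error = function(e) NULL)
    if (!is.null(impS)) {
      sdv <- sqrt(diag(sat_sigma))
      Rres <- (sat_sigma - impS) / tcrossprod(sdv)
      srmr <- sqrt(mean(Rres[upper.tri(Rres, diag = TRUE)]^2))
    }
  }

  tgt <- match(target, names(par))
  est <- if (!is.na(tgt)) par[tgt] else NA_real_
  se <- if (!is.na(tgt)) ses[tgt] else NA_real_
  zv <- est / se
  out$estimate <- unname(est)
  out$se <- unname(se)
  out$z <- unname(zv)
  out$p <- unname(2 * pnorm(-abs(zv)))
  out$chisq <- idx[["chisq"]]
  out$cfi <- idx[["cfi"]]
  out$rmsea <- idx[["rmsea"]]
  out$srmr <- srmr
  out$loglik <- ll_joint
  # parameters mapped back into the unconstrained layout (fixed -> 0)
  full <- spec_par_template(spec)
  common <- intersect(names(full), names(par))
  full[common] <- par[common]
  out$params <- full
  out
}

#' Fit the growth model at every voxel of a map stack
#'
#' Runs the conditional latent growth model independently at each in-mask
#' voxel: FIML fit, observed-information standard errors, the iterated
#' negative-variance boundary rule, saturated/baseline reference likelihoods
#' and fit indices. Output volumes are written in voxel order, so results
#' are independent of iteration order; with `n_starts = 1` the whole run is
#' deterministic given the data.
#'
#' @param stack a `"map_stack"` from [stack_maps()] or [as_map_stack()].
#' @param spec model specification; default a conditional linear growth
#'   model on the stack's covariate columns.
#' @param target label of the parameter whose estimate/SE/z/p volumes are
#'   reported (default the slope-on-MFQ path).
#' @param seed integer seed (start jitter when `n_starts > 1`).
#' @param n_starts optimizer starts per voxel (moment start first).
#' @param verbose print progress every few thousand voxels?
#' @return A `"stat_map_set"`: named 3D volumes (`estimate`, `se`, `z`,
#'   `p`, `chisq`, `cfi`, `rmsea`, `srmr`, `loglik`, `converged`,
#'   `constrained`, `inadmissible`), the per-voxel parameter matrix, grid
#'   metadata and a run report.
#' @export
fit_voxelwise <- function(stack, spec = NULL, target = "S~mfq_fof",
                          seed = 1, n_starts = 1, verbose = FALSE) {
  stopifnot(inherits(stack, "map_stack"))
  Tn <- dim(stack$data)[2]
  if (is.null(spec))
    spec <- build_lgm_spec(Tn, covariates = stack$covariate_cols)
  if (!target %in% spec$par_table$label[spec$par_table$free])
    abort(paste0("`target` parameter ", target, " is not free in the spec."))
  V <- dim(stack$data)[3]
  prep <- voxel_prep(stack, spec)
  spec_cache <- new.env(parent = emptyenv())
  stat_names <- c("estimate", "se", "z", "p", "chisq", "cfi", "rmsea",
                  "srmr", "loglik", "converged", "constrained",
                  "inadmissible")
  stats <- matrix(NA_real_, V, length(stat_names),
                  dimnames = list(NULL, stat_names))
  params <- matrix(NA_real_, V, spec$npar,
                   dimnames = list(NULL,
                                   spec$par_table$label[spec$par_table$free]))
  for (v in seq_len(V)) {
    y <- matrix(stack$data[, , v], prep$n, Tn)
    fv <- tryCatch(
      fit_voxel_core(y, prep, spec, spec_cache, target,
                     n_starts = n_starts, seed = seed + v),
      error = function(e) NULL)
    if (is.null(fv)) {
      stats[v, "converged"] <- 0
      next
    }
    stats[v, ] <- c(fv$estimate, fv$se, fv$z, fv$p, fv$chisq, fv$cfi,
                    fv$rmsea, fv$srmr, fv$loglik,
                    as.numeric(fv$converged), fv$constrained,
                    fv$inadmissible)
    params[v, ] <- fv$params
    if (verbose && v %% 2000 == 0)
      message("  voxel ", v, " / ", V)
  }
  volumes <- lapply(stat_names, function(nm) {
    vol <- array(NA_real_, stack$grid_dims)
    vol[stack$voxel_index] <- stats[, nm]
    vol
  })
  names(volumes) <- stat_names
  report <- list(
    n_voxels = V,
    n_converged = sum(stats[, "converged"] == 1, na.rm = TRUE),
    n_constrained = sum(stats[, "constrained"] == 1, na.rm = TRUE),
    n_inadmissible = sum(stats[, "inadmissible"] == 1, na.rm = TRUE),
    df = spec$df, seed = seed, target = target)
  structure(list(volumes = volumes, params = params,
                 voxel_index = stack$voxel_index,
                 grid_dims = stack$grid_dims, voxel_size = stack$voxel_size,
                 spec = spec, target = target, seed = seed,
                 report = report, stack = stack),
            class = "stat_map_set")
}

#' @export
print.stat_map_set <- function(x, ...) {
  r <- x$report
  cat("<stat_map_set> ", r$n_voxels, " voxels on a ",
      paste(x$grid_dims, collapse = "x"), " grid (",
      x$voxel_size, " mm)\n", sep = "")
  cat("target: ", x$target, "; converged: ", r$n_converged,
      "; constrained: ", r$n_constrained, "; inadmissible: ",
      r$n_inadmissible, "\n", sep = "")
  invisible(x)
}

#' Binary fit-quality mask from SEM fit indices
#'
#' 1 where the model fit is acceptable — RMSEA at or below `rmsea_max`, CFI
#' at or above `cfi_min`, SRMR at or below `srmr_max` (closed thresholds) —
#' and the voxel's model converged; 0 elsewhere.
#'
#' @param maps a `"stat_map_set"`.
#' @param rmsea_max,cfi_min,srmr_max fit-index thresholds.
#' @return A 3D 0/1 array.
#' @export
fit_quality_mask <- function(maps, rmsea_max = 0.10, cfi_min = 0.90,
                             srmr_max = 0.10) {
  need <- c("rmsea", "cfi", "srmr", "converged")
  miss <- setdiff(need, names(maps$volumes))
  if (length(miss) > 0)
    abort(paste0("Missing index volume(s): ", paste(miss, collapse = ", ")))
  v <- maps$volumes
  ok <- !is.na(v$rmsea) & !is.na(v$cfi) & !is.na(v$srmr) &
    v$converged == 1 &
    v$rmsea <= rmsea_max & v$cfi >= cfi_min & v$srmr <= srmr_max
  array(as.numeric(ok), maps$grid_dims)
}

#' Cluster-extent correction of a voxelwise p map
#'
#' Thresholds the p volume at `voxel_p` inside the fit-quality mask, labels
#' connected components under the chosen neighbourhood, and retains
#' components whose volume reaches `min_volume_mm3` (on a 2-mm isotropic
#' grid the default 240 mm3 means at least 30 voxels).
#'
#' @param p_volume 3D array of voxelwise p-values, or a `"stat_map_set"`
#'   (its `p` volume is used and, unless given, its quality mask).
#' @param quality_mask 3D 0/1 array; defaults to all-ones for a bare array
#'   input, or to [fit_quality_mask()] of the map set.
#' @param voxel_p voxelwise threshold (p strictly below it survives).
#' @param min_volume_mm3 minimum cluster extent in mm3.
#' @param voxel_size voxel edge length in mm (taken from the map set when
#'   available); an unknown voxel size is an error.
#' @param connectivity 6 (faces, default), 18 or 26.
#' @return A `"cluster_set"`: a `clusters` tibble (id, voxel count, volume,
#'   minimum p, peak-|estimate| voxel when available) with a `members`
#'   list-column of voxel-index matrices, plus the label volume.
#' @export
cluster_correct <- function(p_volume, quality_mask = NULL, voxel_p = 0.001,
                            min_volume_mm3 = 240, voxel_size = NULL,
                            connectivity = 6) {
  maps <- NULL
  if (inherits(p_volume, "stat_map_set")) {
    maps <- p_volume
    p_volume <- maps$volumes$p
    voxel_size <- voxel_size %||% maps$voxel_size
    if (is.null(quality_mask)) quality_mask <- fit_quality_mask(maps)
  }
  voxel_size <- voxel_size %||% attr(p_volume, "voxel_size")
  if (is.null(voxel_size))
    abort("Unknown voxel size; pass `voxel_size` explicitly.")
  if (!connectivity %in% c(6, 18, 26))
    abort("`connectivity` must be 6, 18 or 26.")
  dims <- dim(p_volume)
  if (is.null(quality_mask)) quality_mask <- array(1, dims)
  if (!all(dim(quality_mask) == dims))
    abort("`quality_mask` does not match the p volume.")
  bin <- !is.na(p_volume) & p_volume < voxel_p & quality_mask > 0
  lab <- cpp_label_components(array(as.integer(bin), dims),
                              as.integer(connectivity))
  lab <- array(as.integer(lab), dims)
  vox_vol <- voxel_size^3
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  rows <- list()
  keep_lab <- array(0L, dims)
  next_id <- 0L
  if (length(ids) > 0) {
    sizes <- tabulate(lab[lab > 0], nbins = max(ids))
    ord <- ids[order(-sizes[ids])]
    for (id in ord) {
      nvox <- sizes[id]
      if (nvox * vox_vol < min_volume_mm3) next
      next_id <- next_id + 1L
      members <- which(lab == id, arr.ind = TRUE)
      colnames(members) <- c("i", "j", "k")
      keep_lab[lab == id] <- next_id
      pmin_v <- min(p_volume[members], na.rm = TRUE)
      peak <- c(NA_integer_, NA_integer_, NA_integer_)
      peak_est <- NA_real_
      if (!is.null(maps)) {
        est <- maps$volumes$estimate[members]
        con <- maps$volumes$constrained[members]
        elig <- which(!is.na(est) & (is.na(con) | con == 0))
        if (length(elig) > 0) {
          b <- elig[which.max(abs(est[elig]))]
          peak <- members[b, ]
          peak_est <- est[b]
        }
      }
      rows[[next_id]] <- tibble(
        cluster_id = next_id, n_voxels = nvox,
        volume_mm3 = nvox * vox_vol, min_p = pmin_v,
        peak_i = peak[1], peak_j = peak[2], peak_k = peak[3],
        peak_estimate = peak_est,
        members = list(members))
    }
  }
  clusters <- if (length(rows) > 0) dplyr::bind_rows(rows) else
    tibble(cluster_id = integer(), n_voxels = integer(),
           volume_mm3 = numeric(), min_p = numeric(),
           peak_i = integer(), peak_j = integer(), peak_k = integer(),
           peak_estimate = numeric(), members = list())
  structure(list(clusters = clusters, labels = keep_lab,
                 voxel_p = voxel_p, min_volume_mm3 = min_volume_mm3,
                 voxel_size = voxel_size, connectivity = connectivity),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat("<cluster_set> ", nrow(x$clusters), " cluster(s) at p < ",
      x$voxel_p, ", >= ", x$min_volume_mm3, " mm3\n", sep = "")
  if (nrow(x$clusters) > 0)
    print(dplyr::select(x$clusters, -"members"))
  invisible(x)
}

#' Peak-voxel model of a cluster
#'
#' Among member voxels where no boundary constraint was applied, selects
#' the voxel with the largest absolute target estimate and (when the map
#' set retains its stack) refits the full conditional model and the
#' unconditional model there for reporting. If every member voxel was
#' constrained the cluster is reported without a peak model.
#'
#' @param cluster one row of a `"cluster_set"` clusters tibble (or the
#'   cluster_set plus `cluster_id`).
#' @param maps the `"stat_map_set"` the clusters came from.
#' @param cluster_id cluster to use when `cluster` is a cluster_set.
#' @param refit refit full + unconditional models at the peak voxel?
#' @return A list: `voxel` (i, j, k), `mm` coordinates, `estimate`, `p`,
#'   `fit` (peak-voxel `lgm_fit` or `NULL`), `unconditional`.
#' @export
select_peak <- function(cluster, maps, cluster_id = 1, refit = TRUE) {
  if (inherits(cluster, "cluster_set"))
    cluster <- cluster$clusters[cluster$clusters$cluster_id == cluster_id, ]
  members <- cluster$members[[1]]
  if (is.null(members) || nrow(members) == 0) abort("Cluster is empty.")
  est <- maps$volumes$estimate[members]
  con <- maps$volumes$constrained[members]
  elig <- which(!is.na(est) & (is.na(con) | con == 0))
  if (length(elig) == 0) {
    warn("Every member voxel required a boundary constraint; no peak model.")
    return(list(voxel = NULL, mm = NULL, estimate = NA_real_, p = NA_real_,
                fit = NULL, unconditional = NULL))
  }
  b <- elig[which.max(abs(est[elig]))]
  voxel <- as.integer(members[b, ])
  mm <- (voxel - 1) * maps$voxel_size
  lin <- voxel[1] + (voxel[2] - 1) * maps$grid_dims[1] +
    (voxel[3] - 1) * prod(maps$grid_dims[1:2])
  pv <- maps$volumes$p[voxel[1], voxel[2], voxel[3]]
  fit <- uncond <- NULL
  if (refit && !is.null(maps$stack)) {
    vpos <- match(lin, maps$stack$voxel_index)
    df <- voxel_data_frame(maps$stack, vpos)
    fit <- apply_heywood_rule(
      fit_sem_engine(df, maps$spec, seed = maps$seed))
    uspec <- build_lgm_spec(length(maps$stack$waves),
                            outcomes = maps$spec$outcomes)
    uncond <- apply_heywood_rule(
      fit_sem_engine(df, uspec, seed = maps$seed))
  }
  list(voxel = voxel, mm = mm, estimate = est[b], p = pv,
       fit = fit, unconditional = uncond)
}

# one voxel's data as a model-ready data frame
voxel_data_frame <- function(stack, vpos) {
  Tn <- dim(stack$data)[2]
  df <- as.data.frame(matrix(stack$data[, , vpos], ncol = Tn))
  names(df) <- paste0("y", seq_len(Tn))
  dplyr::bind_cols(stack$covariates[c(intersect(
    c("subject_id", "subject"), names(stack$covariates))[1],
    stack$covariate_cols)], df)
}

#' Unconditional slope-variance range across a cluster
#'
#' Refits the unconditional (no-covariate) growth model at every member
#' voxel of a cluster and reports the range of latent slope variances with
#' their p-values — the individual-differences context for a detected
#' covariate effect.
#'
#' @param maps a `"stat_map_set"` retaining its stack.
#' @param cluster a row of the clusters tibble (or cluster_set +
#'   `cluster_id`).
#' @param cluster_id used when `cluster` is a cluster_set.
#' @return A list: per-voxel tibble and `range` (min/max slope variance,
#'   min/max p).
#' @export
cluster_unconditional_range <- function(maps, cluster, cluster_id = 1) {
  if (inherits(cluster, "cluster_set"))
    cluster <- cluster$clusters[cluster$clusters$cluster_id == cluster_id, ]
  members <- cluster$members[[1]]
  uspec <- build_lgm_spec(length(maps$stack$waves),
                          outcomes = maps$spec$outcomes)
  rows <- lapply(seq_len(nrow(members)), function(r) {
    voxel <- members[r, ]
    lin <- voxel[1] + (voxel[2] - 1) * maps$grid_dims[1] +
      (voxel[3] - 1) * prod(maps$grid_dims[1:2])
    vpos <- match(lin, maps$stack$voxel_index)
    df <- voxel_data_frame(maps$stack, vpos)
    ft <- fit_sem_engine(df, uspec, seed = maps$seed, indices = FALSE)
    ev <- ft$estimates[ft$estimates$term == "S~~S", ]
    tibble(i = voxel[1], j = voxel[2], k = voxel[3],
           slope_var = ev$estimate, p = ev$p.value)
  })
  tab <- dplyr::bind_rows(rows)
  list(per_voxel = tab,
       range = tibble(slope_var_min = min(tab$slope_var),
                      slope_var_max = max(tab$slope_var),
                      p_min = min(tab$p), p_max = max(tab$p)))
}
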