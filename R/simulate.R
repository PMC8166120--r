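# Synthetic longitudinal cohorts with known ground truth: demographics and
# attrition, latent-growth outcome panels, spatially clustered voxel fields,
# and toy 4D time-series for the seed-connectivity stage.

#' Population parameters of a linear latent growth process
#'
#' Defines the data-generating truth for a Fisher-z connectivity (or
#' cognitive score) trajectory: latent intercept/slope means, covariate
#' paths onto intercept and slope, the latent disturbance covariance, and
#' per-wave residual variances. Defaults describe a plausible resting-state
#' connectivity outcome: baseline Fisher-z around 0.3, slight average
#' decline, intercept SD 0.2, slope variance of the order reported for
#' 18-month connectivity change, and measurement noise SD ~0.14.
#'
#' @param alpha_i,alpha_s latent intercept and slope means.
#' @param gamma_i_mfq,gamma_s_mfq paths from the subjective-decline score
#'   onto intercept and slope.
#' @param gamma_i_age,gamma_s_age paths from centred age onto intercept and
#'   slope.
#' @param psi_ii,psi_ss,psi_is latent disturbance (co)variances.
#' @param theta per-wave residual variances (all non-negative).
#' @return An object of class `"growth_truth"`.
#' @export
growth_truth <- function(alpha_i = 0.3, alpha_s = -0.01,
                         gamma_i_mfq = 0, gamma_s_mfq = 0,
                         gamma_i_age = 0, gamma_s_age = 0,
                         psi_ii = 0.04, psi_ss = 0.004, psi_is = 0,
                         theta = c(0.02, 0.02, 0.02)) {
  if (any(theta < 0)) abort("Residual variances `theta` must be >= 0.")
  if (psi_ii < 0 || psi_ss < 0)
    abort("Latent disturbance variances must be >= 0.")
  structure(list(alpha_i = alpha_i, alpha_s = alpha_s,
                 gamma_i_mfq = gamma_i_mfq, gamma_s_mfq = gamma_s_mfq,
                 gamma_i_age = gamma_i_age, gamma_s_age = gamma_s_age,
                 psi_ii = psi_ii, psi_ss = psi_ss, psi_is = psi_is,
                 theta = theta), class = "growth_truth")
}

truth_psi <- function(truth)
  matrix(c(truth$psi_ii, truth$psi_is, truth$psi_is, truth$psi_ss), 2, 2)

# truth expressed as the free-parameter vector of a conditional LGM spec
# (for parameter-recovery comparisons)
truth_params <- function(truth, spec) {
  tm <- spec_par_template(spec)
  covs <- spec$covariates
  vals <- c("I~1" = truth$alpha_i, "S~1" = truth$alpha_s,
            "I~~I" = truth$psi_ii, "S~~S" = truth$psi_ss,
            "I~~S" = truth$psi_is)
  if ("mfq_fof" %in% covs)
    vals <- c(vals, "I~mfq_fof" = truth$gamma_i_mfq,
              "S~mfq_fof" = truth$gamma_s_mfq)
  if ("age_c" %in% covs)
    vals <- c(vals, "I~age_c" = truth$gamma_i_age,
              "S~age_c" = truth$gamma_s_age)
  th <- setNames(truth$theta, paste0(spec$outcomes, "~~", spec$outcomes))
  vals <- c(vals, th)
  common <- intersect(names(tm), names(vals))
  tm[common] <- vals[common]
  tm
}

#' Define a spatially clustered slope effect for the voxel-field generator
#'
#' @param center voxel index (length-3 integer, 1-based) of the cluster
#'   centre.
#' @param gamma planted slope-on-MFQ path inside the cluster.
#' @param radius spherical radius in voxels; or
#' @param volume_mm3 target cluster volume, realized as the nearest
#'   `ceiling(volume / voxel volume)` voxels to the centre (ties broken
#'   lexicographically).
#' @return A list describing the cluster.
#' @export
effect_cluster <- function(center, gamma, radius = NULL, volume_mm3 = NULL) {
  if (is.null(radius) == is.null(volume_mm3))
    abort("Give exactly one of `radius` or `volume_mm3`.")
  list(center = as.integer(center), gamma = gamma, radius = radius,
       volume_mm3 = volume_mm3)
}

#' Configuration of a synthetic longitudinal cohort
#'
#' Defaults emulate the design of a three-wave aging cohort measured about
#' every 18 months: 69 subjects at baseline of whom about 49 enrol in
#' follow-up, thinning to expected wave counts of roughly 34 and 28;
#' subjective-decline scores on the 0-6 scale (mean 2.99, SD 0.91,
#' truncated); ages 50-85 (mean 68.33, SD 7.95, truncated); and optional
#' covariate-dependent dropout. Non-monotone attendance is allowed by
#' default; `monotone = TRUE` forces dropout to be permanent, in which case
#' the retention targets must be non-increasing.
#'
#' @param n_subjects baseline sample size.
#' @param n_longitudinal expected number enrolled in the longitudinal arm.
#' @param n_waves number of measurement occasions.
#' @param wave_spacing_months nominal spacing between waves.
#' @param loadings slope loadings (first must be 0).
#' @param mfq_mean,mfq_sd,mfq_bounds truncated-normal parameters of the
#'   subjective-decline score.
#' @param age_mean,age_sd,age_bounds truncated-normal parameters of baseline
#'   age.
#' @param covariate_correlation Gaussian-copula correlation between age and
#'   the decline score (0 = independent).
#' @param p_female,p_african_american demographic proportions (descriptive
#'   only).
#' @param truth a [growth_truth()] for the outcome process.
#' @param retention per-wave marginal retention targets among longitudinal
#'   enrollees (wave 1 must be 1).
#' @param dropout_logodds named vector `c(age = ..., mfq_fof = ...)` of
#'   log-odds of missingness per unit of the (mean-centred) covariate.
#' @param monotone logical; permanent dropout?
#' @param grid_dims,voxel_size analysis grid for voxel fields (2-mm
#'   isotropic 24^3 by default).
#' @param effect_clusters list of [effect_cluster()]s.
#' @param seed integer seed; all generator randomness flows from it.
#' @return An object of class `"simulation_config"`.
#' @export
simulation_config <- function(n_subjects = 69, n_longitudinal = 49,
                              n_waves = 3, wave_spacing_months = 18,
                              loadings = seq(0, n_waves - 1),
                              mfq_mean = 2.99, mfq_sd = 0.91,
                              mfq_bounds = c(0, 6),
                              age_mean = 68.33, age_sd = 7.95,
                              age_bounds = c(50, 85),
                              covariate_correlation = 0,
                              p_female = 56 / 69,
                              p_african_american = 54 / 69,
                              truth = growth_truth(),
                              retention = c(1, 34 / 49, 28 / 49),
                              dropout_logodds = c(age = 0, mfq_fof = 0),
                              monotone = FALSE,
                              grid_dims = c(24L, 24L, 24L), voxel_size = 2,
                              effect_clusters = list(), seed = 1L) {
  if (length(retention) != n_waves)
    abort("`retention` must have one target per wave.")
  if (retention[1] != 1) abort("Wave-1 retention must be 1.")
  if (any(retention <= 0 | retention > 1))
    abort("Retention targets must lie in (0, 1].")
  if (monotone && any(diff(retention) > 1e-12))
    abort("Infeasible retention targets: must be non-increasing under monotone dropout.")
  if (length(loadings) != n_waves || loadings[1] != 0)
    abort("`loadings` must have length `n_waves` with first loading 0.")
  if (length(truth$theta) != n_waves)
    abort("`truth$theta` must have one residual variance per wave.")
  for (cl in effect_clusters) {
    if (any(cl$center < 1) || any(cl$center > grid_dims))
      abort("Effect cluster centre lies outside the grid.")
  }
  structure(list(
    n_subjects = n_subjects, n_longitudinal = n_longitudinal,
    n_waves = n_waves, wave_spacing_months = wave_spacing_months,
    loadings = loadings,
    mfq_mean = mfq_mean, mfq_sd = mfq_sd, mfq_bounds = mfq_bounds,
    age_mean = age_mean, age_sd = age_sd, age_bounds = age_bounds,
    covariate_correlation = covariate_correlation,
    p_female = p_female, p_african_american = p_african_american,
    truth = truth, retention = retention,
    dropout_logodds = dropout_logodds, monotone = monotone,
    grid_dims = as.integer(grid_dims), voxel_size = voxel_size,
    effect_clusters = effect_clusters, seed = as.integer(seed)),
    class = "simulation_config")
}

# truncated normal via inverse-CDF (exact, vectorized)
rtnorm <- function(n, mean, sd, lower, upper, u = runif(n)) {
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(plo + u * (phi - plo), mean, sd)
}

#' Generate a synthetic cohort with attrition
#'
#' Draws demographics and per-wave attendance according to a
#' [simulation_config()]: truncated-normal age and subjective-decline
#' scores (optionally copula-correlated), a Bernoulli longitudinal-arm
#' indicator, and per-wave presence driven by the retention targets shifted
#' on the log-odds scale by the configured covariate coefficients (so with
#' zero coefficients the marginal retention matches the target).
#'
#' @param config a [simulation_config()].
#' @return A tibble, one row per subject: `subject_id`, `age`, `age_c`,
#'   `mfq_fof`, `sex`, `racial_identity`, `longitudinal`, and logical
#'   `present_1..present_T`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  rho <- config$covariate_correlation
  z1 <- rnorm(n); z2 <- rnorm(n)
  u_age <- pnorm(z1)
  u_mfq <- pnorm(rho * z1 + sqrt(1 - rho^2) * z2)
  age <- rtnorm(n, config$age_mean, config$age_sd,
                config$age_bounds[1], config$age_bounds[2], u = u_age)
  mfq <- rtnorm(n, config$mfq_mean, config$mfq_sd,
                config$mfq_bounds[1], config$mfq_bounds[2], u = u_mfq)
  sex <- ifelse(runif(n) < config$p_female, "female", "male")
  race <- ifelse(runif(n) < config$p_african_american,
                 "African American", "white")
  longitudinal <- runif(n) < config$n_longitudinal / config$n_subjects

  b <- config$dropout_logodds
  shift <- b[["age"]] * (age - config$age_mean) +
    b[["mfq_fof"]] * (mfq - config$mfq_mean)
  present <- matrix(FALSE, n, config$n_waves)
  present[, 1] <- TRUE
  for (w in seq_len(config$n_waves)[-1]) {
    r_marg <- if (config$monotone)
      config$retention[w] / config$retention[w - 1] else config$retention[w]
    p_miss <- plogis(qlogis(1 - r_marg) + shift)
    attend <- longitudinal & (runif(n) >= p_miss)
    present[, w] <- if (config$monotone) present[, w - 1] & attend else attend
  }
  out <- tibble(
    subject_id = sprintf("S%03d", seq_len(n)),
    age = age, age_c = center_age(age), mfq_fof = mfq,
    sex = sex, racial_identity = race, longitudinal = longitudinal)
  for (w in seq_len(config$n_waves))
    out[[paste0("present_", w)]] <- present[, w]
  out
}

present_matrix <- function(records) {
  cols <- sort(grep("^present_[0-9]+$", names(records), value = TRUE))
  as.matrix(records[cols])
}

# draw from N(0, Psi) allowing a singular (PSD) Psi
draw_mvn <- function(n, Psi) {
  ev <- eigen(Psi, symmetric = TRUE)
  if (any(ev$values < -1e-10 * max(abs(ev$values), 1)))
    abort('Latent disturbance matrix "Psi" is not positive semidefinite.')
  lam <- pmax(ev$values, 0)
  Z <- matrix(rnorm(n * length(lam)), n)
  Z %*% (t(ev$vectors) * sqrt(lam))
}

#' Simulate a longitudinal outcome panel from a growth truth
#'
#' Each subject's trajectory is
#' `y_it = (alpha_I + gamma_I x_i + zeta_Ii) + lambda_t (alpha_S +
#' gamma_S x_i + zeta_Si) + eps_it`, with covariates `x = (mfq_fof, age_c)`
#' taken from `records`; waves the subject did not attend are set missing.
#'
#' @param records a cohort tibble from [generate_cohort()] (needs
#'   `mfq_fof`, `age_c` and the `present_*` columns).
#' @param truth a [growth_truth()].
#' @param loadings slope loadings (default `0..T-1`; first must be 0).
#' @param seed integer seed.
#' @return A tibble: `subject_id`, `mfq_fof`, `age_c`, `y1..yT` (`NA` where
#'   absent).
#' @export
generate_growth_panel <- function(records, truth, loadings = NULL, seed = 1) {
  stopifnot(inherits(truth, "growth_truth"))
  pres <- present_matrix(records)
  Tn <- ncol(pres)
  loadings <- loadings %||% seq(0, Tn - 1)
  if (length(loadings) != Tn) abort("`loadings` must have one value per wave.")
  if (loadings[1] != 0) abort("The first slope loading must be 0.")
  set.seed(seed)
  n <- nrow(records)
  m <- records$mfq_fof; a <- records$age_c
  zeta <- draw_mvn(n, truth_psi(truth))
  mu_i <- truth$alpha_i + truth$gamma_i_mfq * m + truth$gamma_i_age * a +
    zeta[, 1]
  mu_s <- truth$alpha_s + truth$gamma_s_mfq * m + truth$gamma_s_age * a +
    zeta[, 2]
  Y <- matrix(NA_real_, n, Tn)
  for (t in seq_len(Tn)) {
    Y[, t] <- mu_i + loadings[t] * mu_s +
      rnorm(n, sd = sqrt(truth$theta[t]))
  }
  Y[!pres] <- NA_real_
  out <- tibble(subject_id = records$subject_id, mfq_fof = m, age_c = a)
  for (t in seq_len(Tn)) out[[paste0("y", t)]] <- Y[, t]
  out
}

#' Simulate per-wave connectivity maps with planted effect clusters
#'
#' Generates an independent growth panel at every voxel of the configured
#' grid. Voxels inside the configured effect clusters use the planted
#' slope-on-MFQ path; background voxels use a slope-on-MFQ path of 0 (other
#' truth parameters are shared). Voxel noise is independent across voxels;
#' the generator plants clustered signal, not spatially smooth noise.
#'
#' @param config a [simulation_config()] (grid, clusters, truth, seed).
#' @param records optional cohort tibble; generated from `config` when
#'   omitted.
#' @return An object of class `"voxel_field"`: `data` (subjects x waves x
#'   voxels array), `gamma_map` and logical `truth_mask` 3D arrays,
#'   `records`, grid metadata, and the generating truth.
#' @export
generate_voxel_field <- function(config, records = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(records)) records <- generate_cohort(config)
  dims <- config$grid_dims
  V <- prod(dims)
  gamma_map <- array(0, dims)
  planted <- array(FALSE, dims)
  for (cl in config$effect_clusters) {
    memb <- cluster_members(cl, dims, config$voxel_size)
    lin <- memb[, 1] + (memb[, 2] - 1) * dims[1] +
      (memb[, 3] - 1) * dims[1] * dims[2]
    clash <- planted[lin] & abs(gamma_map[lin] - cl$gamma) > 1e-12
    if (any(clash))
      abort("Overlapping effect clusters with conflicting gamma values.")
    gamma_map[lin] <- cl$gamma
    planted[lin] <- TRUE
  }
  truth <- config$truth
  pres <- present_matrix(records)
  n <- nrow(records); Tn <- config$n_waves
  lam <- config$loadings
  m <- records$mfq_fof; a <- records$age_c

  set.seed(config$seed + 1L)   # distinct stream from the cohort draw
  L <- chol_psd(truth_psi(truth))
  zi <- matrix(rnorm(n * V), n, V)
  zs <- matrix(rnorm(n * V), n, V)
  ZI <- L[1, 1] * zi
  ZS <- L[2, 1] * zi + L[2, 2] * zs
  bI <- truth$alpha_i + truth$gamma_i_mfq * m + truth$gamma_i_age * a
  bS <- truth$alpha_s + truth$gamma_s_mfq * m + truth$gamma_s_age * a
  gv <- as.vector(gamma_map)
  Imat <- bI + ZI                       # n x V
  Smat <- bS + outer(m, gv) + ZS        # n x V
  dat <- array(NA_real_, c(n, Tn, V))
  for (t in seq_len(Tn)) {
    noise <- matrix(rnorm(n * V, sd = sqrt(truth$theta[t])), n, V)
    page <- Imat + lam[t] * Smat + noise
    page[!pres[, t], ] <- NA_real_
    dat[, t, ] <- page
  }
  structure(list(data = dat, gamma_map = gamma_map,
                 truth_mask = planted, records = records,
                 grid_dims = dims, voxel_size = config$voxel_size,
                 loadings = lam, truth = truth, seed = config$seed),
            class = "voxel_field")
}

# lower-triangular factor of a PSD 2x2 (or general) matrix
chol_psd <- function(S) {
  ev <- eigen(S, symmetric = TRUE)
  if (any(ev$values < -1e-10 * max(abs(ev$values), 1)))
    abort('Latent disturbance matrix "Psi" is not positive semidefinite.')
  lam <- pmax(ev$values, 0)
  L <- ev$vectors %*% diag(sqrt(lam), length(lam))
  # not triangular in general; only the factor property L L' = S is used
  L
}

# voxels belonging to an effect cluster
cluster_members <- function(cl, dims, voxel_size) {
  cc <- cl$center
  if (!is.null(cl$radius)) {
    r <- cl$radius
    rng <- lapply(1:3, function(d)
      max(1, floor(cc[d] - r)):min(dims[d], ceiling(cc[d] + r)))
    g <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
    d2 <- (g[, 1] - cc[1])^2 + (g[, 2] - cc[2])^2 + (g[, 3] - cc[3])^2
    g[d2 <= r^2 + 1e-9, , drop = FALSE]
  } else {
    nvox <- ceiling(cl$volume_mm3 / voxel_size^3)
    r <- ceiling(nvox^(1 / 3)) + 2
    rng <- lapply(1:3, function(d)
      max(1, cc[d] - r):min(dims[d], cc[d] + r))
    g <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
    d2 <- (g[, 1] - cc[1])^2 + (g[, 2] - cc[2])^2 + (g[, 3] - cc[3])^2
    ord <- order(d2, g[, 1], g[, 2], g[, 3])
    g[ord[seq_len(min(nvox, nrow(g)))], , drop = FALSE]
  }
}

#' Simulate a 4D image whose target voxels correlate with an ROI mean
#'
#' A common standard-normal signal is placed in the ROI voxels; each target
#' voxel is `r * s + sqrt(1 - r^2) * e` so its population correlation with
#' the ROI mean equals `target_r`; all other voxels are independent noise.
#' A fixture generator for the seed-map stage, with no hemodynamic realism.
#'
#' @param grid_dims length-3 integer grid size.
#' @param roi_voxels integer matrix (rows = voxels, columns = i, j, k).
#' @param target_voxels integer matrix of voxels carrying the correlated
#'   signal (may be `NULL`).
#' @param target_r population correlation, `|target_r| < 1`.
#' @param n_volumes number of time points (>= 30).
#' @param seed integer seed.
#' @param voxel_size voxel edge length in mm (isotropic).
#' @return A 4D array with attributes `voxel_size` and `roi_voxels`.
#' @export
generate_timeseries <- function(grid_dims, roi_voxels, target_voxels = NULL,
                                target_r = 0, n_volumes = 100, seed = 1,
                                voxel_size = 2) {
  if (abs(target_r) >= 1) abort("`target_r` must satisfy |r| < 1.")
  if (n_volumes < 30) abort("`n_volumes` must be at least 30.")
  roi_voxels <- rbind(roi_voxels)
  set.seed(seed)
  arr <- array(rnorm(prod(grid_dims) * n_volumes),
               c(grid_dims, n_volumes))
  s <- rnorm(n_volumes)
  for (r in seq_len(nrow(roi_voxels)))
    arr[roi_voxels[r, 1], roi_voxels[r, 2], roi_voxels[r, 3], ] <- s
  if (!is.null(target_voxels)) {
    target_voxels <- rbind(target_voxels)
    for (r in seq_len(nrow(target_voxels))) {
      e <- rnorm(n_volumes)
      arr[target_voxels[r, 1], target_voxels[r, 2], target_voxels[r, 3], ] <-
        target_r * s + sqrt(1 - target_r^2) * e
    }
  }
  attr(arr, "voxel_size") <- voxel_size
  attr(arr, "roi_voxels") <- roi_voxels
  arr
}

#' Simulate coupled connectivity and cognition growth panels
#'
#' Generates two parallel growth processes over the same subjects and waves:
#' a connectivity process from `fc_truth` and a cognition process from
#' `cog_truth`, whose latent slope is additionally regressed on the
#' connectivity intercept and slope through `coupling`. Both observed panels
#' share the cohort's attendance pattern.
#'
#' @param records cohort tibble from [generate_cohort()].
#' @param fc_truth,cog_truth [growth_truth()] objects (cognition defaults on
#'   a proportion-score scale, baseline about .40 with SD .12).
#' @param coupling named vector `c(i_fc = ..., s_fc = ...)`: paths from the
#'   connectivity intercept and slope onto the cognition slope.
#' @param loadings shared slope loadings.
#' @param seed integer seed.
#' @return A tibble: `subject_id`, covariates, `fc1..fcT`, `cog1..cogT`.
#' @export
generate_parallel_panels <- function(records,
                                     fc_truth = growth_truth(),
                                     cog_truth = growth_truth(
                                       alpha_i = 0.40, alpha_s = 0.005,
                                       psi_ii = 0.010, psi_ss = 0.001,
                                       psi_is = 0,
                                       theta = c(0.004, 0.004, 0.004)),
                                     coupling = c(i_fc = 0, s_fc = 0),
                                     loadings = NULL, seed = 1) {
  pres <- present_matrix(records)
  Tn <- ncol(pres)
  loadings <- loadings %||% seq(0, Tn - 1)
  set.seed(seed)
  n <- nrow(records)
  m <- records$mfq_fof; a <- records$age_c
  zf <- draw_mvn(n, truth_psi(fc_truth))
  zc <- draw_mvn(n, truth_psi(cog_truth))
  I_f <- fc_truth$alpha_i + fc_truth$gamma_i_mfq * m +
    fc_truth$gamma_i_age * a + zf[, 1]
  S_f <- fc_truth$alpha_s + fc_truth$gamma_s_mfq * m +
    fc_truth$gamma_s_age * a + zf[, 2]
  I_c <- cog_truth$alpha_i + cog_truth$gamma_i_mfq * m +
    cog_truth$gamma_i_age * a + zc[, 1]
  S_c <- cog_truth$alpha_s + cog_truth$gamma_s_mfq * m +
    cog_truth$gamma_s_age * a +
    coupling[["i_fc"]] * I_f + coupling[["s_fc"]] * S_f + zc[, 2]
  out <- tibble(subject_id = records$subject_id, mfq_fof = m, age_c = a)
  for (t in seq_len(Tn)) {
    fc <- I_f + loadings[t] * S_f + rnorm(n, sd = sqrt(fc_truth$theta[t]))
    fc[!pres[, t]] <- NA_real_
    out[[paste0("fc", t)]] <- fc
  }
  for (t in seq_len(Tn)) {
    cg <- I_c + loadings[t] * S_c + rnorm(n, sd = sqrt(cog_truth$theta[t]))
    cg[!pres[, t]] <- NA_real_
    out[[paste0("cog", t)]] <- cg
  }
  out
}
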