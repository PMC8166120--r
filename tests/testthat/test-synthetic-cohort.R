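# synthetic cohort generator: attrition, covariate distributions,
# determinism, deterministic limits of the growth panel, voxel fields,
# time-series fixtures

test_that("no-dropout configuration keeps everyone at every wave", {
  cfg <- simulation_config(n_subjects = 40, n_longitudinal = 40,
                           retention = c(1, 1, 1), seed = 5)
  cohort <- generate_cohort(cfg)
  expect_true(all(cohort$present_1))
  expect_true(all(cohort$present_2))
  expect_true(all(cohort$present_3))
})

test_that("attrition marginals match the configured retention targets", {
  # Monte-Carlo over replicate cohorts against the Bernoulli targets:
  # wave-2 expectation = P(longitudinal) * retention_2
  reps <- 400
  n2 <- n3 <- nlong <- numeric(reps)
  for (r in seq_len(reps)) {
    cohort <- generate_cohort(simulation_config(seed = 10000 + r))
    n2[r] <- sum(cohort$present_2)
    n3[r] <- sum(cohort$present_3)
    nlong[r] <- sum(cohort$longitudinal)
  }
  p_long <- 49 / 69
  e2 <- 69 * p_long * (34 / 49)   # = 34 in expectation
  e3 <- 69 * p_long * (28 / 49)   # = 28
  se2 <- sd(n2) / sqrt(reps)
  se3 <- sd(n3) / sqrt(reps)
  expect_lt(abs(mean(n2) - e2), 4 * se2 + 0.01)
  expect_lt(abs(mean(n3) - e3), 4 * se3 + 0.01)
  expect_lt(abs(mean(nlong) - 49), 4 * sd(nlong) / sqrt(reps) + 0.01)
})

test_that("covariate distributions match the configured targets", {
  cohort <- generate_cohort(simulation_config(n_subjects = 40000, seed = 77))
  expect_true(all(cohort$mfq_fof >= 0 & cohort$mfq_fof <= 6))
  expect_true(all(cohort$age >= 50 & cohort$age <= 85))
  # truncation is mild, so mean/sd sit near the nominal values
  expect_equal(mean(cohort$mfq_fof), 2.99, tolerance = 0.02)
  expect_equal(mean(cohort$age), 68.33, tolerance = 0.15)
  expect_equal(sd(cohort$mfq_fof), 0.91, tolerance = 0.03)
})

test_that("zero dropout coefficients leave the audit odds ratio at 1", {
  # one large cohort, logistic audit of wave-3 missingness on age
  cfg <- simulation_config(n_subjects = 30000, n_longitudinal = 30000,
                           dropout_logodds = c(age = 0, mfq_fof = 0),
                           seed = 9)
  cohort <- generate_cohort(cfg)
  res <- audit_missingness(cohort$age, !cohort$present_3)
  expect_equal(res$odds_ratio, 1, tolerance = 0.01)
  # and a planted age effect is recovered
  cfg2 <- simulation_config(n_subjects = 30000, n_longitudinal = 30000,
                            dropout_logodds = c(age = 0.08, mfq_fof = 0),
                            seed = 9)
  cohort2 <- generate_cohort(cfg2)
  res2 <- audit_missingness(cohort2$age, !cohort2$present_3)
  expect_lt(abs(res2$estimate - 0.08), 0.008)
})

test_that("monotone mode enforces permanent dropout and validates targets", {
  cfg <- simulation_config(monotone = TRUE, seed = 3)
  cohort <- generate_cohort(cfg)
  expect_true(all(!cohort$present_2 | cohort$present_1))
  expect_true(all(!cohort$present_3 | cohort$present_2))
  expect_error(
    simulation_config(monotone = TRUE, retention = c(1, 0.5, 0.8)),
    "Infeasible retention")
})

test_that("growth panel reduces to the closed-form mean when noise is off", {
  cohort <- complete_cohort(12, seed = 4)
  truth <- growth_truth(alpha_i = 0.4, alpha_s = -0.03,
                        psi_ii = 0, psi_ss = 0, psi_is = 0,
                        theta = c(0, 0, 0))
  panel <- generate_growth_panel(cohort, truth, seed = 1)
  for (t in 1:3)
    expect_equal(panel[[paste0("y", t)]],
                 rep(0.4 - 0.03 * (t - 1), 12), tolerance = 1e-12)
})

test_that("growth panel is byte-identical under a fixed seed", {
  cohort <- complete_cohort(20, seed = 6)
  p1 <- generate_growth_panel(cohort, growth_truth(), seed = 11)
  p2 <- generate_growth_panel(cohort, growth_truth(), seed = 11)
  expect_identical(p1, p2)
  p3 <- generate_growth_panel(cohort, growth_truth(), seed = 12)
  expect_false(identical(p1, p3))
})

test_that("large panels recover the planted slope-on-MFQ path by moments", {
  cohort <- complete_cohort(5000, seed = 8)
  truth <- growth_truth(gamma_s_mfq = -0.05)
  panel <- generate_growth_panel(cohort, truth, seed = 9)
  # per-subject OLS slope over loadings 0,1,2, regressed on the score
  Y <- as.matrix(panel[c("y1", "y2", "y3")])
  lam <- 0:2
  slope <- drop((Y %*% (lam - mean(lam))) / sum((lam - mean(lam))^2))
  mom <- coef(lm(slope ~ panel$mfq_fof))[2]
  expect_lt(abs(unname(mom) + 0.05), 0.0075)
})

test_that("empirical moments match the model-implied moments", {
  cohort <- complete_cohort(200000, seed = 13)
  truth <- fixture_truth()
  panel <- generate_growth_panel(cohort, truth, seed = 14)
  spec <- default_spec()
  X <- as.matrix(panel[c("mfq_fof", "age_c")])
  imp <- implied_moments(spec, truth_params_for_test(truth, spec),
                         x_mean = colMeans(X), x_cov = cov(X))
  Y <- as.matrix(panel[c("y1", "y2", "y3")])
  n <- nrow(Y)
  # means and covariances within ~3 Monte-Carlo standard errors
  for (t in 1:3) {
    se <- sd(Y[, t]) / sqrt(n)
    expect_lt(abs(mean(Y[, t]) - imp$mean[t]), 4 * se)
  }
  emp_cov <- cov(Y)
  for (s in 1:3) for (t in s:3) {
    mc_se <- sd(Y[, s] * Y[, t]) / sqrt(n)   # crude but adequate bound
    expect_lt(abs(emp_cov[s, t] - imp$cov[s, t]), 4 * mc_se + 1e-4)
  }
})

test_that("non-PSD latent disturbance matrices are rejected by name", {
  cohort <- complete_cohort(10, seed = 2)
  bad <- growth_truth(psi_ii = 0.01, psi_ss = 0.01)
  bad$psi_is <- 0.05   # |cov| > sqrt(var*var)
  expect_error(generate_growth_panel(cohort, bad, seed = 1),
               "Psi.*not positive semidefinite")
})

test_that("voxel fields plant clusters exactly where configured", {
  # no clusters -> empty truth mask
  cfg0 <- simulation_config(grid_dims = c(8, 8, 8), seed = 5)
  f0 <- generate_voxel_field(cfg0)
  expect_equal(sum(f0$truth_mask), 0)
  # two disjoint clusters -> exactly 2 connected components
  cfg2 <- simulation_config(
    grid_dims = c(12, 12, 12),
    effect_clusters = list(
      effect_cluster(c(3, 3, 3), gamma = -0.2, radius = 1.5),
      effect_cluster(c(9, 9, 9), gamma = 0.2, radius = 1.5)),
    seed = 5)
  f2 <- generate_voxel_field(cfg2)
  lab <- fcgrowth:::cpp_label_components(
    array(as.integer(f2$truth_mask), dim(f2$truth_mask)), 6L)
  expect_equal(max(lab), 2)
  # overlapping clusters with conflicting effects are an error
  cfg_bad <- simulation_config(
    grid_dims = c(8, 8, 8),
    effect_clusters = list(
      effect_cluster(c(4, 4, 4), gamma = -0.2, radius = 2),
      effect_cluster(c(5, 4, 4), gamma = 0.3, radius = 2)),
    seed = 5)
  expect_error(generate_voxel_field(cfg_bad), "conflicting")
  # a volume-targeted cluster realises ceiling(volume / voxel^3) voxels
  cfgv <- simulation_config(
    grid_dims = c(12, 12, 12),
    effect_clusters = list(effect_cluster(c(6, 6, 6), gamma = -0.1,
                                          volume_mm3 = 300)),
    seed = 5)
  fv <- generate_voxel_field(cfgv)
  expect_equal(sum(fv$truth_mask), ceiling(300 / 8))
})

test_that("time-series fixtures hit the target correlation", {
  dims <- c(5, 5, 5)
  roi <- rbind(c(2, 2, 2), c(3, 2, 2))
  tgt <- rbind(c(4, 4, 4))
  arr <- generate_timeseries(dims, roi, tgt, target_r = 0.6,
                             n_volumes = 5000, seed = 3)
  ref <- colMeans(rbind(arr[2, 2, 2, ], arr[3, 2, 2, ]))
  r <- cor(ref, arr[4, 4, 4, ])
  expect_equal(r, 0.6, tolerance = 0.03)   # 1/sqrt(n-3) sampling bound
  # null voxel uncorrelated
  r0 <- cor(ref, arr[1, 5, 1, ])
  expect_lt(abs(r0), 0.05)
  # reproducible under the seed
  arr2 <- generate_timeseries(dims, roi, tgt, target_r = 0.6,
                              n_volumes = 5000, seed = 3)
  expect_identical(arr, arr2)
  expect_error(generate_timeseries(dims, roi, tgt, target_r = 1,
                                   n_volumes = 100), "\\|r\\| < 1")
  expect_error(generate_timeseries(dims, roi, tgt, target_r = 0.2,
                                   n_volumes = 10), "at least 30")
})
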