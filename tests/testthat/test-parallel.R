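# parallel-process models: separability, identification, recovery,
# indirect effects

test_that("parallel spec identification follows from moment counting", {
  spec <- build_parallel_spec(3, 3, covariates = c("mfq_fof", "age_c"))
  # 8 observed variables: 44 moments; structural: 4 means + 8 covariate
  # paths + 2 cross paths + 6 psi + 6 theta = 26, plus 5 covariate moments
  expect_equal(spec$moments, 44)
  expect_equal(spec$npar, 26)
  expect_equal(spec$df, 44 - 26 - 5)
  # fixing the cognition slope disturbance adds one df
  spec2 <- build_parallel_spec(3, 3, covariates = c("mfq_fof", "age_c"),
                               constraints = "S_cog~~S_cog")
  expect_equal(spec2$npar, spec$npar - 1)
  expect_equal(spec2$df, spec$df + 1)
})

test_that("with zero cross paths the joint model separates into two LGMs", {
  cohort <- complete_cohort(150, seed = 81)
  pp <- generate_parallel_panels(cohort, coupling = c(i_fc = 0, s_fc = 0),
                                 seed = 82)
  spec0 <- build_parallel_spec(3, 3, covariates = c("mfq_fof", "age_c"),
                               constraints = c("S_cog~I_fc" = 0,
                                               "S_cog~S_fc" = 0))
  joint <- fit_parallel(pp, spec = spec0, heywood = FALSE)
  fc_spec <- build_lgm_spec(3, covariates = c("mfq_fof", "age_c"),
                            outcomes = c("fc1", "fc2", "fc3"))
  cog_spec <- build_lgm_spec(3, covariates = c("mfq_fof", "age_c"),
                             outcomes = c("cog1", "cog2", "cog3"))
  f_fc <- fcgrowth:::fit_sem_engine(pp, fc_spec, indices = FALSE)
  f_cog <- fcgrowth:::fit_sem_engine(pp, cog_spec, indices = FALSE)
  # conditional log-likelihoods add; the shared covariate block is counted
  # once in each marginal fit
  llx <- fcgrowth:::xblock_loglik(as.matrix(pp[c("mfq_fof", "age_c")]))
  expect_equal(joint$logLik,
               f_fc$logLik + f_cog$logLik - llx, tolerance = 1e-4)
})

test_that("cross-process coupling is recovered from rich data", {
  cohort <- complete_cohort(2000, seed = 83)
  pp <- generate_parallel_panels(
    cohort,
    fc_truth = growth_truth(gamma_s_mfq = -0.05, psi_ss = 0.01,
                            theta = c(0.01, 0.01, 0.01)),
    coupling = c(i_fc = 0, s_fc = 0.4), seed = 84)
  fit <- fit_parallel(pp, heywood = FALSE)
  expect_true(fit$converged)
  est <- fit$estimates
  b <- est[est$term == "S_cog~S_fc", ]
  expect_lt(abs(b$estimate - 0.4), 4 * b$std.error)
  b0 <- est[est$term == "S_cog~I_fc", ]
  expect_lt(abs(b0$estimate), 4 * b0$std.error)
})

test_that("indirect effects multiply exactly and carry delta-method SEs", {
  cohort <- complete_cohort(800, seed = 85)
  pp <- generate_parallel_panels(
    cohort,
    fc_truth = growth_truth(gamma_s_mfq = -0.08, psi_ss = 0.01,
                            theta = c(0.01, 0.01, 0.01)),
    coupling = c(i_fc = 0, s_fc = 0.5), seed = 86)
  fit <- fit_parallel(pp, heywood = FALSE)
  ie <- indirect_effect(fit, "mfq_fof", "S_fc", "S_cog")
  a <- fit$params["S_fc~mfq_fof"]
  b <- fit$params["S_cog~S_fc"]
  expect_equal(ie$estimate, unname(a * b), tolerance = 1e-12)
  free <- fit$spec$par_table$label[fit$spec$par_table$free]
  ia <- match("S_fc~mfq_fof", free); ib <- match("S_cog~S_fc", free)
  se_ref <- sqrt(b^2 * fit$vcov[ia, ia] + a^2 * fit$vcov[ib, ib] +
                   2 * a * b * fit$vcov[ia, ib])
  expect_equal(ie$std.error, unname(se_ref), tolerance = 1e-12)
  # constrained component paths are refused by name
  spec_c <- build_parallel_spec(3, 3, covariates = c("mfq_fof", "age_c"),
                                constraints = c("S_cog~S_fc" = 0))
  fit_c <- fit_parallel(pp, spec = spec_c, heywood = FALSE)
  expect_error(indirect_effect(fit_c, "mfq_fof", "S_fc", "S_cog"),
               "constrained")
})

test_that("indirect power grows with sample size in a mediation scenario", {
  zs <- vapply(c(100, 500, 2000), function(n) {
    cohort <- complete_cohort(n, seed = 87)
    pp <- generate_parallel_panels(
      cohort,
      fc_truth = growth_truth(gamma_s_mfq = -0.08, psi_ss = 0.01,
                              theta = c(0.01, 0.01, 0.01)),
      coupling = c(i_fc = 0, s_fc = 0.5), seed = 88)
    fit <- fit_parallel(pp, heywood = FALSE)
    abs(indirect_effect(fit, "mfq_fof", "S_fc", "S_cog")$statistic)
  }, numeric(1))
  expect_true(all(diff(zs) > 0))
})

test_that("delta-method indirect SE tracks the Monte-Carlo spread", {
  fc_truth <- growth_truth(gamma_s_mfq = -0.08, psi_ss = 0.01,
                           theta = c(0.01, 0.01, 0.01))
  nrep <- 2000
  est <- se <- rep(NA_real_, nrep)
  spec <- build_parallel_spec(3, 3, covariates = c("mfq_fof", "age_c"))
  for (r in seq_len(nrep)) {
    cohort <- complete_cohort(400, seed = 7000 + r)
    pp <- generate_parallel_panels(cohort, fc_truth = fc_truth,
                                   coupling = c(i_fc = 0, s_fc = 0.5),
                                   seed = 7500 + r)
    ft <- tryCatch(
      fcgrowth:::fit_sem_engine(pp, spec, n_starts = 1, indices = FALSE),
      error = function(e) NULL)
    if (is.null(ft) || !ft$converged || is.null(ft$vcov)) next
    ie <- indirect_effect(ft, "mfq_fof", "S_fc", "S_cog")
    est[r] <- ie$estimate
    se[r] <- ie$std.error
  }
  expect_gt(mean(!is.na(est)), 0.95)
  mc_sd <- sd(est, na.rm = TRUE)
  # mean reported delta SE within 10% of the Monte-Carlo SD
  expect_lt(abs(mean(se, na.rm = TRUE) - mc_sd) / mc_sd, 0.10)
  # the product estimator carries an O(1/n) bias of Cov(a_hat, b_hat); at
  # n = 400 that bias must be an order smaller than the sampling SD
  expect_lt(abs(mean(est, na.rm = TRUE) - (-0.04)), 0.3 * mc_sd)
})

test_that("cognitive growth models apply the slope-disturbance boundary rule", {
  # true zero slope disturbance at n = 69: the rule should fire often
  cog_truth <- growth_truth(alpha_i = 0.4, alpha_s = 0.005,
                            psi_ii = 0.01, psi_ss = 0, psi_is = 0,
                            theta = c(0.004, 0.004, 0.004))
  fired <- 0
  for (r in 1:12) {
    cohort <- generate_cohort(simulation_config(n_subjects = 69,
                                                seed = 900 + r))
    pp <- generate_parallel_panels(cohort, cog_truth = cog_truth,
                                   seed = 950 + r)
    cogdat <- pp[c("subject_id", "mfq_fof", "age_c", "cog1", "cog2", "cog3")]
    fit <- fit_cognitive_lgm(cogdat)
    if ("S~~S" %in% fit$constrained) {
      fired <- fired + 1
      # fixing the disturbance adds a degree of freedom
      expect_equal(fit$fit$df, 4)
    }
  }
  expect_gt(fired, 3)
})
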