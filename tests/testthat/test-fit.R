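# model fitting: recovery, invariances, fit indices, the boundary rule,
# standardization

test_that("parameters are recovered from a rich complete panel", {
  truth <- fixture_truth()
  cohort <- complete_cohort(2000, seed = 41)
  panel <- generate_growth_panel(cohort, truth, seed = 42)
  spec <- default_spec()
  fit <- fit_lgm(panel, spec)
  expect_true(fit$converged)
  tp <- truth_params_for_test(truth, spec)
  est <- fit$params[names(tp)]
  se <- fit$estimates$std.error[match(names(tp), fit$estimates$term)]
  expect_true(all(abs(est - tp) < 4 * se))
})

test_that("rescaling slope loadings is a pure reparameterization", {
  truth <- fixture_truth()
  cohort <- generate_cohort(simulation_config(n_subjects = 69, seed = 43))
  panel <- generate_growth_panel(cohort, truth, seed = 44)
  s1 <- build_lgm_spec(3, covariates = c("mfq_fof", "age_c"))
  s2 <- build_lgm_spec(3, loadings = c(0, 18, 36),
                       covariates = c("mfq_fof", "age_c"))
  f1 <- fit_lgm(panel, s1)
  f2 <- fit_lgm(panel, s2)
  expect_equal(f1$logLik, f2$logLik, tolerance = 1e-6)
  expect_equal(f1$fit$chisq, f2$fit$chisq, tolerance = 1e-4)
  expect_equal(f1$fit$cfi, f2$fit$cfi, tolerance = 1e-6)
  expect_equal(f1$fit$rmsea, f2$fit$rmsea, tolerance = 1e-6)
  expect_equal(f1$fit$srmr, f2$fit$srmr, tolerance = 1e-4)
  # slope-scale parameters rescale by 1/18 (variance by 1/18^2)
  expect_equal(f2$params["S~mfq_fof"] * 18, f1$params["S~mfq_fof"],
               tolerance = 1e-5, ignore_attr = TRUE)
  expect_equal(f2$params["S~1"] * 18, f1$params["S~1"],
               tolerance = 1e-5, ignore_attr = TRUE)
  expect_equal(f2$params["S~~S"] * 18^2, f1$params["S~~S"],
               tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("a saturated specification fits perfectly: chi2 = 0, df = 0", {
  # 2 outcomes, identity loadings, full Psi, zero residuals: 5 params =
  # 5 moments
  spec <- sem_spec(diag(2), outcomes = c("y1", "y2"),
                   latents = c("e1", "e2"),
                   constraints = c("y1~~y1" = 0, "y2~~y2" = 0))
  set.seed(45)
  dat <- data.frame(y1 = rnorm(40), y2 = rnorm(40))
  fit <- fcgrowth:::fit_sem_engine(dat, spec)
  expect_equal(spec$df, 0)
  expect_equal(fit$fit$chisq, 0, tolerance = 1e-5)
  expect_equal(fit$fit$cfi, 1)
  expect_equal(fit$fit$rmsea, 0)
  expect_equal(fit$fit$srmr, 0, tolerance = 1e-4)
})

test_that("fit indices implement the documented boundary behaviour", {
  # chi2 below df forces RMSEA to 0
  idx <- fit_indices(logL_model = -100.5, df_model = 3, logL_sat = -100,
                     logL_baseline = -150, df_baseline = 10, n = 69)
  expect_equal(idx$chisq, 1, tolerance = 1e-12)
  expect_equal(idx$rmsea, 0)
  expect_equal(idx$cfi, 1)
  # chi2 above df gives the standard formula
  idx2 <- fit_indices(logL_model = -110, df_model = 3, logL_sat = -100,
                      logL_baseline = -150, df_baseline = 10, n = 69)
  expect_equal(idx2$chisq, 20)
  expect_equal(idx2$rmsea, sqrt((20 - 3) / (3 * 69)))
  expect_lt(idx2$cfi, 1)
  expect_true(idx2$rmsea.upper >= idx2$rmsea.lower)
  # RMSEA CI endpoints solve the noncentral chi-square equations
  lo_ncp <- 3 * 69 * idx2$rmsea.lower^2
  hi_ncp <- 3 * 69 * idx2$rmsea.upper^2
  expect_equal(pchisq(20, 3, ncp = lo_ncp), 0.975, tolerance = 1e-4)
  expect_equal(pchisq(20, 3, ncp = hi_ncp), 0.025, tolerance = 1e-4)
})

test_that("the boundary rule fixes CI-covering negative variances to 0", {
  # simulate with a true zero wave-2 residual at modest n so negative
  # estimates occur; the rule must fire and never raise the log-likelihood
  truth <- growth_truth(psi_ii = 0.05, psi_ss = 0.01, psi_is = 0,
                        theta = c(0.02, 0, 0.02))
  fired <- 0; n_ok <- 0
  for (r in 1:20) {
    cohort <- complete_cohort(60, seed = 500 + r)
    panel <- generate_growth_panel(cohort, truth, seed = 600 + r)
    fit <- fit_lgm(panel, build_lgm_spec(3))
    if (!fit$converged) next
    n_ok <- n_ok + 1
    hw <- apply_heywood_rule(fit)
    if (length(hw$constrained) > 0) {
      fired <- fired + 1
      # constrained refit can never beat the unconstrained optimum
      expect_lte(hw$logLik, fit$logLik + 1e-6)
      expect_true(all(hw$params[hw$constrained] == 0 |
                        is.na(match(hw$constrained,
                                    names(hw$params)))))
    } else {
      expect_identical(hw$params, fit$params)
    }
  }
  expect_gt(fired, 2)   # the rule fires on a nontrivial fraction
})

test_that("clean fits pass through the boundary rule unchanged", {
  panel <- read_fixture69()
  fit <- fit_lgm(panel, default_spec())
  hw <- apply_heywood_rule(fit)
  expect_equal(length(hw$constrained), 0)
  expect_identical(hw$params, fit$params)
})

test_that("standardization uses model-implied variances", {
  truth <- fixture_truth()
  cohort <- complete_cohort(3000, seed = 46)
  panel <- generate_growth_panel(cohort, truth, seed = 47)
  fit <- fit_lgm(panel, default_spec())
  std <- standardize(fit)
  # check S~mfq_fof against a hand computation
  X <- as.matrix(panel[c("mfq_fof", "age_c")])
  S_x <- cov(X) * (nrow(X) - 1) / nrow(X)
  g <- fit$params
  var_S <- g["S~mfq_fof"]^2 * S_x[1, 1] + g["S~age_c"]^2 * S_x[2, 2] +
    2 * g["S~mfq_fof"] * g["S~age_c"] * S_x[1, 2] + g["S~~S"]
  expect_equal(std$std.estimate[std$term == "S~mfq_fof"],
               unname(g["S~mfq_fof"] * sqrt(S_x[1, 1]) / sqrt(var_S)),
               tolerance = 1e-8)
  # latent covariance standardizes to a correlation in [-1, 1]
  expect_lte(abs(std$std.estimate[std$term == "I~~S"]), 1)
})

test_that("likelihood never increases when constraints are added", {
  panel <- read_fixture69()
  f_free <- fit_lgm(panel, default_spec())
  for (cons in list("S~~S", "y2~~y2", c("S~~S", "y1~~y1"))) {
    f_c <- fit_lgm(panel, build_lgm_spec(3,
                                         covariates = c("mfq_fof", "age_c"),
                                         constraints = cons))
    expect_lte(f_c$logLik, f_free$logLik + 1e-6)
  }
})

test_that("tidy and glance expose the estimates and fit block", {
  panel <- read_fixture69()
  fit <- fit_lgm(panel, default_spec())
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "std.error", "statistic",
                    "p.value", "std.estimate") %in% names(td)))
  expect_equal(nrow(td), 12)
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(gl$converged)
  expect_true(all(c("chisq", "cfi", "rmsea", "srmr", "logLik") %in%
                    names(gl)))
})
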