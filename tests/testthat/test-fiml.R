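# FIML likelihood: complete-data reductions, marginalization over missing
# waves, saturated and baseline reference models

library(dplyr)

# plain-R multivariate normal log-density, the independent reference used
# throughout this file
dmvn_log <- function(x, mu, S) {
  k <- length(mu)
  ld <- determinant(S, logarithm = TRUE)$modulus
  -0.5 * (k * log(2 * pi) + as.numeric(ld) +
            drop(t(x - mu) %*% solve(S) %*% (x - mu)))
}

test_that("complete-data FIML equals the joint multivariate normal density", {
  truth <- fixture_truth()
  cohort <- complete_cohort(50, seed = 21)
  panel <- generate_growth_panel(cohort, truth, seed = 22)
  spec <- default_spec()
  params <- truth_params_for_test(truth, spec)
  X <- as.matrix(panel[c("mfq_fof", "age_c")])
  imp <- implied_moments(spec, params, x_mean = colMeans(X),
                         x_cov = cov(X) * (nrow(X) - 1) / nrow(X))
  Z <- cbind(as.matrix(panel[c("y1", "y2", "y3")]), X)
  ll_ref <- sum(vapply(seq_len(nrow(Z)), function(i)
    dmvn_log(Z[i, ], imp$mean, imp$cov), numeric(1)))
  expect_equal(fiml_loglik(panel, spec, params), ll_ref, tolerance = 1e-8)
})

test_that("a subject observed at one wave contributes a marginal density", {
  truth <- fixture_truth()
  cohort <- complete_cohort(8, seed = 23)
  panel <- generate_growth_panel(cohort, truth, seed = 24)
  spec <- default_spec()
  params <- truth_params_for_test(truth, spec)
  X <- as.matrix(panel[c("mfq_fof", "age_c")])
  mu_x <- colMeans(X); S_x <- cov(X) * (nrow(X) - 1) / nrow(X)
  imp <- implied_moments(spec, params, x_mean = mu_x, x_cov = S_x)
  panel2 <- panel
  panel2$y2[1] <- NA; panel2$y3[1] <- NA   # subject 1: wave 1 only
  ll_full <- fiml_loglik(panel, spec, params)
  ll_miss <- fiml_loglik(panel2, spec, params)
  # difference = joint density of subject 1 minus its (y1, x) marginal
  z1 <- c(as.numeric(panel[1, c("y1", "y2", "y3")]), X[1, ])
  keep <- c(1, 4, 5)
  d_ref <- dmvn_log(z1, imp$mean, imp$cov) -
    dmvn_log(z1[keep], imp$mean[keep], imp$cov[keep, keep])
  expect_equal(ll_full - ll_miss, d_ref, tolerance = 1e-8)
})

test_that("saturated FIML: closed form when complete, EM = direct when not", {
  truth <- fixture_truth()
  cohort <- complete_cohort(60, seed = 25)
  panel <- generate_growth_panel(cohort, truth, seed = 26)
  vars <- c("y1", "y2", "y3", "mfq_fof", "age_c")
  sat <- saturated_loglik(panel, vars)
  Z <- as.matrix(panel[vars])
  mu <- colMeans(Z); S <- cov(Z) * (nrow(Z) - 1) / nrow(Z)
  ll_ref <- sum(vapply(seq_len(nrow(Z)), function(i)
    dmvn_log(Z[i, ], mu, S), numeric(1)))
  expect_equal(sat$loglik, ll_ref, tolerance = 1e-6)
  # with missingness: EM and direct maximization find the same optimum
  panel$y2[1:20] <- NA; panel$y3[10:30] <- NA
  s_em <- saturated_loglik(panel, vars, method = "em")
  s_dir <- saturated_loglik(panel, vars, method = "direct")
  expect_equal(s_em$loglik, s_dir$loglik, tolerance = 1e-5)
  expect_gt(s_em$loglik, fiml_loglik(panel, default_spec(),
                                     truth_params_for_test(truth,
                                                           default_spec())))
})

test_that("saturated model rejects unusable inputs", {
  truth <- fixture_truth()
  panel <- generate_growth_panel(complete_cohort(30, seed = 27), truth,
                                 seed = 28)
  panel$y2 <- NA_real_
  expect_error(saturated_loglik(panel, c("y1", "y2", "y3")),
               "entirely missing")
  small <- generate_growth_panel(complete_cohort(4, seed = 1), truth,
                                 seed = 2)
  expect_error(saturated_loglik(small, c("y1", "y2", "y3", "mfq_fof",
                                         "age_c")), "Too few subjects")
})

test_that("pattern grouping rejects incomplete covariates", {
  panel <- generate_growth_panel(complete_cohort(20, seed = 3),
                                 fixture_truth(), seed = 4)
  panel$mfq_fof[3] <- NA
  expect_error(fit_lgm(panel, default_spec()), "complete")
})

test_that("compiled analytic gradient matches numerical differentiation", {
  truth <- fixture_truth()
  cohort <- generate_cohort(simulation_config(n_subjects = 69, seed = 29))
  panel <- generate_growth_panel(cohort, truth, seed = 30)
  spec <- default_spec()
  ps <- fcgrowth:::pattern_split(panel, spec$outcomes, spec$covariates)
  par0 <- truth_params_for_test(truth, spec) * 1.13 + 0.01
  g_a <- fcgrowth:::cpp_sem_grad(par0, spec$model, ps$patterns)
  h <- 1e-6
  for (j in seq_along(par0)) {
    pp <- par0; pm <- par0
    pp[j] <- pp[j] + h; pm[j] <- pm[j] - h
    g_n <- (fcgrowth:::cpp_sem_loglik(pp, spec$model, ps$patterns) -
              fcgrowth:::cpp_sem_loglik(pm, spec$model, ps$patterns)) / (2 * h)
    expect_equal(g_a[j], g_n, tolerance = 1e-4)
  }
})
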