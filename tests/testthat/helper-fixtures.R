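# shared fixtures: generating truths and configurations used across tests

# well-conditioned truth whose MLE stays interior at n = 69 (used for the
# packaged fixture and oracle comparisons)
fixture_truth <- function() {
  growth_truth(gamma_s_mfq = -0.06, gamma_i_mfq = 0.04,
               gamma_i_age = -0.004, gamma_s_age = 0.001,
               psi_ii = 0.05, psi_ss = 0.012, psi_is = 0.005,
               theta = c(0.01, 0.01, 0.01))
}

# the packaged 69-subject synthetic cohort (69/34/25 attendance), generated
# by generate_cohort(simulation_config(seed = 2, truth = fixture_truth()))
# + generate_growth_panel(seed = 102) and frozen as TSV
read_fixture69 <- function() {
  path <- system.file("extdata", "synthetic_cohort69.tsv",
                      package = "fcgrowth")
  readr::read_tsv(path, show_col_types = FALSE)
}

default_spec <- function() build_lgm_spec(3, covariates = c("mfq_fof", "age_c"))

# quick complete-data cohort (no attrition) for estimation tests
complete_cohort <- function(n, seed = 1) {
  generate_cohort(simulation_config(
    n_subjects = n, n_longitudinal = n, retention = c(1, 1, 1),
    seed = seed))
}

# named all-zero parameter vector for a spec
spec_zero_params <- function(spec)
  stats::setNames(numeric(spec$npar),
                  spec$par_table$label[spec$par_table$free])

# the generating truth expressed in the free-parameter layout of a spec
truth_params_for_test <- function(truth, spec)
  fcgrowth:::truth_params(truth, spec)

# long-format conversion for nlme-based oracles
panel_to_long <- function(panel) {
  long <- tidyr::pivot_longer(panel, dplyr::all_of(c("y1", "y2", "y3")),
                              names_to = "wave", values_to = "y")
  long$time <- as.numeric(sub("y", "", long$wave)) - 1
  long[!is.na(long$y), ]
}
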