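# Parallel-process growth models: a connectivity growth process and a
# cognition growth process over the same subjects, with the cognition slope
# regressed on the connectivity intercept and slope, all latent factors
# regressed on the covariates, and delta-method indirect effects.

#' Build a parallel-process growth model specification
#'
#' Two linear growth blocks — connectivity (`I_fc`, `S_fc` over
#' `fc1..fcT`) and cognition (`I_cog`, `S_cog` over `cog1..cogT`) — joined
#' by directed paths from the connectivity intercept and slope onto the
#' cognition slope. Every latent factor is regressed on each covariate.
#' Latent disturbances covary within a block only, so with the cross-block
#' paths fixed at 0 the model separates into two independent growth models.
#'
#' @param fc_waves,cog_waves number of waves per block (>= 3 each).
#' @param fc_loadings,cog_loadings slope loadings (default `0..T-1`; first
#'   must be 0). Both blocks share the default wave coding.
#' @param covariates covariate names (e.g. `c("mfq_fof", "age_c")`).
#' @param constraints parameters to fix, as in [sem_spec()] — e.g.
#'   `"S_cog~~S_cog"` to fix the cognition slope disturbance to 0.
#' @return An object of class `c("parallel_spec", "sem_spec")`.
#' @export
build_parallel_spec <- function(fc_waves = 3, cog_waves = 3,
                                fc_loadings = seq(0, fc_waves - 1),
                                cog_loadings = seq(0, cog_waves - 1),
                                covariates = c("mfq_fof", "age_c"),
                                constraints = NULL) {
  if (fc_waves < 3 || cog_waves < 3)
    abort("Each block needs at least 3 waves.")
  if (fc_loadings[1] != 0 || cog_loadings[1] != 0)
    abort("The first slope loading of each block must be 0.")
  fc_out <- paste0("fc", seq_len(fc_waves))
  cog_out <- paste0("cog", seq_len(cog_waves))
  Lambda <- rbind(
    cbind(1, fc_loadings, 0, 0),
    cbind(0, 0, 1, cog_loadings))
  latents <- c("I_fc", "S_fc", "I_cog", "S_cog")
  psi_pairs <- list(c("I_fc", "I_fc"), c("S_fc", "S_fc"),
                    c("I_fc", "S_fc"),
                    c("I_cog", "I_cog"), c("S_cog", "S_cog"),
                    c("I_cog", "S_cog"))
  b_paths <- list(c("S_cog", "I_fc"), c("S_cog", "S_fc"))
  spec <- sem_spec(Lambda, outcomes = c(fc_out, cog_out), latents = latents,
                   covariates = covariates, psi_pairs = psi_pairs,
                   b_paths = b_paths, constraints = constraints,
                   subclass = "parallel_spec")
  spec$fc_waves <- fc_waves; spec$cog_waves <- cog_waves
  spec$fc_loadings <- fc_loadings; spec$cog_loadings <- cog_loadings
  spec
}

# rebuild with an extended constraint set (used by the Heywood rule)
rebuild_parallel_spec <- function(spec, constraints) {
  build_parallel_spec(spec$fc_waves, spec$cog_waves,
                      spec$fc_loadings, spec$cog_loadings,
                      covariates = spec$covariates,
                      constraints = constraints)
}

#' Fit a parallel-process growth model by FIML
#'
#' Joint FIML fit over the connectivity waves, cognition waves and
#' covariates; the boundary (Heywood) rule is applied to negative variance
#' estimates after fitting.
#'
#' @param fc_panel data frame with `fc1..fcT` columns (or a pre-joined
#'   table also holding `cog1..cogT`).
#' @param cog_panel optional data frame with `cog1..cogT`, matched to
#'   `fc_panel` by `subject_id` (subjects must align).
#' @param spec a [build_parallel_spec()]; built from the data by default.
#' @param covariates covariate names used when `spec` is `NULL`.
#' @param n_starts,seed optimizer controls as in [fit_lgm()].
#' @param heywood apply [apply_heywood_rule()] (default `TRUE`)?
#' @return An `"lgm_fit"`.
#' @export
fit_parallel <- function(fc_panel, cog_panel = NULL, spec = NULL,
                         covariates = c("mfq_fof", "age_c"),
                         n_starts = 3, seed = 1, heywood = TRUE) {
  data <- as_tibble(fc_panel)
  if (!is.null(cog_panel)) {
    cog_panel <- as_tibble(cog_panel)
    if (!"subject_id" %in% names(data) ||
        !"subject_id" %in% names(cog_panel))
      abort("Both panels need a `subject_id` column to align subjects.")
    if (!identical(sort(data$subject_id), sort(cog_panel$subject_id)))
      abort("Subjects differ between the connectivity and cognition panels.")
    cogcols <- grep("^cog[0-9]+$", names(cog_panel), value = TRUE)
    data <- dplyr::left_join(data, cog_panel[c("subject_id", cogcols)],
                             by = "subject_id")
  }
  if (is.null(spec)) {
    fc_w <- length(grep("^fc[0-9]+$", names(data)))
    cog_w <- length(grep("^cog[0-9]+$", names(data)))
    spec <- build_parallel_spec(fc_w, cog_w, covariates = covariates)
  }
  fit <- fit_sem_engine(data, spec, n_starts = n_starts, seed = seed)
  if (heywood) fit <- apply_heywood_rule(fit)
  fit
}

#' Delta-method indirect effect through a latent path
#'
#' For a mediation chain covariate -> latent mediator -> latent outcome,
#' the indirect effect is the product of the two component paths
#' `a = via~from` and `b = to~via`; its standard error is the first-order
#' delta approximation `sqrt(b^2 Var(a) + a^2 Var(b) + 2ab Cov(a, b))`.
#'
#' @param fit a converged `"lgm_fit"` from [fit_parallel()].
#' @param from_covariate covariate name (e.g. `"mfq_fof"`).
#' @param via_latent mediator latent (e.g. `"S_fc"`).
#' @param to_latent outcome latent (e.g. `"S_cog"`).
#' @return A one-row tibble: `label`, `estimate`, `std.error`, `statistic`,
#'   `p.value`, and the component path estimates.
#' @export
indirect_effect <- function(fit, from_covariate, via_latent, to_latent) {
  stopifnot(inherits(fit, "lgm_fit"))
  if (!fit$converged) abort("Fit did not converge.")
  lab_a <- paste0(via_latent, "~", from_covariate)
  lab_b <- paste0(to_latent, "~", via_latent)
  free <- fit$spec$par_table$label[fit$spec$par_table$free]
  for (lab in c(lab_a, lab_b)) {
    if (!lab %in% fit$spec$par_table$label)
      abort(paste0("No such path in the model: ", lab))
    if (!lab %in% free)
      abort(paste0("Component path ", lab,
                   " is constrained; indirect effect undefined."))
  }
  ia <- match(lab_a, free); ib <- match(lab_b, free)
  a <- unname(fit$params[ia]); b <- unname(fit$params[ib])
  if (is.null(fit$vcov)) abort("Fit has no covariance matrix for the SEs.")
  va <- fit$vcov[ia, ia]; vb <- fit$vcov[ib, ib]; cab <- fit$vcov[ia, ib]
  est <- a * b
  se <- sqrt(max(b^2 * va + a^2 * vb + 2 * a * b * cab, 0))
  z <- est / se
  tibble(label = paste0(from_covariate, " -> ", via_latent, " -> ",
                        to_latent),
         estimate = est, std.error = se, statistic = z,
         p.value = 2 * pnorm(-abs(z)),
         path_a = a, path_b = b)
}

#' Conditional growth model for a cognitive index
#'
#' Fits the conditional latent growth model to a cognitive outcome panel
#' (columns `cog1..cogT` or `y1..yT`) with the covariates, applying the
#' boundary rule — which, at typical sample sizes, is what fixes a negative
#' latent slope disturbance to 0 when its confidence interval covers 0.
#'
#' @param cog_panel data frame with the outcome waves and covariates.
#' @param covariates covariate names.
#' @param n_starts,seed optimizer controls.
#' @return An `"lgm_fit"` (with `$constrained` listing any boundary fixes).
#' @export
fit_cognitive_lgm <- function(cog_panel, covariates = c("mfq_fof", "age_c"),
                              n_starts = 3, seed = 1) {
  ycols <- sort(grep("^cog[0-9]+$", names(cog_panel), value = TRUE))
  if (length(ycols) == 0)
    ycols <- sort(grep("^y[0-9]+$", names(cog_panel), value = TRUE))
  if (length(ycols) < 3) abort("Need at least 3 outcome waves.")
  spec <- build_lgm_spec(length(ycols), covariates = covariates,
                         outcomes = ycols)
  fit <- fit_sem_engine(as.data.frame(cog_panel), spec,
                        n_starts = n_starts, seed = seed)
  apply_heywood_rule(fit)
}
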