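# Fitting latent growth models by FIML: front end, fit indices,
# standardized solution, and the boundary-constraint (Heywood) rule.

#' Fit a latent growth model by full-information maximum likelihood
#'
#' Maximizes the FIML log-likelihood of a [build_lgm_spec()] /
#' [sem_spec()] model by quasi-Newton iteration from one or more
#' deterministic starting points (a method-of-moments start plus jittered
#' copies). Standard errors come from the inverse observed information
#' (numerical Hessian of the negative log-likelihood); fit indices are
#' computed against the FIML-saturated and independence models. Variance
#' parameters are intentionally unconstrained so that negative (Heywood)
#' estimates are observable; see [apply_heywood_rule()].
#'
#' @param data data frame holding the outcome columns (`NA` = missing wave)
#'   and complete covariate columns named in the specification.
#' @param spec model specification; when `NULL`, a conditional linear growth
#'   model is built from `covariates` and the `y1..yT` columns of `data`.
#' @param covariates covariate names used when `spec` is `NULL`.
#' @param n_starts number of optimizer starts (first is the moment start).
#' @param seed integer seed controlling the start jitter.
#' @param se compute standard errors (observed information)?
#' @param indices compute chi-square, CFI, RMSEA (with 95% CI) and SRMR?
#' @param rmsea_n denominator convention for RMSEA: `"n"` (default) or
#'   `"n-1"`.
#'
#' @return An object of class `"lgm_fit"`; see [tidy.lgm_fit()] and
#'   [glance.lgm_fit()] for tabular views.
#' @examples
#' truth <- growth_truth()
#' cohort <- generate_cohort(simulation_config(n_subjects = 200, seed = 7))
#' panel <- generate_growth_panel(cohort, truth, seed = 8)
#' fit <- fit_lgm(panel, covariates = c("mfq_fof", "age_c"))
#' glance(fit)
#' @export
fit_lgm <- function(data, spec = NULL, covariates = character(),
                    n_starts = 3, seed = 1, se = TRUE, indices = TRUE,
                    rmsea_n = c("n", "n-1")) {
  rmsea_n <- match.arg(rmsea_n)
  if (is.null(spec)) {
    ycols <- sort(grep("^y[0-9]+$", names(data), value = TRUE))
    if (length(ycols) < 3)
      abort("Could not find outcome columns y1..yT in `data`.")
    spec <- build_lgm_spec(length(ycols), covariates = covariates,
                           outcomes = ycols)
  }
  stopifnot(inherits(spec, "sem_spec"))
  fit_sem_engine(data, spec, n_starts = n_starts, seed = seed, se = se,
                 indices = indices, rmsea_n = rmsea_n)
}

# shared engine behind fit_lgm / fit_parallel / fit_cognitive_lgm
fit_sem_engine <- function(data, spec, n_starts = 3, seed = 1, se = TRUE,
                           indices = TRUE, rmsea_n = "n",
                           patterns = NULL) {
  data <- as.data.frame(data)
  ps <- patterns %||% pattern_split(data, spec$outcomes, spec$covariates)
  if (ps$n == 0) abort("`data` is empty.")
  st <- start_values(spec, data)
  # make sure at least one start is admissible
  if (!is.finite(cpp_sem_loglik(st, spec$model, ps$patterns))) {
    pt <- spec$par_table
    offd <- pt$free & pt$mat == "Psi" & !pt$variance
    st[pt$label[offd]] <- 0
    varsel <- pt$free & pt$variance
    st[pt$label[varsel]] <- pmax(st[pt$label[varsel]], 0.1)
  }
  starts <- make_starts(spec, st, n_starts, seed)
  res <- cpp_sem_fit(starts, spec$model, ps$patterns)
  params <- setNames(drop(res$par), names(st))
  converged <- isTRUE(res$converged)
  warnings <- character()

  llx <- xblock_loglik(ps$X)
  ll_cond <- res$loglik
  ll_joint <- ll_cond + llx

  vc <- NULL
  ses <- rep(NA_real_, spec$npar)
  if (se && converged) {
    H <- cpp_sem_hessian(drop(res$par), spec$model, ps$patterns)
    vc <- tryCatch(solve(H), error = function(e) NULL)
    if (is.null(vc) || any(!is.finite(diag(vc)))) {
      warnings <- c(warnings, "observed information matrix not invertible")
      vc <- NULL
    } else if (any(diag(vc) < 0)) {
      warnings <- c(warnings,
                    "observed information not positive definite at optimum")
      ses <- sqrt(pmax(diag(vc), NA))
    } else {
      ses <- sqrt(diag(vc))
    }
    if (!is.null(vc)) ses <- sqrt(pmax(diag(vc), 0))
  }

  vars_joint <- c(spec$outcomes, spec$covariates)
  sat <- NULL
  fitblock <- NULL
  if (indices) {
    sat <- saturated_loglik(data, vars_joint)
    ll_base <- baseline_loglik(data, vars_joint)
    d <- length(vars_joint)
    df_base <- spec$moments - 2 * d
    imp <- implied_fit_moments(spec, params, ps)
    fitblock <- fit_indices(
      logL_model = ll_joint, df_model = spec$df,
      logL_sat = sat$loglik, logL_baseline = ll_base, df_baseline = df_base,
      n = ps$n, sigma_sat = sat$cov, sigma_model = imp$cov,
      rmsea_n = rmsea_n)
  }

  zstat <- params / ses
  pval <- 2 * pnorm(-abs(zstat))
  stdest <- tryCatch(standardized_values(spec, params, ps),
                     error = function(e) rep(NA_real_, spec$npar))

  estimates <- tibble(
    term = names(params),
    estimate = unname(params),
    std.error = unname(ses),
    statistic = unname(zstat),
    p.value = unname(pval),
    std.estimate = unname(stdest))

  structure(list(
    spec = spec, data = data, params = params, vcov = vc,
    estimates = estimates,
    logLik = ll_joint, logLik_conditional = ll_cond,
    logLik_sat = if (!is.null(sat)) sat$loglik else NA_real_,
    sat_moments = if (!is.null(sat)) sat[c("mean", "cov")] else NULL,
    fit = fitblock,
    n = ps$n, n_with_outcome = ps$n_with_outcome,
    converged = converged,
    diagnostics = list(iterations = res$iterations,
                       grad_norm = res$grad_norm,
                       start_used = res$start_used,
                       n_starts = n_starts, seed = seed,
                       rmsea_n = rmsea_n),
    constrained = spec$par_table$label[!spec$par_table$free &
                                         spec$par_table$variance &
                                         spec$par_table$fixed_value == 0],
    inadmissible = FALSE,
    warnings = warnings), class = "lgm_fit")
}

# model-implied joint moments at the fitted parameters, using sample
# covariate moments for the saturated exogenous block
implied_fit_moments <- function(spec, params, ps) {
  q <- length(spec$covariates)
  if (q > 0) {
    mu_x <- colMeans(ps$X)
    S_x <- crossprod(sweep(ps$X, 2, mu_x)) / nrow(ps$X)
    implied_moments(spec, params, x_mean = mu_x, x_cov = S_x)
  } else {
    implied_moments(spec, params)
  }
}

#' SEM fit indices from model, saturated and baseline log-likelihoods
#'
#' Computes the likelihood-ratio chi-square against the FIML-saturated model,
#' CFI against the independence baseline, RMSEA with a 95% confidence
#' interval obtained by root-finding on the noncentral chi-square
#' distribution, and (when covariance matrices are supplied) SRMR over
#' covariance residuals standardized by the saturated-estimate standard
#' deviations. When the chi-square falls below its degrees of freedom the
#' RMSEA is 0 by construction; with zero degrees of freedom the model is
#' saturated and CFI = 1, RMSEA = 0.
#'
#' @param logL_model,logL_sat,logL_baseline maximized log-likelihoods.
#' @param df_model,df_baseline degrees of freedom of the model and baseline.
#' @param n number of subjects.
#' @param sigma_sat,sigma_model saturated-estimate and model-implied
#'   covariance matrices of the joint observed vector (optional; needed for
#'   SRMR).
#' @param rmsea_n RMSEA denominator: `"n"` (default) or `"n-1"`.
#' @param ci_level confidence level for the RMSEA interval.
#' @return A one-row tibble: `chisq`, `df`, `p.chisq`, `cfi`, `rmsea`,
#'   `rmsea.lower`, `rmsea.upper`, `srmr`.
#' @export
fit_indices <- function(logL_model, df_model, logL_sat, logL_baseline,
                        df_baseline, n, sigma_sat = NULL, sigma_model = NULL,
                        rmsea_n = c("n", "n-1"), ci_level = 0.95) {
  rmsea_n <- match.arg(rmsea_n)
  if (logL_sat < logL_model - 1e-6 * (abs(logL_model) + 1))
    warn("Saturated log-likelihood below model log-likelihood; chi-square clipped at 0.")
  nn <- if (rmsea_n == "n") n else n - 1
  core <- indices_core(2 * (logL_sat - logL_model), df_model,
                       2 * (logL_sat - logL_baseline), df_baseline, nn)
  chisq <- core[["chisq"]]
  p_chisq <- core[["p"]]
  cfi <- core[["cfi"]]
  rmsea <- core[["rmsea"]]
  ci <- rmsea_ci(chisq, df_model, nn, ci_level)
  srmr <- NA_real_
  if (!is.null(sigma_sat) && !is.null(sigma_model)) {
    sdv <- sqrt(diag(sigma_sat))
    Rres <- (sigma_sat - sigma_model) / tcrossprod(sdv)
    srmr <- sqrt(mean(Rres[upper.tri(Rres, diag = TRUE)]^2))
  }
  tibble(chisq = chisq, df = df_model, p.chisq = p_chisq,
         cfi = min(max(cfi, 0), 1), rmsea = rmsea,
         rmsea.lower = ci[1], rmsea.upper = ci[2], srmr = srmr)
}

# numeric core of the fit indices (also used on the voxelwise fast path):
# chi-squares are clipped at 0, RMSEA is 0 whenever chisq <= df, and a
# saturated model (df = 0) has CFI = 1, RMSEA = 0
indices_core <- function(chisq, df, chisq_b, df_b, n) {
  chisq <- max(chisq, 0)
  chisq_b <- max(chisq_b, 0)
  p <- if (df > 0) pchisq(chisq, df, lower.tail = FALSE) else NA_real_
  excess <- max(chisq - df, 0)
  excess_b <- max(chisq_b - df_b, 0)
  cfi <- if (df == 0) 1 else {
    denom <- max(excess, excess_b, 0)
    if (denom == 0) 1 else 1 - excess / denom
  }
  cfi <- min(max(cfi, 0), 1)
  rmsea <- if (df == 0) 0 else sqrt(excess / (df * n))
  c(chisq = chisq, p = p, cfi = cfi, rmsea = rmsea)
}

# RMSEA confidence interval by root-finding on the noncentral chi-square
rmsea_ci <- function(chisq, df, n, level = 0.95) {
  if (df == 0) return(c(0, 0))
  a <- (1 - level) / 2
  upper_p <- 1 - a   # pchisq(chisq, df, ncp = lo) = upper_p defines lower
  lo <- 0
  if (pchisq(chisq, df, ncp = 0) > upper_p) {
    f <- function(l) pchisq(chisq, df, ncp = l) - upper_p
    lo <- tryCatch(uniroot(f, c(0, max(chisq * 10, 1)), extendInt = "downX",
                           tol = 1e-8)$root, error = function(e) 0)
  }
  hi <- 0
  if (pchisq(chisq, df, ncp = 0) > a) {
    f <- function(l) pchisq(chisq, df, ncp = l) - a
    hi <- tryCatch(uniroot(f, c(0, max(chisq * 10, 1)), extendInt = "downX",
                           tol = 1e-8)$root, error = function(e) NA_real_)
  }
  c(sqrt(max(lo, 0) / (df * n)), sqrt(max(hi, 0) / (df * n)))
}

# standardized estimates from model-implied variances (sample variances for
# exogenous covariates)
standardized_values <- function(spec, params, ps) {
  mm <- spec_matrices(spec, as.numeric(params))
  q <- length(spec$covariates)
  k <- length(spec$latents)
  if (q > 0) {
    mu_x <- colMeans(ps$X)
    S_x <- crossprod(sweep(ps$X, 2, mu_x)) / nrow(ps$X)
  } else {
    S_x <- matrix(0, 0, 0)
  }
  # model-implied latent covariance: eta = M (Gamma x + zeta)
  inner <- mm$Psi
  if (q > 0) inner <- inner + mm$Gamma %*% S_x %*% t(mm$Gamma)
  V_eta <- mm$M %*% inner %*% t(mm$M)
  LamM <- mm$Lambda %*% mm$M
  V_y <- diag(LamM %*% inner %*% t(LamM)) + mm$theta
  sd_eta <- sqrt(pmax(diag(V_eta), 0))
  sd_x <- if (q > 0) sqrt(diag(S_x)) else numeric(0)
  # disturbance part of eta for standardized psi: M Psi M'
  V_dist <- mm$M %*% mm$Psi %*% t(mm$M)

  pt <- spec$par_table
  out <- rep(NA_real_, spec$npar)
  for (r in seq_len(nrow(pt))) {
    if (!pt$free[r]) next
    id <- pt$id[r]
    val <- params[id]
    out[id] <- switch(pt$mat[r],
      alpha = if (sd_eta[pt$row[r]] > 0) val / sd_eta[pt$row[r]] else NA_real_,
      Gamma = if (sd_eta[pt$row[r]] > 0)
        val * sd_x[pt$col[r]] / sd_eta[pt$row[r]] else NA_real_,
      B = if (sd_eta[pt$row[r]] > 0)
        val * sd_eta[pt$col[r]] / sd_eta[pt$row[r]] else NA_real_,
      Psi = {
        i <- pt$row[r]; j <- pt$col[r]
        if (i == j) {
          if (sd_eta[i] > 0) mm$Psi[i, i] / V_eta[i, i] else NA_real_
        } else {
          dd2 <- V_dist[i, i] * V_dist[j, j]
          if (dd2 > 0) V_dist[i, j] / sqrt(dd2) else NA_real_
        }
      },
      Theta = if (V_y[pt$row[r]] > 0) val / V_y[pt$row[r]] else NA_real_)
  }
  out
}

#' Standardized solution of a fitted growth model
#'
#' Returns the parameter table with estimates rescaled to standard-deviation
#' units: covariate and latent regression paths are multiplied by
#' SD(predictor)/SD(outcome) using model-implied latent variances (sample
#' variances for exogenous covariates), disturbance covariances become
#' correlations, and residual variances become proportions of the implied
#' outcome variance. Parameters whose implied variance is zero are `NA` and
#' flagged.
#'
#' @param fit an `"lgm_fit"` object.
#' @return A tibble: `term`, `estimate`, `std.estimate`, `flagged`.
#' @export
standardize <- function(fit) {
  stopifnot(inherits(fit, "lgm_fit"))
  est <- fit$estimates
  tibble(term = est$term, estimate = est$estimate,
         std.estimate = est$std.estimate,
         flagged = is.na(est$std.estimate))
}

#' Apply the negative-variance (Heywood) boundary rule and refit
#'
#' Negative variance estimates whose 95% Wald confidence interval contains 0
#' are treated as sampling noise at the boundary of the parameter space:
#' they are fixed to 0 and the model refit, iterating until no new violation
#' appears (bounded by the number of variance parameters). A negative
#' variance whose confidence interval excludes 0 is flagged inadmissible and
#' left alone. The rule applies to residual variances and latent disturbance
#' variances alike.
#'
#' @param fit an `"lgm_fit"` object from [fit_lgm()] (or the internal
#'   engine); must be converged.
#' @param level confidence level of the Wald interval (default 0.95).
#' @return An `"lgm_fit"`; `$constrained` lists the parameters fixed to 0,
#'   `$inadmissible` is `TRUE` when a significantly negative variance was
#'   found.
#' @export
apply_heywood_rule <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "lgm_fit"))
  if (!fit$converged) {
    warn("Fit did not converge; Heywood rule not applied.")
    return(fit)
  }
  zcrit <- qnorm(1 - (1 - level) / 2)
  current <- fit
  n_var <- sum(fit$spec$par_table$variance)
  for (iter in seq_len(max(n_var, 1))) {
    pt <- current$spec$par_table
    est <- current$estimates
    vrows <- est$term %in% pt$label[pt$variance & pt$free]
    neg <- vrows & est$estimate < 0
    if (!any(neg)) break
    ci_hi <- est$estimate + zcrit * est$std.error
    fixable <- neg & (is.na(ci_hi) | ci_hi >= 0)
    hard <- neg & !fixable
    if (any(hard)) {
      current$inadmissible <- TRUE
      current$warnings <- c(current$warnings,
        paste0("negative variance with CI excluding 0: ",
               paste(est$term[hard], collapse = ", ")))
    }
    if (!any(fixable)) break
    new_fixed <- est$term[fixable]
    all_fixed <- union(current$constrained, new_fixed)
    old_cons <- pt$label[!pt$free]
    old_vals <- setNames(pt$fixed_value[!pt$free], old_cons)
    cons <- c(old_vals, setNames(rep(0, length(new_fixed)), new_fixed))
    spec2 <- respec_with_constraints(fit$spec, cons)
    refit <- tryCatch(
      fit_sem_engine(fit$data, spec2,
                     n_starts = fit$diagnostics$n_starts,
                     seed = fit$diagnostics$seed,
                     rmsea_n = fit$diagnostics$rmsea_n,
                     indices = !is.null(fit$fit),
                     se = TRUE),
      error = function(e) NULL)
    if (is.null(refit) || !refit$converged) {
      current$warnings <- c(current$warnings,
        "constrained refit failed to converge; unconstrained fit returned")
      return(current)
    }
    refit$constrained <- all_fixed
    refit$inadmissible <- current$inadmissible
    current <- refit
  }
  current
}

# rebuild a specification with an extended constraint set
respec_with_constraints <- function(spec, constraints) {
  if (inherits(spec, "lgm_spec")) {
    build_lgm_spec(spec$n_waves, loadings = spec$loadings,
                   covariates = spec$covariates, constraints = constraints,
                   outcomes = spec$outcomes)
  } else if (inherits(spec, "parallel_spec")) {
    rebuild_parallel_spec(spec, constraints)
  } else {
    pt <- spec$par_table
    psi_pairs <- lapply(which(pt$mat == "Psi"), function(r)
      c(spec$latents[pt$row[r]], spec$latents[pt$col[r]]))
    b_paths <- lapply(which(pt$mat == "B"), function(r)
      c(spec$latents[pt$row[r]], spec$latents[pt$col[r]]))
    sem_spec(spec$Lambda, spec$outcomes, spec$latents, spec$covariates,
             psi_pairs = psi_pairs, b_paths = b_paths,
             constraints = constraints)
  }
}

# ---------------------------------------------------------------------------
# methods
# ---------------------------------------------------------------------------

#' @export
print.lgm_fit <- function(x, ...) {
  cat("<lgm_fit> ", length(x$spec$outcomes), " outcomes, n = ", x$n,
      if (!x$converged) "  [NOT CONVERGED]", "\n", sep = "")
  cat("logLik = ", format(x$logLik, digits = 8), "\n", sep = "")
  if (!is.null(x$fit)) {
    f <- x$fit
    cat(sprintf("chisq(%d) = %.3f, p = %.3f, CFI = %.3f, RMSEA = %.3f [%.3f, %.3f], SRMR = %.3f\n",
                f$df, f$chisq, f$p.chisq, f$cfi, f$rmsea, f$rmsea.lower,
                f$rmsea.upper, f$srmr))
  }
  if (length(x$constrained) > 0)
    cat("constrained to 0:", paste(x$constrained, collapse = ", "), "\n")
  print(x$estimates, n = Inf)
  invisible(x)
}

#' Tidy a fitted growth model
#'
#' @param x an `"lgm_fit"`.
#' @param ... unused.
#' @return A tibble with one row per free parameter: `term`, `estimate`,
#'   `std.error`, `statistic` (Wald z), `p.value`, `std.estimate`.
#' @export
tidy.lgm_fit <- function(x, ...) x$estimates

#' One-row summary of a fitted growth model
#'
#' @param x an `"lgm_fit"`.
#' @param ... unused.
#' @return A one-row tibble: fit indices, log-likelihood, sample size,
#'   convergence and constraint flags.
#' @export
glance.lgm_fit <- function(x, ...) {
  f <- x$fit %||% tibble(chisq = NA_real_, df = NA_real_, p.chisq = NA_real_,
                         cfi = NA_real_, rmsea = NA_real_,
                         rmsea.lower = NA_real_, rmsea.upper = NA_real_,
                         srmr = NA_real_)
  dplyr::bind_cols(f, tibble(
    logLik = x$logLik, n = x$n, converged = x$converged,
    n_constrained = length(x$constrained), inadmissible = x$inadmissible))
}

#' @export
logLik.lgm_fit <- function(object, ...) {
  structure(object$logLik, df = object$spec$n_free_total,
            nobs = object$n, class = "logLik")
}

#' @export
coef.lgm_fit <- function(object, ...) object$params

#' @export
vcov.lgm_fit <- function(object, ...) object$vcov
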