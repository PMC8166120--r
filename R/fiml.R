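# FIML likelihood plumbing: missingness-pattern grouping, the saturated and
# independence (baseline) model likelihoods, and starting values.

# Group subjects by outcome-missingness pattern for the compiled likelihood.
# Covariates must be complete; outcomes may contain NA.
pattern_split <- function(data, outcomes, covariates) {
  miss_out <- setdiff(outcomes, names(data))
  if (length(miss_out) > 0)
    abort(paste0("Outcome column(s) not in data: ",
                 paste(miss_out, collapse = ", ")))
  miss_cov <- setdiff(covariates, names(data))
  if (length(miss_cov) > 0)
    abort(paste0("Covariate column(s) not in data: ",
                 paste(miss_cov, collapse = ", ")))
  Y <- as.matrix(data[outcomes])
  X <- as.matrix(data[covariates])
  storage.mode(Y) <- "double"
  if (length(covariates) > 0) {
    storage.mode(X) <- "double"
    if (anyNA(X))
      abort("Covariates must be complete; missing covariates are unsupported.")
  }
  obs_mat <- !is.na(Y)
  none <- rowSums(obs_mat) == 0 & length(covariates) == 0
  if (any(none))
    abort("Every subject must have at least one observed value.")
  key <- apply(obs_mat, 1, function(r) paste(as.integer(r), collapse = ""))
  groups <- split(seq_len(nrow(Y)), key)
  patterns <- lapply(groups, function(idx) {
    obs <- which(obs_mat[idx[1], ])
    list(obs = as.integer(obs - 1L),
         Y = Y[idx, obs, drop = FALSE],
         X = X[idx, , drop = FALSE],
         rows = idx)
  })
  list(patterns = unname(patterns), n = nrow(Y), X = X,
       n_with_outcome = sum(rowSums(obs_mat) > 0),
       outcomes = outcomes, covariates = covariates)
}

# patterns over the joint vector (outcomes then covariates), for the
# saturated-model EM
joint_patterns <- function(data, vars) {
  Z <- as.matrix(data[vars])
  storage.mode(Z) <- "double"
  obs_mat <- !is.na(Z)
  fully_missing <- colSums(obs_mat) == 0
  if (any(fully_missing))
    abort(paste0("Variable(s) entirely missing: ",
                 paste(vars[fully_missing], collapse = ", ")))
  keep <- rowSums(obs_mat) > 0
  Z <- Z[keep, , drop = FALSE]
  obs_mat <- obs_mat[keep, , drop = FALSE]
  key <- apply(obs_mat, 1, function(r) paste(as.integer(r), collapse = ""))
  groups <- split(seq_len(nrow(Z)), key)
  pats <- lapply(groups, function(idx) {
    obs <- which(obs_mat[idx[1], ])
    list(obs = as.integer(obs - 1L), Z = Z[idx, obs, drop = FALSE])
  })
  list(patterns = unname(pats), n = nrow(Z), d = ncol(Z), vars = vars)
}

# closed-form maximized log-likelihood of the saturated covariate block
# (covariates complete by contract); 0 when there are no covariates
xblock_loglik <- function(X) {
  if (is.null(X) || ncol(X) == 0 || nrow(X) == 0) return(0)
  n <- nrow(X); q <- ncol(X)
  mu <- colMeans(X)
  S <- crossprod(sweep(X, 2, mu)) / n
  ld <- determinant(S, logarithm = TRUE)
  if (ld$sign <= 0 || !is.finite(ld$modulus))
    abort("Covariate covariance matrix is singular (constant covariate?).")
  -0.5 * n * (q * log(2 * pi) + as.numeric(ld$modulus) + q)
}

#' FIML log-likelihood of a growth model at given parameter values
#'
#' Each subject contributes the multivariate-normal log-density of whatever
#' subvector of (outcomes, covariates) they have observed; the exogenous
#' covariate block is saturated and profiled at its sample-moment MLE.
#'
#' @param data data frame with the outcome and covariate columns named in
#'   `spec` (outcomes may contain `NA`; covariates must be complete).
#' @param spec a [sem_spec()] / [build_lgm_spec()] specification.
#' @param params numeric vector of free parameter values (optionally named by
#'   parameter label).
#' @param conditional if `TRUE`, return only the conditional log-likelihood
#'   of the outcomes given the covariates (the part that depends on the
#'   structural parameters).
#' @return The log-likelihood (a scalar).
#' @export
fiml_loglik <- function(data, spec, params, conditional = FALSE) {
  stopifnot(inherits(spec, "sem_spec"))
  if (!is.null(names(params))) {
    want <- spec$par_table$label[spec$par_table$free]
    if (all(want %in% names(params))) params <- params[want]
  }
  if (length(params) != spec$npar)
    abort(paste0("`params` must have length ", spec$npar, "."))
  ps <- pattern_split(data, spec$outcomes, spec$covariates)
  ll <- cpp_sem_loglik(as.numeric(params), spec$model, ps$patterns)
  if (is.nan(ll))
    abort("Implied covariance matrix is not positive definite at `params`.")
  if (conditional) ll else ll + xblock_loglik(ps$X)
}

#' Saturated-model FIML log-likelihood
#'
#' Maximized log-likelihood of the unstructured multivariate-normal model
#' (free mean vector and covariance matrix) for the joint observed vector
#' under arbitrary outcome missingness, by expectation-maximization or by
#' direct quasi-Newton maximization over a Cholesky parameterization.
#' This is the reference point for the model chi-square.
#'
#' @param data data frame.
#' @param vars variables forming the joint vector (e.g.
#'   `c(spec$outcomes, spec$covariates)`).
#' @param method `"em"` (default) or `"direct"`.
#' @param tol,maxit convergence controls.
#' @return A list: `loglik`, `mean`, `cov`, `n`, `iterations`, `converged`.
#' @export
saturated_loglik <- function(data, vars, method = c("em", "direct"),
                             tol = 1e-12, maxit = 5000) {
  method <- match.arg(method)
  jp <- joint_patterns(data, vars)
  if (jp$n <= jp$d)
    abort(paste0("Too few subjects (", jp$n, ") for a full-rank ", jp$d,
                 "-variable covariance matrix."))
  Z <- as.matrix(data[vars])
  mu0 <- colMeans(Z, na.rm = TRUE)
  v0 <- apply(Z, 2, function(col) {
    s <- var(col, na.rm = TRUE) * (sum(!is.na(col)) - 1) / sum(!is.na(col))
    max(s, 1e-8)
  })
  if (method == "em") {
    res <- cpp_mvn_em(jp$patterns, mu0, diag(v0, jp$d), tol, as.integer(maxit))
    if (!isTRUE(res$converged) && is.null(res$loglik))
      abort("Saturated-model EM failed (non-positive-definite update).")
    Sigma <- res$sigma
    dimnames(Sigma) <- list(vars, vars)
    list(loglik = res$loglik, mean = setNames(drop(res$mu), vars),
         cov = Sigma, n = jp$n, iterations = res$iterations,
         converged = isTRUE(res$converged), method = "em")
  } else {
    d <- jp$d
    # parameters: mean, then row-wise lower-triangular Cholesky of Sigma
    lt <- which(lower.tri(diag(d), diag = TRUE), arr.ind = TRUE)
    unpack <- function(par) {
      mu <- par[seq_len(d)]
      L <- matrix(0, d, d)
      L[lt] <- par[-seq_len(d)]
      diag(L) <- exp(diag(L))
      list(mu = mu, Sigma = L %*% t(L))
    }
    nll <- function(par) {
      u <- unpack(par)
      ll <- cpp_mvn_loglik(jp$patterns, u$mu, u$Sigma)
      if (!is.finite(ll)) 1e10 else -ll
    }
    L0 <- diag(0.5 * log(v0), d)
    p0 <- c(mu0, L0[lt])
    opt <- optim(p0, nll, method = "BFGS",
                 control = list(maxit = maxit, reltol = 1e-14))
    u <- unpack(opt$par)
    dimnames(u$Sigma) <- list(vars, vars)
    list(loglik = -opt$value, mean = setNames(u$mu, vars), cov = u$Sigma,
         n = jp$n, iterations = opt$counts[1],
         converged = opt$convergence == 0, method = "direct")
  }
}

# independence ("baseline") model: every variable normal with free mean and
# variance, all covariances 0; FIML solution is closed form per variable
baseline_loglik <- function(data, vars) {
  ll <- 0
  for (v in vars) {
    x <- data[[v]]
    x <- x[!is.na(x)]
    n <- length(x)
    if (n < 2) abort(paste0("Variable ", v, " has fewer than 2 observations."))
    s2 <- mean((x - mean(x))^2)
    if (s2 <= 0) abort(paste0("Variable ", v, " has zero variance."))
    ll <- ll - 0.5 * n * (log(2 * pi) + log(s2) + 1)
  }
  ll
}

# ---------------------------------------------------------------------------
# starting values: wave-wise OLS for the mean structure, least squares on the
# pairwise-complete residual covariance for the (co)variance structure
# ---------------------------------------------------------------------------
start_values <- function(spec, data) {
  outcomes <- spec$outcomes; covariates <- spec$covariates
  p <- length(outcomes); q <- length(covariates)
  Lambda <- spec$model$Lambda
  k <- ncol(Lambda)
  Y <- as.matrix(data[outcomes])
  X <- if (q > 0) as.matrix(data[covariates]) else matrix(0, nrow(Y), 0)

  # wave-wise OLS coefficients (intercept + covariates) and residuals
  b0 <- numeric(p)
  bcov <- matrix(0, p, max(q, 1L))[, seq_len(q), drop = FALSE]
  R <- matrix(NA_real_, nrow(Y), p)
  for (t in seq_len(p)) {
    ok <- !is.na(Y[, t])
    Xt <- cbind(1, X[ok, , drop = FALSE])
    ft <- lm.fit(Xt, Y[ok, t])
    cf <- ft$coefficients
    cf[is.na(cf)] <- 0
    b0[t] <- cf[1]
    if (q > 0) bcov[t, ] <- cf[-1]
    R[ok, t] <- ft$residuals
  }
  # mean-structure starts: mu_y = Lambda alpha, cov coefs = Lambda Gamma
  alpha_st <- drop(qr.coef(qr(Lambda), b0))
  alpha_st[is.na(alpha_st)] <- 0
  Gamma_st <- matrix(0, k, max(q, 1L))[, seq_len(q), drop = FALSE]
  if (q > 0) {
    for (j in seq_len(q)) {
      g <- drop(qr.coef(qr(Lambda), bcov[, j]))
      g[is.na(g)] <- 0
      Gamma_st[, j] <- g
    }
  }
  # covariance-structure starts: C ~ Lambda Psi Lambda' + diag(theta)
  C <- suppressWarnings(cov(R, use = "pairwise.complete.obs"))
  C[!is.finite(C)] <- 0
  pt <- spec$par_table
  free_psi <- pt[pt$mat == "Psi" & pt$free, ]
  free_theta <- pt[pt$mat == "Theta" & pt$free, ]
  pairs <- which(upper.tri(C, diag = TRUE), arr.ind = TRUE)
  yvec <- C[pairs]
  Dm <- matrix(0, nrow(pairs), nrow(free_psi) + nrow(free_theta))
  if (nrow(free_psi) > 0) {
    for (r in seq_len(nrow(free_psi))) {
      i <- free_psi$row[r]; j <- free_psi$col[r]
      coefv <- Lambda[pairs[, 1], i] * Lambda[pairs[, 2], j]
      if (i != j) coefv <- coefv + Lambda[pairs[, 1], j] * Lambda[pairs[, 2], i]
      Dm[, r] <- coefv
    }
  }
  if (nrow(free_theta) > 0) {
    for (r in seq_len(nrow(free_theta))) {
      t <- free_theta$row[r]
      Dm[, nrow(free_psi) + r] <- as.numeric(pairs[, 1] == t & pairs[, 2] == t)
    }
  }
  # subtract fixed Psi/Theta contributions
  fixed_psi <- pt[pt$mat == "Psi" & !pt$free & pt$fixed_value != 0, ]
  if (nrow(fixed_psi) > 0) {
    for (r in seq_len(nrow(fixed_psi))) {
      i <- fixed_psi$row[r]; j <- fixed_psi$col[r]
      coefv <- Lambda[pairs[, 1], i] * Lambda[pairs[, 2], j]
      if (i != j) coefv <- coefv + Lambda[pairs[, 1], j] * Lambda[pairs[, 2], i]
      yvec <- yvec - coefv * fixed_psi$fixed_value[r]
    }
  }
  cv <- tryCatch(qr.coef(qr(Dm), yvec), error = function(e) NULL)
  if (is.null(cv)) cv <- rep(0, ncol(Dm))
  cv[is.na(cv)] <- 0

  st <- spec_par_template(spec)
  for (r in seq_len(nrow(pt))) {
    if (!pt$free[r]) next
    lab <- pt$label[r]
    st[lab] <- switch(pt$mat[r],
      alpha = alpha_st[pt$row[r]],
      Gamma = Gamma_st[pt$row[r], pt$col[r]],
      B = 0,
      Psi = {
        rr <- which(free_psi$label == lab)
        cv[rr]
      },
      Theta = {
        rr <- which(free_theta$label == lab)
        cv[nrow(free_psi) + rr]
      })
  }
  # keep variance starts strictly positive and the start admissible
  varsel <- pt$free & pt$variance
  floorv <- 0.05 * mean(pmax(diag(C), 1e-6))
  st[pt$label[varsel]] <- pmax(st[pt$label[varsel]], floorv)
  st
}

# build the start matrix (first column the moment start, the rest jittered
# deterministically from `seed`)
make_starts <- function(spec, st, n_starts, seed) {
  npar <- length(st)
  S <- matrix(rep(st, n_starts), npar, n_starts)
  if (n_starts > 1) {
    set.seed(seed)
    varsel <- spec$par_table$variance[spec$par_table$free]
    for (j in 2:n_starts) {
      S[, j] <- st * (1 + 0.3 * rnorm(npar)) + 0.02 * rnorm(npar)
      S[varsel, j] <- abs(S[varsel, j]) + 1e-4
    }
  }
  S
}
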