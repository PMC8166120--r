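#' Construct a structural equation model specification
#'
#' Low-level constructor for the family of latent growth structures fit by
#' this package: observed outcomes load on latent factors through a fixed
#' loading matrix, latent factors may be regressed on each other and on
#' exogenous covariates, latent disturbances have a free (co)variance block,
#' and observed residual variances are wave-specific. Covariates are modelled
#' as exogenous with a saturated moment block, so full-information maximum
#' likelihood (FIML) remains valid when outcome waves are missing.
#'
#' Parameters are labelled in tilde notation: `"I~1"` is a latent mean,
#' `"S~mfq_fof"` a covariate path, `"S_cog~S_fc"` a latent regression,
#' `"I~~S"` a disturbance covariance and `"y1~~y1"` a residual variance.
#'
#' @param Lambda numeric matrix of fixed loadings, outcomes by latents.
#' @param outcomes character vector of observed outcome names (rows of
#'   `Lambda`).
#' @param latents character vector of latent factor names (columns of
#'   `Lambda`).
#' @param covariates character vector of exogenous covariate names (may be
#'   empty).
#' @param psi_pairs list of length-2 character vectors naming the free
#'   disturbance (co)variance entries; defaults to the full symmetric block.
#' @param b_paths list of length-2 character vectors `c(to, from)` of free
#'   latent regressions; default none.
#' @param constraints parameters to fix: a character vector of labels (fixed
#'   at 0) or a named numeric vector of label = value.
#' @param gamma_free logical; free covariate paths for every latent (default
#'   `TRUE`).
#' @param theta_free logical; free residual variance per outcome (default
#'   `TRUE`).
#' @param subclass optional S3 subclass tag.
#'
#' @return An object of class `"sem_spec"`: fixed matrices, a parameter table
#'   (`$par_table`), and the model degrees of freedom implied by moment
#'   counting over the joint observed vector (outcomes plus covariates).
#' @export
sem_spec <- function(Lambda, outcomes, latents, covariates = character(),
                     psi_pairs = NULL, b_paths = NULL, constraints = NULL,
                     gamma_free = TRUE, theta_free = TRUE,
                     subclass = character()) {
  Lambda <- as.matrix(Lambda)
  p <- nrow(Lambda); k <- ncol(Lambda); q <- length(covariates)
  if (length(outcomes) != p) abort("`outcomes` must match nrow(Lambda).")
  if (length(latents) != k) abort("`latents` must match ncol(Lambda).")
  rownames(Lambda) <- outcomes; colnames(Lambda) <- latents

  if (is.null(psi_pairs)) {
    psi_pairs <- list()
    for (i in seq_len(k)) for (j in i:k)
      psi_pairs[[length(psi_pairs) + 1L]] <- c(latents[i], latents[j])
  }

  rows <- list()
  add <- function(label, block, matrix, i, j, variance = FALSE) {
    rows[[length(rows) + 1L]] <<- tibble(
      label = label, block = block, mat = matrix,
      row = i, col = j, variance = variance)
  }
  for (i in seq_len(k)) add(paste0(latents[i], "~1"), "mean", "alpha", i, 1L)
  if (gamma_free && q > 0) {
    for (i in seq_len(k)) for (j in seq_len(q))
      add(paste0(latents[i], "~", covariates[j]), "path", "Gamma", i, j)
  }
  for (bp in b_paths %||% list()) {
    i <- match(bp[1], latents); j <- match(bp[2], latents)
    if (anyNA(c(i, j))) abort("Unknown latent in `b_paths`.")
    add(paste0(bp[1], "~", bp[2]), "beta", "B", i, j)
  }
  for (pp in psi_pairs) {
    i <- match(pp[1], latents); j <- match(pp[2], latents)
    if (anyNA(c(i, j))) abort("Unknown latent in `psi_pairs`.")
    add(paste0(latents[min(i, j)], "~~", latents[max(i, j)]), "psi", "Psi",
        min(i, j), max(i, j), variance = i == j)
  }
  if (theta_free) {
    for (i in seq_len(p))
      add(paste0(outcomes[i], "~~", outcomes[i]), "theta", "Theta", i, 1L,
          variance = TRUE)
  }
  par_table <- dplyr::bind_rows(rows)
  if (anyDuplicated(par_table$label))
    abort("Duplicate parameter labels in specification.")

  # apply constraints: fix named parameters at the given value
  par_table$free <- TRUE
  par_table$fixed_value <- NA_real_
  if (!is.null(constraints)) {
    if (is.character(constraints))
      constraints <- setNames(rep(0, length(constraints)), constraints)
    bad <- setdiff(names(constraints), par_table$label)
    if (length(bad) > 0)
      abort(paste0("Unknown parameter(s) in `constraints`: ",
                   paste(bad, collapse = ", ")))
    hit <- match(names(constraints), par_table$label)
    par_table$free[hit] <- FALSE
    par_table$fixed_value[hit] <- unname(constraints)
  }
  par_table$id <- ifelse(par_table$free, cumsum(par_table$free), 0L)

  # index / fixed-value matrices for the compiled likelihood
  a_idx <- integer(k); a_fix <- numeric(k)
  G_idx <- matrix(0L, k, max(q, 1L))[, seq_len(q), drop = FALSE]
  G_fix <- matrix(0, k, max(q, 1L))[, seq_len(q), drop = FALSE]
  B_idx <- matrix(0L, k, k); B_fix <- matrix(0, k, k)
  P_idx <- matrix(0L, k, k); P_fix <- matrix(0, k, k)
  T_idx <- integer(p); T_fix <- numeric(p)
  for (r in seq_len(nrow(par_table))) {
    pt <- par_table[r, ]
    id <- pt$id; fx <- if (pt$free) 0 else pt$fixed_value
    switch(pt$mat,
      alpha = { a_idx[pt$row] <- id; a_fix[pt$row] <- fx },
      Gamma = { G_idx[pt$row, pt$col] <- id; G_fix[pt$row, pt$col] <- fx },
      B     = { B_idx[pt$row, pt$col] <- id; B_fix[pt$row, pt$col] <- fx },
      Psi   = {
        P_idx[pt$row, pt$col] <- id; P_idx[pt$col, pt$row] <- id
        P_fix[pt$row, pt$col] <- fx; P_fix[pt$col, pt$row] <- fx
      },
      Theta = { T_idx[pt$row] <- id; T_fix[pt$row] <- fx })
  }
  npar <- sum(par_table$free)

  p_all <- p + q
  moments <- p_all + p_all * (p_all + 1) / 2
  n_free_total <- npar + q + q * (q + 1) / 2  # + saturated covariate block
  df <- moments - n_free_total
  if (df < 0)
    abort(paste0("Model is under-identified: ", n_free_total,
                 " free parameters against ", moments,
                 " observed moments (df = ", df, ")."))

  structure(
    list(
      model = list(Lambda = Lambda,
                   a_idx = a_idx, a_fix = a_fix,
                   G_idx = G_idx, G_fix = G_fix,
                   B_idx = B_idx, B_fix = B_fix,
                   P_idx = P_idx, P_fix = P_fix,
                   T_idx = T_idx, T_fix = T_fix,
                   npar = npar),
      par_table = par_table,
      outcomes = outcomes, latents = latents, covariates = covariates,
      Lambda = Lambda,
      npar = npar, df = df, moments = moments,
      n_free_total = n_free_total),
    class = c(subclass, "sem_spec"))
}

#' Build a (conditional) linear latent growth model specification
#'
#' A latent intercept `I` and slope `S` underlie the repeated outcome
#' `y1..yT`; the intercept is centred at the first wave (first slope loading
#' fixed to 0) and change is linear in the slope loadings. When covariates
#' are supplied both latent factors are regressed on each of them
#' (a conditional growth model); with no covariates the model is
#' unconditional.
#'
#' @param n_waves number of measurement occasions (at least 3 for an
#'   identified model with free per-wave residual variances).
#' @param loadings slope loadings, one per wave; default `0, 1, ..., T-1`
#'   codes time in units of one inter-wave interval. The first loading must
#'   be 0.
#' @param covariates character vector of covariate column names (e.g.
#'   `c("mfq_fof", "age_c")`); empty for an unconditional model.
#' @param constraints parameters to fix, as in [sem_spec()].
#' @param outcomes outcome column names; default `y1..yT`.
#'
#' @return An object of class `c("lgm_spec", "sem_spec")`.
#' @examples
#' build_lgm_spec(3)                      # unconditional: df = 1
#' build_lgm_spec(3, covariates = c("mfq_fof", "age_c"))
#' @export
build_lgm_spec <- function(n_waves, loadings = seq(0, n_waves - 1),
                           covariates = character(), constraints = NULL,
                           outcomes = paste0("y", seq_len(n_waves))) {
  if (length(loadings) != n_waves)
    abort("`loadings` must have one value per wave.")
  if (loadings[1] != 0)
    abort("The first slope loading must be 0 (intercept centred at wave 1).")
  Lambda <- cbind(I = rep(1, n_waves), S = loadings)
  spec <- sem_spec(Lambda, outcomes = outcomes, latents = c("I", "S"),
                   covariates = covariates, constraints = constraints,
                   subclass = "lgm_spec")
  spec$loadings <- loadings
  spec$n_waves <- n_waves
  spec
}

#' @export
print.sem_spec <- function(x, ...) {
  cat("<", class(x)[1], "> ", length(x$outcomes), " outcomes, ",
      length(x$latents), " latent factors, ",
      length(x$covariates), " covariates\n", sep = "")
  cat("free parameters: ", x$npar, " (+", x$n_free_total - x$npar,
      " saturated covariate moments), df = ", x$df, "\n", sep = "")
  free <- x$par_table$label[x$par_table$free]
  cat("free: ", paste(free, collapse = ", "), "\n", sep = "")
  fixed <- x$par_table[!x$par_table$free, ]
  if (nrow(fixed) > 0)
    cat("fixed: ", paste0(fixed$label, " = ", fixed$fixed_value,
                          collapse = ", "), "\n", sep = "")
  invisible(x)
}

# parameter vector template with labels, for implied_moments() etc.
spec_par_template <- function(spec) {
  setNames(numeric(spec$npar), spec$par_table$label[spec$par_table$free])
}

# assemble full matrices from a parameter vector (R-side mirror of the
# compiled build step; used by implied_moments and standardization)
spec_matrices <- function(spec, params) {
  m <- spec$model
  k <- ncol(m$Lambda); p <- nrow(m$Lambda); q <- ncol(m$G_idx)
  pull <- function(idx, fix) {
    out <- fix
    sel <- idx > 0
    out[sel] <- params[idx[sel]]
    out
  }
  alpha <- pull(m$a_idx, m$a_fix)
  Gamma <- matrix(pull(m$G_idx, m$G_fix), k, q)
  B <- matrix(pull(m$B_idx, m$B_fix), k, k)
  Psi <- matrix(pull(m$P_idx, m$P_fix), k, k)
  theta <- pull(m$T_idx, m$T_fix)
  M <- if (any(B != 0)) solve(diag(k) - B) else diag(k)
  list(alpha = alpha, Gamma = Gamma, B = B, Psi = Psi, theta = theta, M = M,
       Lambda = m$Lambda)
}

#' Model-implied moments of the joint observed vector
#'
#' Computes the mean vector and covariance matrix implied by a growth model
#' specification for the joint vector (outcomes, covariates). The covariate
#' block is saturated, so its moments are supplied directly.
#'
#' @param spec a [sem_spec()] specification.
#' @param params named or positional numeric vector of free parameter values
#'   (order of `spec$par_table` rows with `free = TRUE`).
#' @param x_mean,x_cov covariate moments; required when the specification has
#'   covariates.
#'
#' @return A list with `mean` and `cov` over
#'   `c(spec$outcomes, spec$covariates)`.
#' @export
implied_moments <- function(spec, params, x_mean = NULL, x_cov = NULL) {
  stopifnot(inherits(spec, "sem_spec"))
  if (length(params) != spec$npar)
    abort(paste0("`params` must have length ", spec$npar, "."))
  if (!is.null(names(params))) {
    want <- spec$par_table$label[spec$par_table$free]
    if (!all(want %in% names(params)))
      abort("Named `params` must cover every free parameter label.")
    params <- params[want]
  }
  mm <- spec_matrices(spec, as.numeric(params))
  q <- length(spec$covariates)
  LamM <- mm$Lambda %*% mm$M
  if (q > 0) {
    if (is.null(x_mean) || is.null(x_cov))
      abort("`x_mean` and `x_cov` are required when covariates are present.")
    x_cov <- as.matrix(x_cov)
    if (length(x_mean) != q || !all(dim(x_cov) == q))
      abort("Covariate moment dimensions do not match the specification.")
    mu_y <- drop(LamM %*% (mm$alpha + mm$Gamma %*% x_mean))
    Syy <- LamM %*% (mm$Gamma %*% x_cov %*% t(mm$Gamma) + mm$Psi) %*% t(LamM) +
      diag(mm$theta, nrow = length(mm$theta))
    Syx <- LamM %*% mm$Gamma %*% x_cov
    mu <- c(mu_y, x_mean)
    Sigma <- rbind(cbind(Syy, Syx), cbind(t(Syx), x_cov))
  } else {
    mu <- drop(LamM %*% mm$alpha)
    Sigma <- LamM %*% mm$Psi %*% t(LamM) +
      diag(mm$theta, nrow = length(mm$theta))
  }
  nm <- c(spec$outcomes, spec$covariates)
  names(mu) <- nm
  dimnames(Sigma) <- list(nm, nm)
  list(mean = mu, cov = Sigma)
}
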