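# Cohort preparation: subjective-decline questionnaire scoring, covariate
# centering, attrition audit, and demographic goodness-of-fit tests.

#' Score the Memory Functioning Questionnaire, Frequency of Forgetting
#'
#' Items are answered on a 7-point Likert scale where 1 expresses frequent
#' concern about forgetting and 7 no concern. Scoring inverts each item
#' (8 - response) so that larger values reflect a greater degree of
#' subjective cognitive decline, averages across items, and subtracts one so
#' the resulting score lies on a 0-6 scale with an interpretable zero point.
#'
#' @param items integer/numeric vector of Likert responses in 1..7 (at least
#'   one item).
#' @return The score, a scalar in \[0, 6\]; higher = more perceived decline.
#' @examples
#' score_mfq(rep(7, 10))  # no concern -> 0
#' score_mfq(c(1, 7))     # -> 3
#' @export
score_mfq <- function(items) {
  if (length(items) < 1) abort("`items` must contain at least one response.")
  bad <- which(is.na(items) | items < 1 | items > 7 | items != round(items))
  if (length(bad) > 0)
    abort(paste0("Likert responses must be integers in 1..7; invalid at index ",
                 paste(bad, collapse = ", "), "."))
  mean(8 - items) - 1
}

#' Center baseline age at 70 years
#'
#' @param age_years numeric vector of ages in years.
#' @return `age_years - 70`.
#' @export
center_age <- function(age_years) age_years - 70

#' Audit attrition with a univariate logistic regression
#'
#' Regresses a missingness indicator on a single baseline covariate by
#' maximum likelihood (iteratively reweighted least squares) and reports the
#' odds ratio per unit of the covariate with a two-sided Wald p-value. This
#' is the screening step for whether follow-up attendance is predictable
#' from baseline measures (a missing-at-random diagnostic). Complete
#' separation is detected and flagged rather than reported as a finite
#' estimate.
#'
#' @param baseline_covariate numeric vector, one value per subject.
#' @param missing_at_wave logical (or 0/1) vector: `TRUE` when the subject's
#'   data are missing at the audited wave.
#' @return A one-row tibble: `estimate` (log-odds slope), `odds_ratio`,
#'   `std.error`, `statistic`, `p.value`, `n`, `separation`.
#' @export
audit_missingness <- function(baseline_covariate, missing_at_wave) {
  x <- baseline_covariate
  y <- as.integer(as.logical(missing_at_wave))
  if (length(x) != length(y))
    abort("`baseline_covariate` and `missing_at_wave` must have equal length.")
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (sum(y == 0) < 2 || sum(y == 1) < 2)
    abort("Need at least 2 subjects in each missingness class.")
  if (var(x) == 0) {
    return(tibble(estimate = 0, odds_ratio = 1, std.error = NA_real_,
                  statistic = NA_real_, p.value = NA_real_,
                  n = length(y), separation = FALSE))
  }
  fit <- suppressWarnings(glm(y ~ x, family = binomial()))
  cf <- summary(fit)$coefficients
  slope <- cf["x", "Estimate"]
  se <- cf["x", "Std. Error"]
  separated <- !fit$converged || abs(slope) > 15 || se > 100
  tibble(estimate = slope,
         odds_ratio = exp(slope),
         std.error = se,
         statistic = if (separated) NA_real_ else slope / se,
         p.value = if (separated) NA_real_ else 2 * pnorm(-abs(slope / se)),
         n = length(y),
         separation = separated)
}

#' Pearson goodness-of-fit chi-square for category counts
#'
#' Tests observed category counts against expected proportions, e.g. whether
#' a cohort's sex split departs from 50/50.
#'
#' @param observed_counts non-negative integer vector of category counts.
#' @param expected_proportions probabilities summing to 1; default equal.
#' @return A one-row tibble: `chisq`, `df`, `p.value`, `n`, and the leading
#'   category's `proportion`.
#' @examples
#' goodness_of_fit_chi2(c(56, 13))  # chisq(1) = 26.80
#' @export
goodness_of_fit_chi2 <- function(observed_counts,
                                 expected_proportions =
                                   rep(1 / length(observed_counts),
                                       length(observed_counts))) {
  o <- observed_counts
  if (any(o < 0)) abort("Counts must be non-negative.")
  if (abs(sum(expected_proportions) - 1) > 1e-8)
    abort("`expected_proportions` must sum to 1.")
  if (any(expected_proportions <= 0))
    abort("Expected proportions must be strictly positive (no zero expected cell).")
  ht <- suppressWarnings(stats::chisq.test(o, p = expected_proportions))
  tibble(chisq = unname(ht$statistic), df = unname(ht$parameter),
         p.value = unname(ht$p.value), n = sum(o),
         proportion = o[1] / sum(o))
}

#' Derive analysis covariates from a raw covariate table
#'
#' Adds `age_c` (baseline age centred at 70) and, when Likert item columns
#' `mfq_1..mfq_k` are present, the derived `mfq_fof` score per subject.
#'
#' @param data data frame with at least an `age` column; optionally
#'   `mfq_1..mfq_k` item columns or an existing `mfq_fof` column.
#' @return The data frame with `age_c` (and `mfq_fof`) columns added.
#' @export
prep_covariates <- function(data) {
  if (!"age" %in% names(data)) abort("`data` must contain an `age` column.")
  out <- dplyr::mutate(as_tibble(data), age_c = center_age(.data$age))
  item_cols <- grep("^mfq_[0-9]+$", names(out), value = TRUE)
  if (length(item_cols) > 0 && !"mfq_fof" %in% names(out)) {
    items <- as.matrix(out[item_cols])
    out$mfq_fof <- apply(items, 1, score_mfq)
  }
  out
}
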