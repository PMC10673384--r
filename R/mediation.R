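#' Product-method decomposition of a total effect
#'
#' Extracts the three paths of the single-mediator product method from
#' three fitted models sharing the same covariate set:
#' \itemize{
#'   \item \code{fit_a}: metabolite ~ exposure (+ covariates); path a is
#'     the exposure coefficient.
#'   \item \code{fit_outcome}: outcome ~ exposure + metabolite
#'     (+ covariates); path b is the metabolite coefficient, the direct
#'     effect c-prime is the exposure coefficient.
#'   \item \code{fit_total}: outcome ~ exposure (+ covariates); the total
#'     effect c is the exposure coefficient.
#' }
#' The indirect effect is IE = a*b and the additivity gap
#' |c - (a*b + c')| is recorded (exactly zero for nested single-level
#' least-squares fits on identical rows; nonzero in general for mixed
#' models or differing complete-case sets).
#'
#' @param fit_a,fit_outcome,fit_total \code{lmm_fit} objects.
#' @param exposure_term name of the exposure coefficient
#'   (default \code{"smoking_num"}).
#' @param metabolite_term name of the metabolite coefficient in
#'   \code{fit_outcome}; defaults to the metabolite recorded in its spec.
#' @return object of class \code{mediation_result}: a one-row data.frame
#'   with a, se_a, b, se_b, c, se_c, c_prime, se_c_prime, ie,
#'   additivity_gap, plus metabolite/outcome labels. Confidence interval
#'   and classification are attached by [mediate()] /
#'   [monte_carlo_ci()] + [classify_mediation()].
#' @export
product_method <- function(fit_a, fit_outcome, fit_total,
                           exposure_term = "smoking_num",
                           metabolite_term = fit_outcome$spec$metabolite) {
  if (is.null(metabolite_term))
    stop("fit_outcome carries no metabolite term")
  a <- coef_row(fit_a, exposure_term)
  b <- coef_row(fit_outcome, metabolite_term)
  cp <- coef_row(fit_outcome, exposure_term)
  cc <- coef_row(fit_total, exposure_term)
  res <- data.frame(
    metabolite = metabolite_term,
    outcome = fit_total$spec$outcome,
    a = a$beta, se_a = a$se, p_a = a$p,
    b = b$beta, se_b = b$se, p_b = b$p,
    c = cc$beta, se_c = cc$se, p_c = cc$p,
    c_prime = cp$beta, se_c_prime = cp$se, p_c_prime = cp$p,
    stringsAsFactors = FALSE)
  res$ie <- res$a * res$b
  res$de <- res$c_prime
  res$additivity_gap <- abs(res$c - (res$ie + res$de))
  class(res) <- c("mediation_result", "data.frame")
  res
}

#' Monte-Carlo confidence interval for a product of coefficients
#'
#' Draws a* ~ Normal(a, se_a^2) and b* ~ Normal(b, se_b^2) independently
#' (zero cross-model covariance: the two coefficients come from separate
#' models), forms the products a*b*, and returns the empirical alpha/2 and
#' 1 - alpha/2 quantiles. Deterministic given the seed.
#'
#' @param a,se_a,b,se_b point estimates and standard errors of the two
#'   paths; standard errors must be nonnegative.
#' @param reps number of Monte-Carlo draws (default 1e5).
#' @param alpha two-sided level in (0, 1) (default 0.05 for a 95% CI).
#' @param seed integer seed.
#' @return numeric vector \code{c(low, high)}.
#' @export
monte_carlo_ci <- function(a, se_a, b, se_b, reps = 1e5, alpha = 0.05,
                           seed = 1L) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (se_a < 0 || se_b < 0) stop("standard errors must be >= 0")
  stopifnot(reps >= 1)
  set.seed(as.integer(seed))
  prod <- stats::rnorm(reps, a, se_a) * stats::rnorm(reps, b, se_b)
  q <- stats::quantile(prod, c(alpha / 2, 1 - alpha / 2), names = FALSE,
                       type = 7)
  c(low = q[1], high = q[2])
}

#' Proportion of the total effect that is mediated
#'
#' Primary definition IE / (IE + DE); the alternate IE / c is reported
#' alongside. The proportion is undefined when IE and DE have opposite
#' signs (inconsistent mediation / suppression), when either is zero with
#' the other nonzero-denominator degenerate cases, or when IE + DE = 0.
#'
#' @param ie indirect effect (a*b).
#' @param de direct effect (c-prime).
#' @param c total effect for the alternate denominator (optional).
#' @return list(proportion, proportion_of_c, defined, reason).
#' @export
proportion_mediated <- function(ie, de, c = NULL) {
  alt <- if (!is.null(c) && c != 0) ie / c else NA_real_
  if (ie + de == 0)
    return(list(proportion = NA_real_, proportion_of_c = alt,
                defined = FALSE, reason = "zero denominator"))
  if (ie != 0 && de != 0 && sign(ie) != sign(de))
    return(list(proportion = NA_real_, proportion_of_c = alt,
                defined = FALSE, reason = "inconsistent (opposite signs)"))
  list(proportion = ie / (ie + de), proportion_of_c = alt,
       defined = TRUE, reason = "")
}

#' Classify the mediation pattern
#'
#' Rule table on the indirect-effect confidence interval and the direct
#' effect: \code{"none"} if the IE CI contains 0; \code{"inconsistent"} if
#' the CI excludes 0 and IE and DE have opposite signs;
#' \code{"complete"} if the CI excludes 0 and the direct effect is not
#' significant (p >= de_alpha); \code{"partial"} otherwise.
#'
#' @param ie indirect-effect point estimate.
#' @param de direct-effect point estimate.
#' @param ci length-2 CI for the indirect effect.
#' @param de_p p-value of the direct effect.
#' @param de_alpha significance level for the direct effect (default 0.05).
#' @return character label.
#' @export
classify_mediation <- function(ie, de, ci, de_p, de_alpha = 0.05) {
  stopifnot(length(ci) == 2, ci[1] <= ci[2])
  if (ci[1] <= 0 && ci[2] >= 0) return("none")
  if (sign(ie) != sign(de) && de != 0) return("inconsistent")
  if (de_p >= de_alpha) return("complete")
  "partial"
}

#' Full single-mediator decomposition with CI and classification
#'
#' Convenience wrapper: runs [product_method()], attaches the Monte-Carlo
#' CI for the indirect effect, the mediated proportions and the
#' classification.
#'
#' @inheritParams product_method
#' @param reps,alpha,seed forwarded to [monte_carlo_ci()].
#' @return \code{mediation_result} one-row data.frame with ci_low,
#'   ci_high, proportion_mediated, proportion_of_c, classification,
#'   mc_reps and seed columns added.
#' @export
mediate <- function(fit_a, fit_outcome, fit_total,
                    exposure_term = "smoking_num",
                    metabolite_term = fit_outcome$spec$metabolite,
                    reps = 1e5, alpha = 0.05, seed = 1L) {
  res <- product_method(fit_a, fit_outcome, fit_total,
                        exposure_term, metabolite_term)
  ci <- monte_carlo_ci(res$a, res$se_a, res$b, res$se_b,
                       reps = reps, alpha = alpha, seed = seed)
  res$ci_low <- ci[["low"]]
  res$ci_high <- ci[["high"]]
  pm <- proportion_mediated(res$ie, res$de, res$c)
  res$proportion_mediated <- pm$proportion
  res$proportion_of_c <- pm$proportion_of_c
  res$proportion_reason <- pm$reason
  res$classification <- classify_mediation(res$ie, res$de, ci, res$p_c_prime)
  res$mc_reps <- reps
  res$seed <- as.integer(seed)
  res
}

#' Plain-text path-diagram report for one mediation result
#'
#' Prints the decomposition as a small text diagram: total effect c,
#' paths a and b with the indirect effect and its CI, direct effect
#' c-prime, and the mediated proportions.
#'
#' @param res one-row \code{mediation_result} from [mediate()].
#' @return the formatted report, invisibly; printed as a side effect.
#' @export
mediation_report <- function(res) {
  lines <- c(
    sprintf("Mediator %s on outcome %s", res$metabolite, res$outcome),
    sprintf("  total effect     c  = %+.4f (SE %.4f, p = %.3g)",
            res$c, res$se_c, res$p_c),
    sprintf("  exposure -> M    a  = %+.4f (SE %.4f)", res$a, res$se_a),
    sprintf("  M -> outcome     b  = %+.4f (SE %.4f)", res$b, res$se_b),
    sprintf("  indirect effect  IE = %+.4f  95%% CI [%+.4f, %+.4f]",
            res$ie, res$ci_low, res$ci_high),
    sprintf("  direct effect    c' = %+.4f (SE %.4f, p = %.3g)",
            res$c_prime, res$se_c_prime, res$p_c_prime),
    if (!is.na(res$proportion_mediated))
      sprintf("  proportion mediated IE/(IE+DE) = %.1f%%  (IE/c = %.1f%%)",
              100 * res$proportion_mediated, 100 * res$proportion_of_c)
    else
      sprintf("  proportion mediated: undefined (%s)", res$proportion_reason),
    sprintf("  classification: %s", res$classification))
  cat(paste(lines, collapse = "\n"), "\n")
  invisible(lines)
}
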