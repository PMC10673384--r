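#' Model specification for the longitudinal mixed models
#'
#' Describes one linear mixed model of the screening workflow: an outcome
#' regressed on smoking (the exposure), demographic covariates, centered
#' linear and quadratic age, a practice-effect term (visit minus 2;
#' baseline is visit two), optionally the visit-varying confounders
#' (CES-D, BMI category with reference "normal", weekly alcohol), and
#' optionally one metabolite predictor; with a family random intercept,
#' an individual random intercept and an individual random age slope.
#'
#' @param outcome name of the outcome column (a cognitive composite, or a
#'   metabolite column for the exposure-to-mediator screen).
#' @param exposure_coding \code{"categorical"} (never/former/current with
#'   never as reference; used for total-effect reporting) or
#'   \code{"numeric"} (never = 0, former = 1, current = 2; used for the
#'   mediation paths).
#' @param full if \code{TRUE}, include CES-D, BMI categories and weekly
#'   alcohol in addition to the reduced covariate set.
#' @param metabolite optional name of a metabolite column to include as a
#'   predictor.
#' @param include_exposure set \code{FALSE} to drop the smoking term.
#' @param include_covariates set \code{FALSE} to drop the demographic,
#'   age, and practice terms entirely (useful for reduced designs such as
#'   a pure random-intercept model).
#' @param random_family,random_individual,random_age_slope random-effect
#'   switches; models of CSF metabolites conventionally disable the family
#'   intercept (few related individuals). With all three off the model is
#'   fitted by ordinary least squares.
#' @param correlated_slope estimate the individual slope-intercept
#'   covariance freely (default) or force it to zero.
#' @param scale_metabolite z-score the metabolite predictor before fitting
#'   (off by default: QC'd log10 abundances enter as-is).
#' @return object of class \code{model_spec}.
#' @export
model_spec <- function(outcome,
                       exposure_coding = c("categorical", "numeric"),
                       full = TRUE,
                       metabolite = NULL,
                       include_exposure = TRUE,
                       include_covariates = TRUE,
                       random_family = TRUE,
                       random_individual = TRUE,
                       random_age_slope = TRUE,
                       correlated_slope = TRUE,
                       scale_metabolite = FALSE) {
  exposure_coding <- match.arg(exposure_coding)
  structure(list(outcome = outcome, exposure_coding = exposure_coding,
                 full = full, metabolite = metabolite,
                 include_exposure = include_exposure,
                 include_covariates = include_covariates,
                 random_family = random_family,
                 random_individual = random_individual,
                 random_age_slope = random_age_slope,
                 correlated_slope = correlated_slope,
                 scale_metabolite = scale_metabolite),
            class = "model_spec")
}

## prepare the modelling frame: centered age, practice effect, factor coding
prepare_model_frame <- function(data, spec) {
  need <- c(spec$outcome, "individual_id")
  if (spec$include_exposure) need <- c(need, "smoking")
  if (spec$include_covariates)
    need <- c(need, "age", "visit", "sex", "race", "education")
  if (spec$random_family) need <- c(need, "family_id")
  if (spec$random_age_slope) need <- c(need, "age")
  if (spec$full && spec$include_covariates)
    need <- c(need, "cesd", "bmi_category", "alcohol_weekly")
  if (!is.null(spec$metabolite)) need <- c(need, spec$metabolite)
  need <- unique(need)
  miss <- setdiff(need, names(data))
  if (length(miss) > 0)
    stop(sprintf("columns missing from data: %s", paste(miss, collapse = ", ")))
  d <- data[, need, drop = FALSE]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if ("age" %in% need) {
    d$age_c <- d$age - mean(d$age)
    d$age_c2 <- d$age_c^2
  }
  if (spec$include_covariates) {
    d$practice <- d$visit - 2
    d$sex <- factor(d$sex, levels = c("M", "F"))
    d$race <- factor(d$race, levels = c("other", "white"))
    if (spec$full)
      d$bmi_category <- factor(d$bmi_category,
                               levels = c("normal", "underweight",
                                          "overweight", "obese"))
  }
  if (spec$include_exposure) {
    if (spec$exposure_coding == "categorical") {
      d$smoking <- factor(d$smoking, levels = c("never", "former", "current"))
    } else {
      d$smoking_num <- smoking_numeric(d$smoking)
    }
  }
  if (!is.null(spec$metabolite) && spec$scale_metabolite)
    d[[spec$metabolite]] <- as.numeric(scale(d[[spec$metabolite]]))
  ## unused factor levels (e.g. no underweight individuals in a small
  ## sample) would create all-zero design columns; constant factors are a
  ## design error
  for (v in names(d)) {
    if (is.factor(d[[v]])) {
      d[[v]] <- droplevels(d[[v]])
      if (nlevels(d[[v]]) < 2)
        stop(sprintf(
          "rank-deficient fixed design; constant factor term: %s", v))
    }
  }
  d
}

build_formulas <- function(spec) {
  fixed <- c(
    if (spec$include_exposure)
      if (spec$exposure_coding == "categorical") "smoking" else "smoking_num",
    if (!is.null(spec$metabolite)) sprintf("`%s`", spec$metabolite),
    if (spec$include_covariates) c(
      "sex", "race", "education",
      if (spec$full) c("cesd", "bmi_category", "alcohol_weekly"),
      "age_c", "age_c2", "practice"))
  if (length(fixed) == 0) fixed <- "1"
  ind_term <- if (spec$random_individual && spec$random_age_slope) {
    if (spec$correlated_slope) "(1 + age_c | individual_id)"
    else "(1 + age_c || individual_id)"
  } else if (spec$random_individual) {
    "(1 | individual_id)"
  } else if (spec$random_age_slope) {
    "(0 + age_c | individual_id)"
  }
  rand <- c(if (spec$random_family) "(1 | family_id)", ind_term)
  list(fixed = stats::reformulate(fixed, response = sprintf("`%s`", spec$outcome)),
       full = stats::reformulate(c(fixed, rand),
                                 response = sprintf("`%s`", spec$outcome)),
       has_random = length(rand) > 0)
}

#' Fit one linear mixed model of the screening workflow
#'
#' Fits the model described by a [model_spec()] by REML via
#' \pkg{lme4} (or by ordinary least squares when every random term is
#' switched off). Reports per-coefficient Wald z statistics, standard
#' errors, 95% confidence intervals and p-values; variance components;
#' the intraclass correlation (random intercepts only) and the
#' marginal/conditional R-squared.
#'
#' A rank-deficient fixed design is an error naming the collinear terms;
#' optimizer non-convergence is reported in \code{$converged} (with the
#' messages in \code{$convergence_messages}), never silently.
#'
#' @param data long-format data.frame (one row per individual-visit or per
#'   matched sample).
#' @param spec a [model_spec()].
#' @return object of class \code{lmm_fit}: list with \code{coefficients}
#'   (data.frame term/beta/se/ci_low/ci_high/z/p), \code{varcomp} (named
#'   vector family/individual/age_slope/residual), \code{icc},
#'   \code{r2_marginal}, \code{r2_conditional}, counts, \code{logLik},
#'   \code{converged}, \code{singular}, and the underlying fitted model in
#'   \code{$model}.
#' @export
fit_lmm <- function(data, spec) {
  stopifnot(inherits(spec, "model_spec"))
  d <- prepare_model_frame(data, spec)
  if (length(unique(d$individual_id)) < 2)
    stop("at least 2 individuals required")
  fml <- build_formulas(spec)

  X <- stats::model.matrix(fml$fixed, d)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dep <- colnames(X)[setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])]
    stop(sprintf("rank-deficient fixed design; collinear term(s): %s",
                 paste(dep, collapse = ", ")))
  }

  msgs <- character(0)
  singular <- FALSE
  if (fml$has_random) {
    fit <- withCallingHandlers(
      lme4::lmer(fml$full, data = d, REML = TRUE,
                 control = lme4::lmerControl(calc.derivs = FALSE)),
      warning = function(w) {
        msgs <<- c(msgs, conditionMessage(w))
        invokeRestart("muffleWarning")
      },
      message = function(m) {
        msgs <<- c(msgs, conditionMessage(m))
        invokeRestart("muffleMessage")
      })
    ## a boundary (singular) fit is a valid REML estimate, not a failure
    all_msgs <- c(msgs, unlist(fit@optinfo$conv$lme4))
    converged <- fit@optinfo$conv$opt == 0 &&
      !any(grepl("failed to converge", all_msgs, ignore.case = TRUE))
    singular <- lme4::isSingular(fit, tol = 1e-4)
    beta <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    vc <- lme4::VarCorr(fit)
    varcomp <- c(family = 0, individual = 0, age_slope = 0,
                 residual = attr(vc, "sc")^2)
    slope_cov <- 0
    if ("family_id" %in% names(vc))
      varcomp[["family"]] <- vc$family_id[1, 1]
    iid <- grep("individual_id", names(vc))
    for (k in iid) {
      m <- vc[[k]]
      if ("(Intercept)" %in% rownames(m))
        varcomp[["individual"]] <- varcomp[["individual"]] +
          m["(Intercept)", "(Intercept)"]
      if ("age_c" %in% rownames(m))
        varcomp[["age_slope"]] <- varcomp[["age_slope"]] + m["age_c", "age_c"]
      if (all(c("(Intercept)", "age_c") %in% rownames(m)))
        slope_cov <- m["(Intercept)", "age_c"]
    }
  } else {
    fit <- stats::lm(fml$fixed, data = d)
    converged <- TRUE
    beta <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
    varcomp <- c(family = 0, individual = 0, age_slope = 0,
                 residual = summary(fit)$sigma^2)
    slope_cov <- 0
  }

  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  coefs <- data.frame(term = names(beta), beta = unname(beta),
                      se = unname(se),
                      ci_low = unname(beta - stats::qnorm(0.975) * se),
                      ci_high = unname(beta + stats::qnorm(0.975) * se),
                      z = unname(z), p = unname(p),
                      stringsAsFactors = FALSE)

  ## variance of the fixed-effect predictor and of the random part,
  ## for the marginal/conditional R^2 decomposition
  xb <- as.numeric(X %*% beta)
  var_fixed <- if (length(xb) > 1) stats::var(xb) else 0
  m1 <- if ("age_c" %in% names(d)) mean(d$age_c) else 0
  m2 <- if ("age_c" %in% names(d)) mean(d$age_c^2) else 0
  re_var <- varcomp[["family"]] + varcomp[["individual"]] +
    2 * slope_cov * m1 + varcomp[["age_slope"]] * m2
  re_var <- max(re_var, 0)

  out <- structure(list(
    spec = spec, coefficients = coefs, varcomp = varcomp,
    slope_cov = slope_cov, correlated_slope = spec$correlated_slope,
    var_fixed = var_fixed, random_variance_total = re_var,
    logLik = as.numeric(stats::logLik(fit)),
    n_observations = nrow(d),
    n_individuals = length(unique(d$individual_id)),
    n_families = if ("family_id" %in% names(d))
      length(unique(d$family_id)) else NA_integer_,
    converged = converged, singular = singular,
    convergence_messages = msgs,
    model = fit, frame = d
  ), class = "lmm_fit")
  out$icc <- icc(out)
  r2 <- r2_nakagawa(out)
  out$r2_marginal <- r2[["marginal"]]
  out$r2_conditional <- r2[["conditional"]]
  out
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("Linear mixed model: %s (%d obs, %d individuals, %d families)\n",
              x$spec$outcome, x$n_observations, x$n_individuals, x$n_families))
  print(x$coefficients, digits = 3, row.names = FALSE)
  cat(sprintf("ICC %.3f | marginal R2 %.3f | conditional R2 %.3f\n",
              x$icc, x$r2_marginal, x$r2_conditional))
  if (!x$converged) cat("WARNING: optimizer did not converge\n")
  invisible(x)
}

## pull one coefficient row, error if absent
coef_row <- function(fit, term) {
  i <- match(term, fit$coefficients$term)
  if (is.na(i))
    stop(sprintf("coefficient '%s' absent from fit of '%s'",
                 term, fit$spec$outcome))
  fit$coefficients[i, ]
}

#' Intraclass correlation coefficient
#'
#' Share of outcome variance attributable to the random intercepts:
#' (family + individual intercept variance) / (family + individual +
#' residual variance). The random age-slope variance is excluded.
#'
#' @param fit an \code{lmm_fit} (or any list with a \code{varcomp} vector).
#' @return ICC in [0, 1]; 0 when all random variances are 0.
#' @export
icc <- function(fit) {
  v <- fit$varcomp
  num <- v[["family"]] + v[["individual"]]
  den <- num + v[["residual"]]
  if (den == 0) return(0)
  unname(num / den)
}

#' Marginal and conditional R-squared for a mixed model
#'
#' Variance-decomposition R-squared: marginal = fixed-effect variance over
#' (fixed + random + residual); conditional adds the random-effect variance
#' to the numerator. The random-effect variance term is the mean
#' observation-level variance contributed by the random effects (for the
#' individual slope this is intercept variance + 2 cov mean(age_c) + slope
#' variance mean(age_c^2)), which reduces to the sum of intercept variances
#' for intercept-only structures.
#'
#' @param fit an \code{lmm_fit}, or any list with numeric elements
#'   \code{var_fixed}, \code{random_variance_total} and \code{varcomp}
#'   (for the residual).
#' @return named vector \code{c(marginal=, conditional=)}.
#' @export
r2_nakagawa <- function(fit) {
  vf <- fit$var_fixed
  vr <- fit$random_variance_total
  ve <- fit$varcomp[["residual"]]
  tot <- vf + vr + ve
  if (tot == 0) return(c(marginal = 1, conditional = 1))
  c(marginal = vf / tot, conditional = (vf + vr) / tot)
}

#' Compare a reduced and a full model fit
#'
#' Refits both models by maximum likelihood (REML likelihoods are not
#' comparable across fixed structures) and selects by AIC; an exact tie
#' returns the reduced model by parsimony.
#'
#' @param fit_reduced,fit_full \code{lmm_fit} objects for the same outcome
#'   fitted to the same observations.
#' @return list(choice = "reduced"|"full", aic_reduced, aic_full).
#' @export
compare_fits <- function(fit_reduced, fit_full) {
  if (fit_reduced$spec$outcome != fit_full$spec$outcome)
    stop("fits have different outcomes")
  if (fit_reduced$n_observations != fit_full$n_observations)
    stop("fits use differing observation sets")
  aic_ml <- function(f) {
    if (inherits(f$model, "merMod")) {
      stats::AIC(suppressMessages(suppressWarnings(
        stats::update(f$model, REML = FALSE, data = f$frame))))
    } else {
      stats::AIC(f$model)
    }
  }
  a_r <- aic_ml(fit_reduced)
  a_f <- aic_ml(fit_full)
  list(choice = if (a_f < a_r) "full" else "reduced",
       aic_reduced = a_r, aic_full = a_f)
}
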