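#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: with the p-values sorted ascending,
#' q(i) = min over j >= i of p(j) * m / j, capped at 1, returned in the
#' original order.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return vector of adjusted values (q-values), same order as the input.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must be in [0, 1] with no missing values")
  stats::p.adjust(p, method = "BH")
}

#' Merge a QC'd metabolite matrix into the cohort table
#'
#' Matches each fluid sample to the same individual's nearest visit by age
#' (ties toward the earlier visit) and joins the metabolite columns onto
#' the cohort rows. Individuals absent from the cohort are dropped with a
#' count; when several samples map to the same visit the one with the
#' smallest age gap is kept.
#'
#' @param cohort cohort data.frame.
#' @param matrix a QC'd [metab_matrix()].
#' @return data.frame of matched cohort rows plus one column per
#'   metabolite; metabolite names in attribute \code{"metabolites"}.
#' @export
merge_metabolites <- function(cohort, matrix) {
  stopifnot(inherits(matrix, "metab_matrix"))
  meta <- matrix$meta
  keep <- meta$individual_id %in% cohort$individual_id
  meta <- meta[keep, , drop = FALSE]
  map <- match_samples_to_visits(
    meta, cohort[, c("individual_id", "visit", "age")])
  ## one sample per (individual, visit): keep the closest in age
  map <- map[order(map$individual_id, map$visit, map$age_gap), ]
  map <- map[!duplicated(map[, c("individual_id", "visit")]), ]
  key_cohort <- paste(cohort$individual_id, cohort$visit)
  key_map <- paste(map$individual_id, map$visit)
  rows <- match(key_map, key_cohort)
  merged <- cohort[rows, , drop = FALSE]
  merged <- cbind(merged,
                  matrix$abund[map$sample_id, , drop = FALSE])
  rownames(merged) <- NULL
  attr(merged, "metabolites") <- colnames(matrix$abund)
  attr(merged, "n_unmatched_individuals") <- sum(!keep)
  merged
}

#' Step 1: total effect of smoking on a cognitive outcome
#'
#' Fits the reduced (demographics + age terms + practice) and full
#' (+ CES-D, BMI, weekly alcohol) mixed models for one outcome, selects
#' between them by ML-based AIC, and reports the smoking coefficients of
#' both. With numeric exposure coding the chosen model's smoking
#' coefficient is the total effect (path c) used by the mediation stage.
#'
#' @param cohort cohort data.frame.
#' @param outcome outcome column name.
#' @param exposure_coding passed to [model_spec()]; categorical by default
#'   so former/current effects are reported separately.
#' @param ... further arguments to [model_spec()] (random-effect switches).
#' @return list(choice, fit_reduced, fit_full, comparison, smoking
#'   coefficient rows of the chosen fit).
#' @export
step1_total_effect <- function(cohort, outcome,
                               exposure_coding = "categorical", ...) {
  spec_r <- model_spec(outcome, exposure_coding = exposure_coding,
                       full = FALSE, ...)
  spec_f <- model_spec(outcome, exposure_coding = exposure_coding,
                       full = TRUE, ...)
  fit_r <- fit_lmm(cohort, spec_r)
  fit_f <- fit_lmm(cohort, spec_f)
  cmp <- compare_fits(fit_r, fit_f)
  chosen <- if (cmp$choice == "full") fit_f else fit_r
  smk_terms <- grep("^smoking", chosen$coefficients$term, value = TRUE)
  list(choice = cmp$choice, fit_reduced = fit_r, fit_full = fit_f,
       comparison = cmp, chosen = chosen,
       smoking = chosen$coefficients[
         chosen$coefficients$term %in% smk_terms, , drop = FALSE])
}

## shared worker: fit one model per metabolite and collect one coefficient;
## target_term maps a metabolite id to the coefficient to extract
screen_metabolites <- function(merged, metabolites, make_spec, target_term,
                               outcome_label, fluid, min_obs) {
  rows <- vector("list", length(metabolites))
  skipped <- character(0)
  for (i in seq_along(metabolites)) {
    m <- metabolites[i]
    spec <- make_spec(m)
    need <- c(spec$outcome, m, "smoking", "age", "visit", "sex", "race",
              "education")
    if (spec$full) need <- c(need, "cesd", "bmi_category", "alcohol_weekly")
    need <- intersect(unique(need), names(merged))
    n_cc <- sum(stats::complete.cases(merged[, need, drop = FALSE]))
    if (n_cc < min_obs) {
      skipped <- c(skipped, m)
      next
    }
    fit <- fit_lmm(merged, spec)
    cr <- coef_row(fit, target_term(m))
    rows[[i]] <- data.frame(
      metabolite = m, fluid = fluid, outcome = outcome_label,
      beta = cr$beta, se = cr$se, ci_low = cr$ci_low, ci_high = cr$ci_high,
      p = cr$p, n = fit$n_observations, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  attr(res, "skipped") <- skipped
  res
}

#' Step 2: exposure-to-metabolite screen
#'
#' Regresses each metabolite (as the outcome) on numeric smoking plus the
#' full covariate set with the longitudinal random structure, then adjusts
#' the smoking p-values by Benjamini-Hochberg FDR within the fluid. Plasma
#' and CSF are separate FDR families; CSF models should be run with
#' \code{random_family = FALSE}.
#'
#' @param merged output of [merge_metabolites()].
#' @param metabolites metabolite columns to screen (defaults to the merged
#'   attribute).
#' @param fluid family label recorded in the results.
#' @param fdr_level significance level on the q-values (default 0.05).
#' @param min_obs minimum complete-case rows per metabolite model;
#'   metabolites below it are skipped and listed in attribute
#'   \code{"skipped"}.
#' @param full,include_covariates covariate-set switches forwarded to
#'   [model_spec()] (the pipeline passes the Step-1 choice).
#' @param random_family,random_individual,random_age_slope,correlated_slope
#'   random-structure switches forwarded to [model_spec()]; turning all
#'   three groups off fits by OLS (single-level data).
#' @return data.frame (one row per screened metabolite) with beta, se, CI,
#'   p, q and \code{passed} = (q < fdr_level).
#' @export
step2_metabolite_screen <- function(merged,
                                    metabolites = attr(merged, "metabolites"),
                                    fluid = "plasma",
                                    fdr_level = 0.05, min_obs = 50,
                                    full = TRUE,
                                    include_covariates = TRUE,
                                    random_family = TRUE,
                                    random_individual = TRUE,
                                    random_age_slope = TRUE,
                                    correlated_slope = TRUE) {
  res <- screen_metabolites(
    merged, metabolites,
    make_spec = function(m)
      model_spec(m, exposure_coding = "numeric", full = full,
                 include_covariates = include_covariates,
                 random_family = random_family,
                 random_individual = random_individual,
                 random_age_slope = random_age_slope,
                 correlated_slope = correlated_slope),
    target_term = function(m) "smoking_num", outcome_label = "metabolite",
    fluid = fluid, min_obs = min_obs)
  if (is.null(res)) return(res)
  res$q <- bh_fdr(res$p)
  res$passed <- res$q < fdr_level
  res
}

#' Step 3: mediator-to-outcome screen
#'
#' For each Step-2 survivor, regresses the cognitive outcome on numeric
#' smoking plus the metabolite (plus full covariates and the longitudinal
#' random structure) and extracts the metabolite coefficient (path b).
#' FDR adjustment is within (fluid x outcome) across the candidate set.
#'
#' @param merged output of [merge_metabolites()].
#' @param candidates metabolite ids that passed Step 2.
#' @param outcome cognitive outcome column.
#' @inheritParams step2_metabolite_screen
#' @return data.frame as in [step2_metabolite_screen()], one row per
#'   candidate, with the metabolite coefficient on the outcome.
#' @export
step3_outcome_screen <- function(merged, candidates, outcome,
                                 fluid = "plasma",
                                 fdr_level = 0.05, min_obs = 50,
                                 full = TRUE,
                                 include_covariates = TRUE,
                                 random_family = TRUE,
                                 random_individual = TRUE,
                                 random_age_slope = TRUE,
                                 correlated_slope = TRUE) {
  stopifnot(all(candidates %in% attr(merged, "metabolites")))
  res <- screen_metabolites(
    merged, candidates,
    make_spec = function(m)
      model_spec(outcome, exposure_coding = "numeric", full = full,
                 metabolite = m,
                 include_covariates = include_covariates,
                 random_family = random_family,
                 random_individual = random_individual,
                 random_age_slope = random_age_slope,
                 correlated_slope = correlated_slope),
    target_term = function(m) m, outcome_label = outcome,
    fluid = fluid, min_obs = min_obs)
  if (is.null(res)) return(res)
  res$q <- bh_fdr(res$p)
  res$passed <- res$q < fdr_level
  res
}
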