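#' Simulation configuration for a multilevel longitudinal cohort
#'
#' Builds the configuration object consumed by [generate_cohort()] and
#' [generate_metabolome()]. Defaults emulate a late-midlife longitudinal
#' cohort of sibship-nested individuals observed over one to six visits
#' (baseline indexed as visit 2), with covariate distributions typical of
#' such studies: age ~ 58.5 (SD 6.47, truncated to 40.7-75.0 years), 70.4%
#' female, 94.8% white, 61.4% college-educated, smoking split
#' 56.2/37.0/6.8% across never/former/current, CES-D depressive-symptom
#' scores around 7, and BMI categories 0.6/27.8/35.5/36.1%.
#'
#' Cognitive composite outcomes are generated as a fixed linear predictor
#' (intercept, covariate effects, a numeric smoking direct effect, centered
#' linear and quadratic age, a per-visit practice effect, and planted
#' mediator contributions) plus a family random intercept, an individual
#' random intercept, an individual random age slope, and residual noise.
#'
#' Metabolites live on the log10-abundance scale: planted paths
#' \code{a[j]} are slopes of log10 abundance on numeric smoking
#' (never = 0, former = 1, current = 2), and \code{b[j]} are slopes of the
#' outcome on (centered) log10 abundance. A mediator with
#' \code{sign(a*b) != sign(direct_effect)} acts as a suppressor and is
#' labelled as such.
#'
#' @param n_families number of sibships.
#' @param family_size_probs probabilities for 1, 2, ... individuals per
#'   family (mean ~1.25 by default).
#' @param visit_probs probabilities for 1..6 visits per individual
#'   (default mean 3.73 visits).
#' @param visit_spacing_years years between consecutive visits.
#' @param smoking_probs length-3 probability vector over
#'   never/former/current; must sum to 1.
#' @param covariate_params list of covariate distribution parameters; see
#'   defaults.
#' @param n_metabolites total metabolite count in the generated matrix.
#' @param mediator_spec data.frame with columns \code{index}, \code{a},
#'   \code{b}, \code{role}; roles in
#'   \code{c("mediator","suppressor","null_a","null_b")}. Metabolites not
#'   listed are pure noise. \code{NULL} gives a default panel with one
#'   consistent mediator, one suppressor, one null-a and one null-b
#'   metabolite.
#' @param direct_effect named vector of per-outcome direct effects of
#'   numeric smoking (c-prime).
#' @param covariate_effects named list of fixed-effect coefficients shared
#'   by the four outcomes.
#' @param variance_components named vector: \code{family} and
#'   \code{individual} random-intercept variances, \code{age_slope}
#'   random-slope variance (per year squared), \code{residual} variance.
#' @param practice_effect per-visit score increment (visit minus 2).
#' @param age_coefs named vector \code{c(linear=, quadratic=)} on centered
#'   age.
#' @param metabolite_mu baseline mean log10 abundance (recycled per
#'   metabolite).
#' @param metabolite_ind_sd,metabolite_resid_sd individual-level and
#'   sample-level SDs of log10 abundance.
#' @param missingness per-metabolite missing-completely-at-random fraction
#'   (scalar recycled, or length \code{n_metabolites}).
#' @param missing_low_abundance if \code{TRUE}, missingness is concentrated
#'   in the lowest-abundance entries of each metabolite (abundance-dependent
#'   mechanism for stress-testing QC) instead of MCAR.
#' @param smoking_time_varying if \code{TRUE}, smoking status may change
#'   across visits (initiation, quitting, relapse at small per-visit
#'   probabilities); the default holds status constant within individual.
#' @param seed integer RNG seed; everything downstream is deterministic
#'   given the config.
#' @return object of class \code{sim_config}.
#' @export
sim_config <- function(n_families = 1007,
                       family_size_probs = c(0.80, 0.15, 0.05),
                       visit_probs = c(0.06, 0.12, 0.22, 0.33, 0.17, 0.10),
                       visit_spacing_years = 2,
                       smoking_probs = c(never = 0.562, former = 0.370,
                                         current = 0.068),
                       covariate_params = list(
                         age = list(mean = 58.5, sd = 6.47,
                                    min = 40.7, max = 75.0),
                         sex_female_prob = 0.704,
                         race_white_prob = 0.948,
                         education_prob = 0.614,
                         cesd = list(mean = 7.13, sd = 7.16,
                                     min = 0, max = 60),
                         bmi_probs = c(underweight = 0.006, normal = 0.278,
                                       overweight = 0.355, obese = 0.361),
                         alcohol = list(mean = 4.25, sd = 6.74)
                       ),
                       n_metabolites = 40,
                       mediator_spec = NULL,
                       direct_effect = c(PACC3 = -0.10, IMM = -0.10,
                                         DEL = -0.10, EXE = -0.08),
                       covariate_effects = list(
                         intercept = -1.0, female = 0.50, white = 0.40,
                         college = 0.37, cesd = -0.005,
                         bmi_underweight = -0.20, bmi_overweight = 0.005,
                         bmi_obese = 0.03, alcohol = 0.005
                       ),
                       variance_components = c(family = 0.10,
                                               individual = 0.15,
                                               age_slope = 1e-4,
                                               residual = 0.07),
                       practice_effect = 0.08,
                       age_coefs = c(linear = -0.045, quadratic = -0.001),
                       metabolite_mu = 3,
                       metabolite_ind_sd = 0.25,
                       metabolite_resid_sd = 0.15,
                       missingness = 0,
                       missing_low_abundance = FALSE,
                       smoking_time_varying = FALSE,
                       seed = 1L) {
  if (is.null(mediator_spec)) {
    k <- min(4L, n_metabolites)
    mediator_spec <- data.frame(
      index = seq_len(k),
      a = c(0.40, 0.40, 0.00, 0.40)[seq_len(k)],
      b = c(-0.30, 0.30, -0.30, 0.00)[seq_len(k)],
      role = c("mediator", "suppressor", "null_a", "null_b")[seq_len(k)],
      stringsAsFactors = FALSE
    )
  }
  cfg <- list(
    n_families = n_families, family_size_probs = family_size_probs,
    visit_probs = visit_probs, visit_spacing_years = visit_spacing_years,
    smoking_probs = smoking_probs, covariate_params = covariate_params,
    n_metabolites = n_metabolites, mediator_spec = mediator_spec,
    direct_effect = direct_effect, covariate_effects = covariate_effects,
    variance_components = variance_components,
    practice_effect = practice_effect, age_coefs = age_coefs,
    metabolite_mu = rep_len(metabolite_mu, n_metabolites),
    metabolite_ind_sd = metabolite_ind_sd,
    metabolite_resid_sd = metabolite_resid_sd,
    missingness = rep_len(missingness, n_metabolites),
    missing_low_abundance = missing_low_abundance,
    smoking_time_varying = smoking_time_varying,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stop_cfg <- function(field, msg) {
    stop(sprintf("invalid sim_config field '%s': %s", field, msg),
         call. = FALSE)
  }
  if (abs(sum(cfg$smoking_probs) - 1) > 1e-8)
    stop_cfg("smoking_probs", "must sum to 1")
  if (length(cfg$smoking_probs) != 3L)
    stop_cfg("smoking_probs", "must have length 3 (never/former/current)")
  if (any(cfg$variance_components < 0))
    stop_cfg("variance_components", "variances must be >= 0")
  if (length(cfg$visit_probs) < 1L || any(cfg$visit_probs < 0))
    stop_cfg("visit_probs", "must be nonnegative with at least one entry")
  ms <- cfg$mediator_spec
  if (nrow(ms) > 0) {
    if (any(ms$index < 1L | ms$index > cfg$n_metabolites))
      stop_cfg("mediator_spec", "every mediator index must be <= n_metabolites")
    if (anyDuplicated(ms$index))
      stop_cfg("mediator_spec", "mediator indices must be distinct")
    bad <- ms$role == "null_a" & ms$a != 0
    if (any(bad)) stop_cfg("mediator_spec", "null_a entries must have a = 0")
    bad <- ms$role == "null_b" & ms$b != 0
    if (any(bad)) stop_cfg("mediator_spec", "null_b entries must have b = 0")
  }
  if (any(cfg$missingness < 0 | cfg$missingness >= 1))
    stop_cfg("missingness", "fractions must be in [0, 1)")
  if (cfg$n_families < 1) stop_cfg("n_families", "must be >= 1")
  invisible(cfg)
}

## truncated-normal draws via the inverse-CDF of the conditioned normal
rtruncnorm <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

smoking_levels <- c("never", "former", "current")

#' Numeric coding of smoking status
#'
#' never = 0, former = 1, current = 2.
#' @param smoking character or factor vector of statuses.
#' @return integer vector.
#' @export
smoking_numeric <- function(smoking) {
  m <- match(as.character(smoking), smoking_levels)
  if (anyNA(m)) stop("unknown smoking status value")
  m - 1L
}

#' Generate a multilevel longitudinal cohort with known mediation structure
#'
#' Simulates sibship-nested individuals with repeated visits and four
#' cognitive composite outcomes (PACC3, IMM, DEL, EXE). Planted mediator
#' metabolites are generated per sample here (so outcomes can include the
#' mediator contribution jointly) and stored in the \code{"mediator_log"}
#' attribute; [generate_metabolome()] reuses them unchanged.
#'
#' Visits are indexed starting at 2 (baseline is visit two). Outcome
#' \eqn{y = X\beta + c' \cdot smoking + \sum_j b_j (M_j - \mu_j) +
#' u_{fam} + u_{ind} + s_{ind}(age - \bar{age}) + \epsilon}.
#'
#' @param config a [sim_config()].
#' @return list with components \code{cohort} (data.frame, one row per
#'   individual-visit) and \code{truth} (data.frame of per-metabolite true
#'   a, b, indirect effect and role, with the per-outcome direct effects in
#'   attribute \code{"direct_effect"}).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)
  cp <- config$covariate_params

  fam_sizes <- sample.int(length(config$family_size_probs), config$n_families,
                          replace = TRUE, prob = config$family_size_probs)
  n_ind <- sum(fam_sizes)
  family_id <- rep(sprintf("F%04d", seq_len(config$n_families)), fam_sizes)
  individual_id <- sprintf("I%05d", seq_len(n_ind))

  n_visits <- sample.int(length(config$visit_probs), n_ind,
                         replace = TRUE, prob = config$visit_probs)

  age0 <- rtruncnorm(n_ind, cp$age$mean, cp$age$sd, cp$age$min, cp$age$max)
  sex <- ifelse(stats::runif(n_ind) < cp$sex_female_prob, "F", "M")
  race <- ifelse(stats::runif(n_ind) < cp$race_white_prob, "white", "other")
  education <- as.integer(stats::runif(n_ind) < cp$education_prob)
  smoking0 <- sample(smoking_levels, n_ind, replace = TRUE,
                     prob = config$smoking_probs)
  bmi0 <- sample(names(cp$bmi_probs), n_ind, replace = TRUE,
                 prob = cp$bmi_probs)

  vc <- config$variance_components
  u_fam_by_fam <- stats::rnorm(config$n_families, 0, sqrt(vc[["family"]]))
  u_fam <- rep(u_fam_by_fam, fam_sizes)
  u_ind <- stats::rnorm(n_ind, 0, sqrt(vc[["individual"]]))
  s_ind <- stats::rnorm(n_ind, 0, sqrt(vc[["age_slope"]]))

  idx <- rep(seq_len(n_ind), n_visits)
  visit <- unlist(lapply(n_visits, function(k) seq.int(2L, 1L + k)),
                  use.names = FALSE)
  n_rows <- length(idx)
  age <- age0[idx] + (visit - 2L) * config$visit_spacing_years
  age_c <- age - cp$age$mean

  smoking <- smoking0[idx]
  if (config$smoking_time_varying) {
    ## per-visit transitions: initiation, quitting, relapse
    for (i in seq_len(n_ind)) {
      rows <- which(idx == i)
      if (length(rows) < 2) next
      st <- smoking0[i]
      for (r in rows[-1]) {
        u <- stats::runif(1)
        st <- switch(st,
          never   = if (u < 0.005) "current" else "never",
          current = if (u < 0.10) "former" else "current",
          former  = if (u < 0.02) "current" else "former")
        smoking[r] <- st
      }
    }
  }
  smk_num <- smoking_numeric(smoking)

  ## visit-varying confounders
  cesd <- round(rtruncnorm(n_rows, cp$cesd$mean, cp$cesd$sd,
                           cp$cesd$min, cp$cesd$max))
  al <- cp$alcohol
  shp <- al$mean^2 / al$sd^2
  alcohol <- round(stats::rgamma(n_rows, shape = shp, rate = shp / al$mean), 1)
  bmi <- bmi0[idx]

  ## planted mediator metabolites on the log10 scale, one value per sample
  ms <- config$mediator_spec
  n_med <- nrow(ms)
  mediator_log <- NULL
  med_contrib <- 0
  if (n_med > 0) {
    mu_j <- config$metabolite_mu[ms$index]
    u_met <- matrix(stats::rnorm(n_ind * n_med, 0, config$metabolite_ind_sd),
                    n_ind, n_med)
    e_met <- matrix(stats::rnorm(n_rows * n_med, 0, config$metabolite_resid_sd),
                    n_rows, n_med)
    mediator_log <- sweep(e_met + u_met[idx, , drop = FALSE], 2, mu_j, "+") +
      outer(smk_num, ms$a)
    colnames(mediator_log) <- sprintf("met_%03d", ms$index)
    med_contrib <- sweep(mediator_log, 2, mu_j, "-") %*% ms$b
  }

  ce <- config$covariate_effects
  fixed <- ce$intercept +
    ce$female * (sex[idx] == "F") +
    ce$white * (race[idx] == "white") +
    ce$college * education[idx] +
    ce$cesd * cesd +
    ce$bmi_underweight * (bmi == "underweight") +
    ce$bmi_overweight * (bmi == "overweight") +
    ce$bmi_obese * (bmi == "obese") +
    ce$alcohol * alcohol +
    config$age_coefs[["linear"]] * age_c +
    config$age_coefs[["quadratic"]] * age_c^2 +
    config$practice_effect * (visit - 2L)

  outcomes <- names(config$direct_effect)
  ranef_part <- u_fam[idx] + u_ind[idx] + s_ind[idx] * age_c
  ymat <- sapply(outcomes, function(o) {
    as.numeric(fixed + config$direct_effect[[o]] * smk_num + med_contrib +
                 ranef_part +
                 stats::rnorm(n_rows, 0, sqrt(vc[["residual"]])))
  })

  cohort <- data.frame(
    family_id = family_id[idx], individual_id = individual_id[idx],
    visit = visit, age = age,
    sex = sex[idx], race = race[idx], education = education[idx],
    cesd = cesd, bmi_category = bmi, alcohol_weekly = alcohol,
    smoking = smoking, stringsAsFactors = FALSE
  )
  cohort <- cbind(cohort, as.data.frame(ymat))
  cohort$sample_id <- paste(cohort$individual_id, cohort$visit, sep = "_v")
  attr(cohort, "mediator_log") <- mediator_log

  truth <- data.frame(
    metabolite = sprintf("met_%03d", seq_len(config$n_metabolites)),
    a = 0, b = 0, role = "noise", stringsAsFactors = FALSE
  )
  if (n_med > 0) {
    truth$a[ms$index] <- ms$a
    truth$b[ms$index] <- ms$b
    truth$role[ms$index] <- ms$role
  }
  truth$ie <- truth$a * truth$b
  ## suppressors must oppose the direct effect by construction
  de_sign <- sign(config$direct_effect[[1]])
  sup <- truth$role == "suppressor"
  if (any(sup) && any(sign(truth$ie[sup]) == de_sign | truth$ie[sup] == 0))
    stop("suppressor mediators must satisfy sign(a*b) != sign(direct effect)")
  attr(truth, "direct_effect") <- config$direct_effect

  list(cohort = cohort, truth = truth)
}

#' Generate the sample-by-metabolite abundance matrix
#'
#' Builds the full metabolite matrix for every cohort sample. Planted
#' mediator columns are copied verbatim from the values generated jointly
#' with the outcomes in [generate_cohort()]; remaining columns are baseline
#' plus individual-level and sample-level noise (plus an exposure effect for
#' null-b metabolites). Values are returned as strictly positive abundances
#' (10^log10-scale); missing entries are inserted per the configured
#' per-metabolite fractions (MCAR by default, lowest-abundance-first when
#' \code{missing_low_abundance} is set).
#'
#' @param cohort cohort data.frame from [generate_cohort()].
#' @param truth truth data.frame from the same call.
#' @param config the same [sim_config()].
#' @param fluid label stored in the sample metadata ("plasma" or "csf").
#' @return a [metab_matrix()] with one row per cohort sample.
#' @export
generate_metabolome <- function(cohort, truth, config, fluid = "plasma") {
  stopifnot(inherits(config, "sim_config"))
  if (any(config$mediator_spec$index > config$n_metabolites))
    stop("mediator index out of range")
  set.seed(config$seed + 1L)
  n_rows <- nrow(cohort)
  idx_ind <- match(cohort$individual_id, unique(cohort$individual_id))
  n_ind <- max(idx_ind)
  smk_num <- smoking_numeric(cohort$smoking)

  logm <- matrix(NA_real_, n_rows, config$n_metabolites,
                 dimnames = list(cohort$sample_id, truth$metabolite))
  u <- matrix(stats::rnorm(n_ind * config$n_metabolites, 0,
                           config$metabolite_ind_sd),
              n_ind, config$n_metabolites)
  e <- matrix(stats::rnorm(n_rows * config$n_metabolites, 0,
                           config$metabolite_resid_sd),
              n_rows, config$n_metabolites)
  for (j in seq_len(config$n_metabolites)) {
    logm[, j] <- config$metabolite_mu[j] + truth$a[j] * smk_num +
      u[idx_ind, j] + e[, j]
  }
  ## mediator columns come from the joint generation pass
  med <- attr(cohort, "mediator_log")
  if (!is.null(med)) logm[, colnames(med)] <- med

  abund <- 10^logm
  for (j in seq_len(config$n_metabolites)) {
    f <- config$missingness[j]
    if (f <= 0) next
    n_miss <- round(f * n_rows)
    if (n_miss == 0) next
    drop <- if (config$missing_low_abundance) {
      order(abund[, j])[seq_len(n_miss)]
    } else {
      sample.int(n_rows, n_miss)
    }
    abund[drop, j] <- NA_real_
  }

  metab_matrix(abund,
               data.frame(sample_id = cohort$sample_id,
                          individual_id = cohort$individual_id,
                          age = cohort$age,
                          fluid = fluid, stringsAsFactors = FALSE))
}

#' Cognitive composite from contributing raw test scores
#'
#' Each contributing test score is standardized to mean 0 and SD 1 across
#' subjects; tests where lower raw scores indicate better performance are
#' multiplied by -1 after standardization; the composite is the per-subject
#' mean of the standardized scores.
#'
#' @param raw_scores numeric matrix, subjects in rows, tests in columns.
#' @param lower_is_better logical vector, one flag per test (column).
#' @return numeric vector of composite scores, one per subject.
#' @export
compute_composite <- function(raw_scores, lower_is_better = NULL) {
  raw_scores <- as.matrix(raw_scores)
  if (ncol(raw_scores) < 1L) stop("at least one contributing test required")
  if (is.null(lower_is_better)) lower_is_better <- rep(FALSE, ncol(raw_scores))
  stopifnot(length(lower_is_better) == ncol(raw_scores))
  sds <- apply(raw_scores, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(raw_scores)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop(sprintf("zero-variance contributing test(s): %s",
                 paste(bad, collapse = ", ")))
  }
  z <- scale(raw_scores)
  z[, lower_is_better] <- -z[, lower_is_better, drop = FALSE]
  rowMeans(z)
}
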