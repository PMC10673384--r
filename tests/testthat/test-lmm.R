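test_that("with random structure disabled the fit equals OLS", {
  gen <- generate_cohort(small_config(seed = 21))
  d <- gen$cohort
  fit <- fit_lmm(d, model_spec("PACC3", exposure_coding = "numeric",
                               full = FALSE, random_family = FALSE,
                               random_individual = FALSE,
                               random_age_slope = FALSE))
  # reference OLS on the same design, built by hand
  d$age_c <- d$age - mean(d$age)
  ref <- lm(PACC3 ~ smoking_num + sex + race + education + age_c +
              I(age_c^2) + practice,
            data = transform(d, smoking_num = smoking_numeric(smoking),
                             sex = factor(sex, c("M", "F")),
                             race = factor(race, c("other", "white")),
                             practice = visit - 2))
  expect_equal(unname(fit$coefficients$beta), unname(coef(ref)),
               tolerance = 1e-8)
  expect_equal(fit$coefficients$se, unname(sqrt(diag(vcov(ref)))),
               tolerance = 1e-8)
  expect_equal(unname(fit$varcomp[c("family", "individual", "age_slope")]),
               c(0, 0, 0))
})

test_that("balanced one-way variance components match ANOVA closed form", {
  g <- 40; m <- 5
  set.seed(31)
  d <- data.frame(
    individual_id = rep(sprintf("G%02d", 1:g), each = m),
    family_id = "F1",
    y = rep(rnorm(g, sd = sqrt(2)), each = m) + rnorm(g * m, sd = 1))
  fit <- fit_lmm(d, model_spec("y", include_exposure = FALSE,
                               include_covariates = FALSE,
                               random_family = FALSE,
                               random_age_slope = FALSE))
  # method-of-moments estimators from the one-way ANOVA table
  gm <- tapply(d$y, d$individual_id, mean)
  msb <- m * sum((gm - mean(d$y))^2) / (g - 1)
  msw <- sum((d$y - gm[d$individual_id])^2) / (g * (m - 1))
  expect_equal(fit$varcomp[["residual"]], msw, tolerance = 1e-6)
  expect_equal(fit$varcomp[["individual"]], (msb - msw) / m,
               tolerance = 1e-6)
})

test_that("simulated fixed effects at n=2000 are recovered within 3 SE", {
  cfg <- sim_config(n_families = 430, n_metabolites = 4, seed = 17)
  gen <- generate_cohort(cfg)
  expect_gt(nrow(gen$cohort), 1500)
  fit <- fit_lmm(gen$cohort, model_spec("PACC3", exposure_coding = "numeric"))
  co <- fit$coefficients
  truth <- c(
    smoking_num = unname(cfg$direct_effect[["PACC3"]] +
                           sum(gen$truth$a * gen$truth$b)),
    sexF = cfg$covariate_effects$female,
    racewhite = cfg$covariate_effects$white,
    education = cfg$covariate_effects$college,
    cesd = cfg$covariate_effects$cesd,
    alcohol_weekly = cfg$covariate_effects$alcohol,
    age_c = unname(cfg$age_coefs[["linear"]]),
    practice = cfg$practice_effect)
  for (term in names(truth)) {
    row <- co[co$term == term, ]
    expect_lt(abs(row$beta - truth[[term]]), 3 * row$se)
  }
  expect_true(fit$converged)
  expect_true(all(fit$varcomp >= 0))
  expect_gte(fit$icc, 0); expect_lte(fit$icc, 1)
  expect_lte(fit$r2_marginal, fit$r2_conditional)
})

test_that("ICC and R2 are the stated variance ratios", {
  fake <- list(varcomp = c(family = 2, individual = 1, age_slope = 0.5,
                           residual = 1))
  expect_equal(icc(fake), 0.75)  # age-slope variance excluded
  expect_equal(icc(list(varcomp = c(family = 0, individual = 0,
                                    age_slope = 0, residual = 0))), 0)

  toy <- list(var_fixed = 3, random_variance_total = 1,
              varcomp = c(residual = 1))
  expect_equal(r2_nakagawa(toy), c(marginal = 0.6, conditional = 0.8))
  # limits: perfect fixed fit; pure random outcome
  expect_equal(r2_nakagawa(list(var_fixed = 4, random_variance_total = 0,
                                varcomp = c(residual = 0))),
               c(marginal = 1, conditional = 1))
  expect_equal(r2_nakagawa(list(var_fixed = 0, random_variance_total = 1,
                                varcomp = c(residual = 1))),
               c(marginal = 0, conditional = 0.5))
})

test_that("ICC and R2 match an independent variance decomposition", {
  # intercept-only mixed model: every variance is directly estimable
  g <- 60; m <- 4
  set.seed(55)
  d <- data.frame(
    individual_id = rep(sprintf("G%02d", 1:g), each = m),
    y = rep(rnorm(g, sd = 1.5), each = m) + rnorm(g * m, sd = 0.8))
  fit <- fit_lmm(d, model_spec("y", include_exposure = FALSE,
                               include_covariates = FALSE,
                               random_family = FALSE,
                               random_age_slope = FALSE))
  v <- fit$varcomp
  expect_equal(fit$icc, v[["individual"]] / (v[["individual"]] + v[["residual"]]))
  expect_equal(fit$r2_marginal,
               fit$var_fixed / (fit$var_fixed + v[["individual"]] + v[["residual"]]))
  expect_equal(fit$r2_conditional,
               (fit$var_fixed + v[["individual"]]) /
                 (fit$var_fixed + v[["individual"]] + v[["residual"]]))
  # generative values within broad simulation tolerance
  expect_lt(abs(fit$icc - 1.5^2 / (1.5^2 + 0.8^2)), 0.15)
})

test_that("scale equivariance: outcome * k scales betas and SEs, p fixed", {
  gen <- generate_cohort(small_config(seed = 33))
  d <- gen$cohort
  # exact on the closed-form OLS route
  o1 <- fit_lmm(d, ols_spec("PACC3"))
  d10 <- d; d10$PACC3 <- d10$PACC3 * 10
  o2 <- fit_lmm(d10, ols_spec("PACC3"))
  expect_equal(o2$coefficients$beta, 10 * o1$coefficients$beta,
               tolerance = 1e-8)
  expect_equal(o2$coefficients$se, 10 * o1$coefficients$se,
               tolerance = 1e-8)
  expect_equal(o2$coefficients$p, o1$coefficients$p, tolerance = 1e-8)
  # to optimizer tolerance on the iterative REML route
  f1 <- fit_lmm(d, model_spec("PACC3", exposure_coding = "numeric"))
  f2 <- fit_lmm(d10, model_spec("PACC3", exposure_coding = "numeric"))
  expect_equal(f2$coefficients$beta, 10 * f1$coefficients$beta,
               tolerance = 5e-3)
  expect_equal(f2$coefficients$se, 10 * f1$coefficients$se,
               tolerance = 5e-3)
  expect_equal(f2$coefficients$p, f1$coefficients$p, tolerance = 5e-3)
})

test_that("rank-deficient designs and tiny samples are explicit errors", {
  gen <- generate_cohort(flat_config(n = 100, seed = 3))
  d <- gen$cohort
  # single visit makes the practice term identically zero: collinear with
  # the intercept's null space, reported by name
  expect_error(
    fit_lmm(d, model_spec("PACC3", exposure_coding = "numeric",
                          full = FALSE, random_family = FALSE,
                          random_individual = FALSE,
                          random_age_slope = FALSE)),
    "practice")
  expect_error(fit_lmm(d[1, ], ols_spec("PACC3")), "2 individuals")
})

test_that("model comparison uses ML AIC with reduced on ties", {
  gen <- generate_cohort(small_config(seed = 44))
  spec <- model_spec("PACC3", full = FALSE)
  f <- fit_lmm(gen$cohort, spec)
  tie <- compare_fits(f, f)
  expect_identical(tie$choice, "reduced")
  expect_equal(tie$aic_reduced, tie$aic_full)

  # strong planted confounding through CES-D: full model wins
  cfg <- small_config(seed = 45,
                      covariate_effects = list(
                        intercept = -1, female = 0.5, white = 0.4,
                        college = 0.37, cesd = -0.08,
                        bmi_underweight = -0.2, bmi_overweight = 0.005,
                        bmi_obese = 0.03, alcohol = 0.05))
  gen2 <- generate_cohort(cfg)
  s1 <- step1_total_effect(gen2$cohort, "PACC3")
  expect_identical(s1$choice, "full")

  # pure-noise extra covariates: reduced wins
  cfg3 <- small_config(seed = 46,
                       covariate_effects = list(
                         intercept = -1, female = 0.5, white = 0.4,
                         college = 0.37, cesd = 0,
                         bmi_underweight = 0, bmi_overweight = 0,
                         bmi_obese = 0, alcohol = 0))
  gen3 <- generate_cohort(cfg3)
  s13 <- step1_total_effect(gen3$cohort, "PACC3")
  expect_identical(s13$choice, "reduced")

  expect_error(compare_fits(f, fit_lmm(gen$cohort[1:200, ], spec)),
               "observation")
})

test_that("Wald CIs for the smoking effect attain nominal coverage", {
  n_rep <- 200
  covered <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    cfg <- sim_config(n_families = 60, n_metabolites = 2,
                      mediator_spec = data.frame(index = integer(0),
                                                 a = numeric(0),
                                                 b = numeric(0),
                                                 role = character(0)),
                      seed = 5000 + r)
    gen <- generate_cohort(cfg)
    ## rare degenerate draws (e.g. an all-white small cohort) cannot be
    ## fitted with the race term; they carry no coverage information
    fit <- tryCatch(
      fit_lmm(gen$cohort, model_spec("PACC3", exposure_coding = "numeric",
                                     full = FALSE)),
      error = function(e) NULL)
    if (is.null(fit)) { covered[r] <- NA; next }
    row <- fit$coefficients[fit$coefficients$term == "smoking_num", ]
    truth <- cfg$direct_effect[["PACC3"]]
    covered[r] <- row$ci_low <= truth && truth <= row$ci_high
  }
  expect_gte(mean(covered, na.rm = TRUE), 0.91)
  expect_lte(mean(covered, na.rm = TRUE), 0.99)
})
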