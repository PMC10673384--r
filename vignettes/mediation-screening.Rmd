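---
title: "Mediation screening of high-dimensional metabolomics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mediation screening of high-dimensional metabolomics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medscreen)
```

# The scientific problem

Smoking is an established risk factor for cognitive decline, and untargeted
metabolomics offers a window into the biological pathways that might carry
that effect: if smoking shifts the abundance of a circulating metabolite and
that metabolite in turn is associated with cognitive performance, the
metabolite is a candidate *mediator* of the smoking–cognition relationship.
`medscreen` implements the full screening-and-decomposition workflow for
this question in longitudinal cohort data where individuals are nested in
sibships and observed over repeated visits, together with a synthetic-data
generator that makes every stage testable when the motivating cohort data
are restricted-access.

# The four-step procedure

The workflow is the classical product-of-coefficients approach, run as a
screen over hundreds or thousands of metabolites:

1. **Total effect.** For each cognitive outcome $Y$, fit a linear mixed
   model of $Y$ on smoking status $X$ and covariates; choose between a
   reduced covariate set (sex, race, education, centered age and its
   square, practice effect) and a full set (additionally CES-D depressive
   symptoms, BMI category, weekly alcohol) by AIC computed from
   maximum-likelihood refits. The smoking coefficient of the chosen model
   under numeric exposure coding is the total effect $c$.
2. **Exposure → mediator.** Regress each metabolite $M_j$ (log10
   abundance) on $X$ with the same covariates and random structure; the
   smoking slope is $a_j$. p-values are Benjamini–Hochberg adjusted
   within fluid, and metabolites with $q < 0.05$ survive.
3. **Mediator → outcome.** For each survivor, regress $Y$ on $X$ and
   $M_j$ jointly; the metabolite slope is $b_j$. BH adjustment runs
   within fluid × outcome across the candidate set. The cascade only ever
   narrows: no metabolite reaches step 3 without passing step 2, or step
   4 without passing step 3.
4. **Decomposition.** For each surviving pair, the indirect effect is
   $IE = a_j b_j$, the direct effect is the smoking coefficient $c'$ from
   the step-3 model, and a Monte-Carlo confidence interval is attached to
   $IE$ by drawing $a^* \sim N(\hat a, \mathrm{se}_a^2)$,
   $b^* \sim N(\hat b, \mathrm{se}_b^2)$ independently and taking
   empirical quantiles of $a^* b^*$. The proportion mediated is reported
   as $IE/(IE+DE)$ (with $IE/c$ alongside), and each pair is classified
   `none` / `partial` / `complete` / `inconsistent`.

For nested ordinary-least-squares fits on identical rows the decomposition
is exactly additive, $c = ab + c'$; with mixed models or differing
complete-case sets a small additivity gap can open up, and the package
records it rather than hiding it.

## The mixed model

All models share the structure

$$y_{fit} = \mathbf{x}_{fit}'\beta + u_f + v_i + s_i\,(\mathrm{age}_{fit} -
\overline{\mathrm{age}}) + \varepsilon_{fit},$$

with a random intercept $u_f$ for family, a random intercept $v_i$ and a
random age slope $s_i$ for individual, fitted by REML through `lme4`. The
slope–intercept covariance is estimated freely by default
(`correlated_slope = FALSE` forces it to zero; the mode is recorded in the
fit). Models of CSF metabolites drop the family intercept — CSF subsamples
typically contain too few related individuals to identify it.

Choices the data could not make for us, fixed once and documented here:

* **Inference.** Wald $z$ statistics and normal-quantile confidence
  intervals per coefficient. No Satterthwaite or Kenward–Roger degrees of
  freedom; at the cohort sizes this workflow targets (hundreds of
  individuals, thousands of observations) the difference is negligible.
* **Model comparison.** AIC from ML refits, because REML likelihoods are
  not comparable across fixed-effect structures. An exact tie returns the
  reduced model.
* **ICC.** (family + individual intercept variance) / (those + residual).
  The age-slope variance is excluded so the ICC keeps its interpretation
  as the correlation between two observations of the same individual at
  the centering age.
* **R².** Variance-decomposition marginal and conditional R²: the
  random-effect variance term is the mean observation-level variance
  contributed by the random effects, which for the random slope includes
  $2\,\mathrm{cov}(v,s)\,\overline{\mathrm{age}_c} +
  \mathrm{var}(s)\,\overline{\mathrm{age}_c^2}$ and reduces to the sum of
  intercept variances for intercept-only structures.
* **Exposure coding.** Step 1 reports categorical smoking (never as
  reference, separate former/current coefficients); steps 2–4 use numeric
  coding never = 0, former = 1, current = 2, which matches the
  single-path diagram of the product method. Both codings are available
  everywhere.
* **Degenerate designs.** A rank-deficient fixed design (including a
  factor with a single observed level) is an error naming the offending
  terms; unused factor levels are dropped. Optimizer non-convergence is
  reported in the fit object, never silently; a boundary (singular) fit is
  treated as a valid estimate with a flag.

## Quality control

The QC cascade runs in a fixed order: metabolite missingness, sample
missingness, zero-IQR, log10 transform. Both missingness comparisons are
*strictly* greater-than their thresholds (0.50 for metabolites, 0.40 for
samples), so boundary cases are retained. The order matters — dropping a
high-missingness sample can turn a metabolite's IQR to zero — and the test
suite pins it down with a matrix constructed to flip exactly that way.
IQR uses type-7 (linear-interpolation) quantiles; only the distinction
IQR $= 0$ versus $> 0$ matters, which is insensitive to the quantile rule
for the constant columns it is meant to catch. Metabolites with fewer than
two observed values are removed as degenerate and logged. Residual missing
values are left missing and handled per-model by complete-case analysis;
an optional half-minimum imputation mode exists as a sensitivity check.
Fluid samples collected off-schedule are matched to the same individual's
nearest visit by age, ties resolved toward the earlier visit.

## FDR families

Step 2 adjusts within fluid across metabolites; step 3 adjusts within
fluid × outcome across candidates. Plasma and CSF p-values are never pooled
into one family. The family structure is recorded in the run metadata so a
reader of the outputs can see exactly what was adjusted over.

## Monte-Carlo confidence intervals

The CI for $a b$ assumes zero covariance between $\hat a$ and $\hat b$ —
they come from separate models, the standard assumption for this
construction. The default is 100,000 draws; the interval is deterministic
given a seed, and the test suite checks the quantiles against a numerical
integration of the exact product-of-normals distribution (conditioning on
one factor and integrating the conditional normal CDF), to half a percent
of the interval width at $10^6$ draws. The proportion mediated is reported
only when $IE$ and $DE$ agree in sign; with opposite signs the mediator
acts as a suppressor, the proportion has no meaningful interpretation, and
the pair is classified `inconsistent`.

# The synthetic cohort generator

`sim_config()` + `generate_cohort()` + `generate_metabolome()` emulate the
structure of a late-midlife observational cohort: sibships of 1–3
individuals (mean ≈ 1.25), one to six visits per individual (mean ≈ 3.7,
visits indexed from 2 because key variables first appear at the second
study visit), age at baseline ~ N(58.5, 6.47²) truncated to [40.7, 75.0]
years, 70.4% female, 94.8% white, 61.4% college-educated, smoking split
56.2/37.0/6.8% across never/former/current, CES-D ≈ 7 (SD 7), BMI
categories 0.6/27.8/35.5/36.1%, gamma-distributed weekly alcohol with
mean 4.25. The default variance components (family 0.10, individual 0.15,
age-slope 10⁻⁴, residual 0.07) put the intraclass correlation near 0.78
and the composite SDs near 0.8, matching the scale of standardized
cognitive composites in such cohorts. Smoking is a time-constant
individual attribute by default; a flag enables per-visit initiation,
quitting and relapse at small probabilities, since longitudinal status
changes are plausible but their rates are not identifiable from a single
baseline table.

Metabolites live on the log10-abundance scale (stored as strictly positive
abundances $10^{\log M}$, so the QC transform round-trips): baseline mean
3, individual-level SD 0.25, sample-level SD 0.15, exposure effect
$a_j \times$ numeric smoking. Planted mediators feed back into the
outcomes as $b_j (\log M - \mu_j)$; mediator values are generated jointly
with the cohort (one value per sample, stored with the cohort) so the
outcome and the metabolome are consistent, and `generate_metabolome()`
reuses them verbatim. A planted "suppressor" must satisfy
$\mathrm{sign}(a b) \ne \mathrm{sign}(c')$ and this is asserted at
generation time. Missingness is MCAR per metabolite by default, with an
abundance-dependent (lowest-first) mode for stressing QC.

Cognitive composites are the mean of standardized contributing test
scores, with lower-is-better tests sign-flipped after standardization —
the mean is the conventional combiner for such composites.

**What the generator does not emulate:** assay batch structure and drift,
abundance-dependent measurement error, correlated metabolite modules,
informative dropout, practice effects that plateau, or exposure
measurement error. Passing tests therefore demonstrate that the
*statistical machinery* is correct and calibrated under a faithful
multilevel generative model — not that any particular real-data finding
is reproducible.

Note one structural fact the workflow inherits from single-mediator
decomposition: when several planted pathways run through the same
exposure, the direct effect of any one mediator's model absorbs the
others' indirect paths. The bundled analysis scripts therefore plant a
single mediated pathway per cohort when demonstrating clean recovery, and
demonstrate the suppressor pattern on its own cohort.

# Problem sizes and seeds

The test suite and the acceptance script run everything from scratch at
sizes chosen to give stable Monte-Carlo behavior: QC accounting on
412 × 372 and 1275 × 2500 matrices, BH-FDR oracle equivalence on all
19,530 p-vectors of length ≤ 6 over a fixed five-point grid, additivity on
100 random single-level datasets, CI coverage over 500 replicates at
n = 1000, path recovery over 40 replicates at n = 2000, suppressor
classification over 30 replicates at n = 1000, FDR control over 60
all-null replicates of 30 metabolites, Wald-CI coverage of the smoking
effect over 200 simulated multilevel cohorts of 120 sibships, and an
end-to-end multilevel pipeline of 250 sibships × 20 metabolites. Every
stochastic step takes an explicit seed and is reproducible bit-for-bit.

# Known limitations

* Single-mediator models only: no joint multiple-mediator model, no
  exposure–mediator interaction, no counterfactual (natural effect)
  estimands, and no sensitivity analysis for sequential ignorability.
* The Monte-Carlo CI ignores $\mathrm{cov}(\hat a, \hat b)$; with shared
  covariates across the two models this covariance is typically tiny but
  not exactly zero.
* Wald inference may be anti-conservative in very small cohorts.
* BH-FDR assumes the usual positive-dependence conditions across
  metabolite tests.
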