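# Independent oracles used across the suite. These deliberately avoid the
# code paths they check.

# Step-up FDR adjustment written as the literal definition: sort ascending,
# q(i) = min over j >= i of p(j) * m / j, capped at 1, original order.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- ps[i:m] * m / (i:m)
    q[i] <- min(1, min(cand))
  }
  out <- numeric(m)
  out[ord] <- q
  out
}

# CDF of the product of two independent normals X ~ N(a, sa^2),
# Y ~ N(b, sb^2), by conditioning on X and integrating numerically.
prodnorm_cdf <- function(t, a, sa, b, sb) {
  f <- function(x) {
    g <- ifelse(x > 0, stats::pnorm(t / x, b, sb),
                ifelse(x < 0, 1 - stats::pnorm(t / x, b, sb),
                       as.numeric(t >= 0)))
    stats::dnorm(x, a, sa) * g
  }
  stats::integrate(f, a - 10 * sa, a + 10 * sa, rel.tol = 1e-9,
                   subdivisions = 400L)$value
}

# Quantile of the product-of-normals distribution by root finding.
prodnorm_quantile <- function(prob, a, sa, b, sb) {
  hw <- (abs(a) + 10 * sa) * (abs(b) + 10 * sb)
  stats::uniroot(function(t) prodnorm_cdf(t, a, sa, b, sb) - prob,
                 lower = -hw, upper = hw, tol = 1e-8)$root
}

# Small cohort configuration used by most simulation tests.
small_config <- function(seed = 1, ...) {
  sim_config(n_families = 120, n_metabolites = 10, seed = seed, ...)
}

# Single-visit, no-random-effect configuration: every individual is its own
# family with one visit, so the OLS fitting route is exact and fast.
flat_config <- function(n = 1000, seed = 1, ...) {
  sim_config(n_families = n, family_size_probs = 1, visit_probs = 1,
             variance_components = c(family = 0, individual = 0,
                                     age_slope = 0, residual = 0.07),
             seed = seed, ...)
}

# Generate, QC (no-op filters at zero missingness) and merge a flat cohort;
# returns the merged modelling table plus the truth record.
flat_merged <- function(cfg) {
  gen <- generate_cohort(cfg)
  mm <- generate_metabolome(gen$cohort, gen$truth, cfg)
  qc <- run_qc(mm)
  list(merged = merge_metabolites(gen$cohort, qc$matrix),
       truth = gen$truth, cohort = gen$cohort)
}

# model_spec shorthand for the OLS route on flat cohorts.
ols_spec <- function(outcome, ...) {
  model_spec(outcome, exposure_coding = "numeric",
             include_covariates = FALSE,
             random_family = FALSE, random_individual = FALSE,
             random_age_slope = FALSE, ...)
}
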