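#!/usr/bin/env Rscript
# 03 - Screening steps 1-3.
#
# Step 1: total effect of smoking on each cognitive composite, choosing
#         between the reduced and the confounder-adjusted (full) mixed
#         model by ML-based AIC.
# Step 2: numeric smoking -> each metabolite, BH-FDR within the plasma
#         family.
# Step 3: metabolite -> outcome adjusted for smoking, among Step-2
#         survivors, BH-FDR within outcome.
# All models carry family/individual random intercepts and an individual
# random age slope.

suppressPackageStartupMessages(library(medscreen))

dat <- "results/data"
res_dir <- "results"
cohort <- read.delim(file.path(dat, "cohort.tsv"))
mm <- read_metab_matrix(file.path(dat, "plasma_qc_abundance.tsv"),
                        file.path(dat, "plasma_qc_samples.tsv"))
merged <- merge_metabolites(cohort, mm)
outcomes <- c("PACC3", "IMM", "DEL", "EXE")

## Step 1
cat("== Step 1: total effects and model choice ==\n")
step1 <- lapply(outcomes, function(o) step1_total_effect(cohort, o))
names(step1) <- outcomes
for (o in outcomes) {
  s <- step1[[o]]
  cur <- s$smoking[s$smoking$term == "smokingcurrent", ]
  cat(sprintf("%-6s choice=%-7s current-smoker beta=%+.3f (p=%.3g) ICC=%.2f R2=%.2f/%.2f\n",
              o, s$choice, cur$beta, cur$p, s$chosen$icc,
              s$chosen$r2_marginal, s$chosen$r2_conditional))
}
use_full <- any(vapply(step1, `[[`, "", "choice") == "full")
cat(sprintf("covariate set for steps 2-4: %s\n",
            if (use_full) "full" else "reduced"))
step1_tab <- do.call(rbind, lapply(outcomes, function(o) {
  co <- step1[[o]]$chosen$coefficients
  co$outcome <- o
  co
}))
write.table(step1_tab, file.path(res_dir, "step1_coefficients.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

## Step 2
cat("== Step 2: exposure -> metabolite screen ==\n")
s2 <- step2_metabolite_screen(merged, fluid = "plasma", full = use_full)
cat(sprintf("%d of %d metabolites pass FDR < 0.05\n",
            sum(s2$passed), nrow(s2)))
write.table(s2, file.path(res_dir, "step2_plasma.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

## Step 3
cat("== Step 3: mediator -> outcome screen ==\n")
survivors <- s2$metabolite[s2$passed]
s3 <- do.call(rbind, lapply(outcomes, function(o)
  step3_outcome_screen(merged, survivors, o, fluid = "plasma",
                       full = use_full)))
cat(sprintf("%d metabolite-outcome pairs pass FDR < 0.05\n",
            sum(s3$passed)))
print(s3[s3$passed, c("metabolite", "outcome", "beta", "p", "q")],
      row.names = FALSE, digits = 3)
write.table(s3, file.path(res_dir, "step3_plasma.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
jsonlite::write_json(
  list(use_full = use_full,
       fdr_families = list(step2 = "within fluid",
                           step3 = "within fluid x outcome"),
       step2_survivors = survivors),
  file.path(res_dir, "screen_metadata.json"),
  auto_unbox = TRUE, pretty = TRUE)
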