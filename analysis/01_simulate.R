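#!/usr/bin/env Rscript
# 01 - Simulate the study cohort and plasma metabolome.
#
# Generates a sibship-nested longitudinal cohort (visits indexed from 2,
# baseline at visit two) with four cognitive composite outcomes, and a
# plasma metabolome with three planted truths among noise metabolites:
# one consistent mediator (a = 0.4, b = -0.3), one null-a and one null-b
# metabolite. A single mediated pathway keeps every single-mediator
# decomposition in step 04 uncontaminated (a suppressor pathway is
# demonstrated separately there). Writes the tables the later stages read.

suppressPackageStartupMessages(library(medscreen))

out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(n_families = 400, n_metabolites = 30,
                  mediator_spec = data.frame(
                    index = 1:3,
                    a = c(0.40, 0.00, 0.40),
                    b = c(-0.30, -0.30, 0.00),
                    role = c("mediator", "null_a", "null_b")),
                  missingness = 0.02, seed = 20260101 %% 1e6)

gen <- generate_cohort(cfg)
mm <- generate_metabolome(gen$cohort, gen$truth, cfg, fluid = "plasma")

n_ind <- length(unique(gen$cohort$individual_id))
cat(sprintf("cohort: %d rows, %d individuals, %.2f visits/individual\n",
            nrow(gen$cohort), n_ind, nrow(gen$cohort) / n_ind))

rp <- descriptive_report(gen$cohort)
smo <- rp$categorical[rp$categorical$variable == "smoking", ]
cat("baseline smoking split:\n")
print(transform(smo[, c("level", "count")],
                percent = round(smo$percent, 1)), row.names = FALSE)

write.table(gen$cohort, file.path(out, "cohort.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write_metab_matrix(mm, file.path(out, "plasma_abundance.tsv"),
                   file.path(out, "plasma_samples.tsv"))
jsonlite::write_json(gen$truth, file.path(out, "truth.json"),
                     dataframe = "rows", pretty = TRUE)
jsonlite::write_json(rp, file.path(out, "descriptives.json"),
                     dataframe = "rows", auto_unbox = TRUE, pretty = TRUE)

cat(sprintf("wrote cohort + metabolome + truth to %s/\n", out))
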