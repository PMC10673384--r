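#!/usr/bin/env Rscript
# 02 - Metabolite quality control.
#
# Applies the QC cascade to the simulated plasma matrix: drop metabolites
# with missingness > 50%, drop samples with missingness > 40%, drop
# zero-IQR metabolites, then log10-transform. Writes the QC'd matrix and
# the accounting report.

suppressPackageStartupMessages(library(medscreen))

dat <- "results/data"
mm <- read_metab_matrix(file.path(dat, "plasma_abundance.tsv"),
                        file.path(dat, "plasma_samples.tsv"))
cat("input: "); print(mm)

res <- run_qc(mm, qc_config())
print(res$report)

write_metab_matrix(res$matrix, file.path(dat, "plasma_qc_abundance.tsv"),
                   file.path(dat, "plasma_qc_samples.tsv"))
jsonlite::write_json(res$report[1:7], file.path(dat, "qc_report.json"),
                     auto_unbox = TRUE, pretty = TRUE)
cat(sprintf("wrote QC'd matrix (log10 scale) to %s/\n", dat))
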