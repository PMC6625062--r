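#!/usr/bin/env Rscript
# Stage 4 — longitudinal marker classification.
#
# Per patient: cfDNA change class between baseline and first follow-up
# (decrease > 50% / stable / increase > 50%), ctDNA detectability and
# strict increase at first follow-up, binary TMB view, and the combined
# TMB x marker variables used in place of multivariate models.

library(tmbliquid)

cohort <- read_cohort("results/simulated_cohort")
tmb <- read.delim("results/tmb_per_sample.tsv")
ctdna <- read.csv("results/ctdna_measurements.csv")
cl <- classify_cohort(cohort$patients, tmb, cohort$cfdna, ctdna)
out <- cl
out$tmb_category <- as.character(out$tmb_category)
write.csv(out, "results/classification.csv", row.names = FALSE)

cat("classified", nrow(cl), "patients -> results/classification.csv\n")
cat("  analyzable denominators: TMB", sum(!is.na(cl$tmb_high)),
    "| ctDNA detection", sum(!is.na(cl$ctdna_detectable_fu)),
    "| ctDNA increase", sum(!is.na(cl$ctdna_increasing)),
    "| cfDNA change", sum(!is.na(cl$cfdna_change)), "\n")
print(table(cfdna_change = cl$cfdna_change, response = cl$response))
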