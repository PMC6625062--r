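#!/usr/bin/env Rscript
# Stage 1 — simulate a synthetic melanoma immunotherapy cohort.
#
# Draws a 35-patient cohort under the default study-like conditions
# (lognormal TMB with median 4.7 Mut/Mb, covariate prevalences of the
# clinical table, droplet-level ddPCR rendering of baseline and day-23
# ctDNA) and writes the raw tables every later stage consumes.

library(tmbliquid)

params <- simulation_params(n_patients = 35, seed = 101)
cohort <- generate_cohort(params)
write_cohort(cohort, "results/simulated_cohort")

pts <- cohort$patients
cat("simulated", nrow(pts), "patients ->", "results/simulated_cohort\n")
cat(sprintf("  responders: %d (%.0f%%)\n", sum(pts$response == "responder"),
            100 * mean(pts$response == "responder")))
cat(sprintf("  TMB median %.1f Mut/Mb (IQR %.1f-%.1f), %d QC failures\n",
            median(pts$tmb_true), quantile(pts$tmb_true, 0.25),
            quantile(pts$tmb_true, 0.75), sum(!pts$tmb_qc_pass)))
cat(sprintf("  ddPCR wells: %d, cfDNA measurements: %d\n",
            nrow(cohort$wells), nrow(cohort$cfdna)))
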