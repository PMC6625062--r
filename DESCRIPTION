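Package: tmbliquid
Title: Tumor Mutation Burden and Liquid-Biopsy Biomarkers for Combined
    Immunotherapy in Melanoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Panel-based tumor mutation burden (TMB) estimation with
    extrapolation from a targeted gene panel to the whole coding exome,
    Poisson quantification of circulating tumor DNA (ctDNA) from digital
    droplet PCR (ddPCR) droplet counts, longitudinal classification of
    cell-free DNA and ctDNA dynamics between therapy baseline and first
    follow-up, and the cohort-level association and survival statistics
    (exact Fisher test, exact Monte-Carlo chi-square test for trend,
    Wilcoxon rank-sum, Kaplan-Meier with log-rank and log-rank for trend)
    used to relate these biomarkers to response and melanoma-specific
    survival under combined CTLA-4/PD-1 antibody therapy. Includes a
    synthetic-cohort simulator with droplet-level ddPCR rendering and a
    deterministic golden fixture cohort for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    ggplot2
Config/testthat/edition: 3
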