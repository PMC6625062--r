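# tmbliquid

Biomarker analysis for metastatic melanoma under combined CTLA-4/PD-1
antibody therapy (ipilimumab + nivolumab). About half of these patients do
not respond, and severe toxicity is common, so early markers of
response are clinically valuable. `tmbliquid` implements the two marker
families such studies rely on, plus the statistical layer that relates
them to response and melanoma-specific survival:

- **Tumor mutation burden (TMB)** from a targeted 710-gene panel
  (2.1 Mb of coding sequence), extrapolated to the whole coding exome.
  With `P` passenger and `D` driver mutations (coding variants —
  synonymous included — of class SNV, InDel or essential splice, with
  variant allele fraction ≥ 10%, after subtracting matched-normal calls):

  `TMB = (P · E/S + D) / E  =  P/S + D/E   [Mut/Mb]`

  where `S` = 2.1 Mb is the panel and `E` = 35 Mb the exome coding size.
  Passengers are assumed uniformly distributed over the coding genome and
  are scaled up; drivers are assumed confined to the tumor-associated
  panel genes and are not. Categories: low < 3.3, intermediate 3.3–23.1,
  high > 23.1 Mut/Mb.

- **Liquid-biopsy markers** from digital droplet PCR (ddPCR). With `k` of
  `n` droplets positive, the reaction concentration is the Poisson
  estimate `λ/v = −ln(1 − k/n)/v` (v = 0.85 nl droplet volume), converted
  to tumor-specific variant copies per ml plasma through the assay
  volumes. ctDNA is *detected* at ≥ 3 positive droplets — an analytic
  detection limit of `3/(5 ng · 1000/3.3 pg) ≈ 0.2%` allele fraction at
  the standard 5 ng input. Between baseline and first follow-up (~3 weeks)
  each patient is classified by cfDNA change (decrease > 50% / stable /
  increase > 50%) and by ctDNA detectability and strict increase.

- **Cohort statistics**: two-sided Fisher exact test (hypergeometric
  enumeration, probability ordering), exact chi-square test for trend
  (linear-by-linear statistic, Monte-Carlo permutation with the
  (b+1)/(reps+1) estimator), Wilcoxon rank-sum, Kaplan-Meier with
  log-rank and log-rank for trend, and ordered *combined variables*
  (binary TMB × each liquid-biopsy/clinical marker) used in place of
  multivariate models that do not converge at n = 35. No
  multiple-testing adjustment is applied.

A synthetic-cohort simulator (`generate_cohort()`) renders every raw
layer — variant tables with germline/low-VAF/non-coding decoys,
droplet-level ddPCR counts, cfDNA concentrations, censored survival — and
a deterministic golden cohort (`fixture_golden_cohort()`) reproduces every
published contingency count end to end.

## Worked example

```r
library(tmbliquid)

cohort <- fixture_golden_cohort()          # deterministic 35-patient cohort
res <- analyze_cohort(cohort, mc_reps = 1e5, seed = 17)

res$denominators
#> n_patients        tmb  ctdna_detection  ctdna_increase  cfdna_change
#>         35         30               32              31            31

subset(res$marker_table, !is.na(p_response),
       c(characteristic, level, responder, non_responder, p_response))
#>                        characteristic          level responder non_responder p_response
#>                          TMB [Mut/Mb]           > 23         6             0    0.00156
#>    ctDNA detection at first follow-up Not detectable        10             4    0.01100
#>     ctDNA increase at first follow-up Not increasing        12             8    0.00845
#>                  Cell-free DNA change Decrease > 50%         5             2    0.02067
#>                 LDH baseline elevated             No        11            10    0.29580
#>               Targeted therapy before             No        12            13    0.45819
#>                                   Sex           Male        11             8    0.08656
#>             Liver metastasis baseline             No        14            11    0.02195
#>                      PD-L1 expression          >= 1%         6             4    0.08050
```

Five samples fail sequencing QC (TMB missing, never zero), three patients
lack a follow-up plasma sample and one lacks the baseline sample — hence
the varying denominators. TMB-high (> 23.1 Mut/Mb), undetectable ctDNA
and non-increasing ctDNA at first follow-up, cfDNA decrease > 50%, and
absent liver metastases are each associated with response (p < 0.05);
no patient with TMB ≤ 23.1 and detectable or increasing ctDNA responded.

The numbered scripts under `analysis/` run the same stages as a workflow
(`01` simulate → `02` TMB → `03` ddPCR → `04` classify → `05` statistics),
writing their tables under `results/`.

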