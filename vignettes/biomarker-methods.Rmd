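---
title: "TMB and liquid-biopsy biomarkers: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TMB and liquid-biopsy biomarkers: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmbliquid)
```

`tmbliquid` analyses two biomarker families in metastatic melanoma
patients starting combined CTLA-4/PD-1 antibody therapy — tumor mutation
burden measured once from tumor tissue, and liquid-biopsy dynamics
(total cell-free DNA and circulating tumor DNA) between the start of
therapy and the first follow-up about three weeks later — and relates
them to radiologic response and melanoma-specific survival. This
vignette is the package's account of the underlying models, the
parameters that matter, and the choices made where the design was
genuinely open.

## Panel TMB with exome extrapolation

TMB is the density of somatic coding mutations. From a targeted panel,
the count must be extrapolated to the exome, and the package does this
with an asymmetric rule that reflects how mutations arise:

* **Passenger** mutations accrue roughly uniformly over the coding
  genome, so the panel count `P` scales with coding size: a panel of
  `S` Mb sees the fraction `S/E` of what an `E`-Mb exome would.
* **Driver** mutations are concentrated in the tumor-associated genes a
  cancer panel is designed around, so the driver count `D` is taken at
  face value and *not* scaled.

Normalizing the extrapolated total to the exome gives
`TMB = (P·E/S + D)/E = P/S + D/E` Mut/Mb. The estimator is linear in
each count, collapses to `(P+D)/S` when `E = S`, and ties drivers'
contribution to the exome size only through the normalization.

Counting rules: a variant qualifies if it is tumor-private (its
chrom/pos/ref/alt key absent from the matched normal — a different
alternate allele at the same site is a different key), coding
(synonymous **and** non-synonymous; deep-intronic and other non-coding
changes are excluded), of class SNV, InDel or essential splice, and has
variant allele fraction **≥ 10%**. The threshold is read as inclusive
("a minimum of 10%" is an attained minimum). The VAF filter is applied
to all variants before the driver/passenger split; driver status is an
input annotation (per-variant flag or a driver-gene list), never
inferred, because no driver catalogue is canonical. Whether an
"essential splice" change means exactly the ±2 dinucleotide is likewise
left to the upstream annotation.

Parameters and defaults: panel size `S = 2.1` Mb (a 710-gene panel),
exome size `E = 35` Mb — a conventional coding-exome figure, configurable
because annotation releases differ and no single value is canonical.
Category cutoffs 3.3 and 23.1 Mut/Mb with the printed interval
"3.3–23.1" read as closed: 3.3 and 23.1 are intermediate, high is
strictly above 23.1. This reading keeps a non-responder at 17.3 Mut/Mb
below "high" and is consistent with a cohort in which every responder
above the cutoff exceeds it clearly. Samples failing sequencing QC carry
`qc_pass = FALSE` and a missing TMB — never zero — and drop out of each
analysis separately.

## ddPCR quantification

Digital droplet PCR partitions a reaction into ~20,000 droplets. Under
Poisson loading, the per-droplet occupancy is `λ = −ln(1 − k/n)` when
`k` of `n` droplets are positive, and the reaction concentration is
`λ/v` with `v` the droplet volume. The estimate exceeds the naive
`k/(nv)` because a positive droplet may hold several copies. Back-
calculation to plasma multiplies by the reaction volume, divides by the
eluate fraction loaded and by the plasma volume extracted. Replicate
wells are merged by summing counts before estimation.

Defaults follow the QX200 convention: 0.85 nl droplets, 20 µl
reactions, 4 ml plasma, 5 ng cfDNA input. None of these are universal,
so all are configuration with the defaults stated; every worked example
in the documentation states the volumes it uses.

Detection requires **≥ 3 mutant-positive droplets** in the merged
measurement (the threshold is applied after merging; whether a published
"three independent observations" means per well or per merged
measurement is ambiguous, and per-measurement is the stricter, simpler
reading). Wild-type droplets never affect detection. With `m` ng of
input there are about `m·1000/3.3` haploid genome copies in the
reaction (3.3 pg per copy), so the analytic limit of detection is
`3/(m·1000/3.3)` — 0.198% ≈ 0.2% at 5 ng. Measurements below threshold
report 0 copies/ml for classification but keep the raw Poisson estimate
for audit. A *saturated* channel (every droplet positive) has no finite
estimate; the pipeline quantifies it half a droplet below saturation,
flags it, and warns that the value is a lower bound, while the
low-level estimator treats saturation as an error.

## Longitudinal classification

The first follow-up sample is the earliest measurement in a 14–42 day
window — our bracket around the typical ~3-week (IQR 21–29 day) first
liquid-biopsy follow-up, configurable.

* **cfDNA change**: decrease > 50%, stable, or increase > 50% of the
  baseline concentration. "More than 50%" is strict, so a change of
  exactly ±50% is stable.
* **ctDNA detectability** at follow-up is the detection call alone.
* **ctDNA increase** requires follow-up copies/ml *strictly* above
  baseline, with undetected measurements counted as 0 copies/ml; a
  patient undetectable at both timepoints is not increasing. An
  undetected follow-up can therefore never be "increasing". Whether the
  original analysis required crossing the detection threshold instead of
  a raw-copy increase is not recoverable; strict inequality on reported
  copies is our reading.

Patients missing a baseline or follow-up sample get missing marker
values and are excluded per analysis (never imputed), which is why the
denominators differ across markers (30 with TMB, 32 with a detection
call, 31 with increase and cfDNA-change calls in the 35-patient golden
cohort).

**Combined variables** cross the binary TMB view (> 23.1 vs ≤ 23.1
Mut/Mb) with each of ctDNA detectability, ctDNA increase, cfDNA change,
liver metastases and sex, ordered best-prognosis-first in the
conventional table row order. They stand in for multivariate models,
which do not converge at this cohort size. Levels never observed (e.g.
TMB-high with liver metastases) are dropped rather than carried as
empty rows. A missing component yields a missing combined label.

## Statistical layer

* **Fisher exact test** (2×2, two-sided): conditional on both margins
  the first cell is hypergeometric; the p-value sums the probabilities
  of all tables no more probable than the observed one (probability
  ordering, with a `1 + 1e-7` relative tolerance for floating-point
  ties). This rule reproduces the published 0.002 / 0.011 / 0.008 /
  0.022 values, as verified by enumeration.
* **Exact chi-square test for trend** (k×2 ordered): the linear-by-
  linear statistic `(n−1)r²` — equivalently `(T − E[T])²/Var[T]` for the
  score total `T` of the first column — with equally spaced integer
  scores over the rows in table order. Because the statistic is a fixed
  monotone transform of `|T − E[T]|` once margins are fixed, the
  permutation null is sampled as random tables with fixed margins
  (Patefield's algorithm via `r2dtable`), and the p-value uses the
  add-one estimator `(b+1)/(reps+1)`, which is never exactly 0. The
  exact Monte-Carlo settings of the original SPSS analysis are
  unreported; agreement is to printed precision with ≥ 10^5
  permutations and a fixed seed.
* **Wilcoxon rank-sum** for TMB by response: exact enumeration for
  small untied samples, normal approximation with tie correction
  otherwise (`stats::wilcox.test`).
* **Survival**: Kaplan-Meier product-limit curves (melanoma-specific:
  deaths from other causes are censored), the k-sample log-rank test,
  and for 3+ ordered groups the log-rank test for trend
  `(s'(O−E))²/(s'Vs)` built from `survival::survdiff`'s observed-minus-
  expected vector and covariance. P-values use the asymptotic
  chi-square reference, the default of the original software.
* No multiple-testing adjustment, matching the original analysis; the
  package reports unadjusted p-values and leaves any correction to the
  caller.

## Synthetic cohort

Patient-level data for such studies are typically unavailable, so the
simulator renders every raw layer the pipeline consumes, under one
master seed with per-patient sub-streams (so partial reruns are
stable). Defaults, chosen once to match the published cohort summaries:

* TMB lognormal with meanlog `log(4.7)` and sdlog
  `log(8.5)/(2·Φ⁻¹(0.75)) ≈ 1.586`, the parameters implied by a median
  of 4.7 Mut/Mb and IQR 2–17; about half of a large cohort falls inside
  [2, 17]. A 5/35 QC-failure rate yields missing TMB.
* Variant lists are built by inverse construction — passenger/driver
  counts chosen so the panel estimator returns the drawn TMB — plus
  germline, sub-threshold-VAF and non-coding decoys that the somatic
  filter and counting rules must remove.
* Response is logistic in log-TMB plus a latent clearance propensity
  `z ~ N(0,1)` (intercept −1.8, slope 1.0, clearance slope 0.5),
  calibrated to ≈ 43% responders.
* Baseline ctDNA lognormal with median 5 copies/ml and sdlog 2.5 — a
  wide dispersion leaving roughly a quarter to a third of patients
  below the 0.2% LoD, mirroring the published detectability fractions
  (14/32 undetectable at follow-up, 9 undetectable at both
  timepoints). Follow-up concentration is baseline times a lognormal
  fold-change with median 0.2 (responders) or 2.0 (non-responders),
  modulated by `z`. Droplet counts are then drawn binomially with
  per-droplet positive probability `1 − exp(−cv)` — the exact inverse
  of the Poisson estimator. The wild-type channel background comes from
  the total cfDNA mass. TMB and baseline ctDNA are drawn independently;
  their true joint distribution is unknown and this is flagged as a
  modeling assumption.
* cfDNA baseline lognormal with median 10 ng/ml (a typical advanced-
  cancer plasma level), fold-change median 0.6 / 1.4 by response.
* Survival is exponential (median ≈ 1500 days for responders, 250 for
  non-responders) with independent exponential censoring tuned to a 40%
  marginal censoring fraction. Covariate prevalences: liver metastases
  0.29, elevated LDH 0.40, male 0.54, prior targeted therapy 0.29.

What the simulator does **not** model: clonal evolution, assay dropout
correlated with disease burden, inter-assay efficiency differences,
non-exponential hazards, and any real correlation structure between
covariates. Passing tests on synthetic cohorts therefore validate the
*pipeline's arithmetic and logic* — filtering, Poisson inversion,
classification boundaries, exact-test correctness, calibration under
the null — not clinical performance on real data.

## The golden cohort

`fixture_golden_cohort()` is a deterministic 35-patient cohort whose
raw layers were constructed so that the full pipeline reproduces every
published marker-by-response count and all five combined-variable
tables simultaneously, including the missingness pattern: five QC
failures (three responders, two non-responders), three patients without
a follow-up sample, one TMB-high responder without a baseline sample
(detection known, increase and cfDNA change missing), and nine patients
undetectable at both timepoints. The joint assignment is forced almost
everywhere by the printed margins; where the published table prints an
impossible duplicate row label (the TMB × sex block lists "female"
twice), the margins determine which row is male. This cohort is the
end-to-end acceptance fixture: its Fisher column reproduces the
printed 0.002 / 0.011 / 0.008 / 0.022 and its cfDNA trend test 0.022.

## Numerical choices and problem sizes

Degenerate inputs error early and loudly: zero margins for Fisher,
fewer than two informative rows for trend, saturation for the
low-level Poisson estimator, negative times for survival. Monte-Carlo
tests record their seed and replicate count in the result and in the
run manifest, and are chunked (10^5 tables at a time) to bound memory.
The test suite exercises the statistical oracles on exhaustively
enumerable sizes (2×2 up to N = 40; k×2 up to 10 subjects), recovers
ddPCR concentrations over 250 replicate wells, and calibrates the
null rejection rate over 1000 simulated 35-patient cohorts — sizes at
which exhaustive enumeration or tight Monte-Carlo error is attainable
in seconds to a few minutes.

## Known limitations

The exome size and driver annotation are inputs, and TMB estimates are
only as comparable as those choices; the trend test's scores are the
equally spaced defaults, not data-driven; log-rank p-values are
asymptotic and optimistic at very small group sizes; and the package
deliberately implements no multivariate regression — the combined
ordered variables are the intended substitute at this cohort scale.
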