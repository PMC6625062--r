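# Deterministic 35-patient golden cohort.
#
# The per-patient assignment below jointly realizes every printed
# cross-tabulation of the cohort's characteristics tables: marker-by-
# response counts (TMB class, ctDNA detectability and increase at first
# follow-up, cfDNA change class, LDH, prior targeted therapy, sex, liver
# metastases, PD-L1) and all five combined TMB x marker variables,
# including the varying per-analysis denominators (30 patients with TMB,
# 32 with a detection call, 31 with an increase call and a cfDNA change).
# Missingness is realized mechanistically: five tumor samples fail
# sequencing QC; three patients lack a follow-up plasma sample (no
# detection, increase, or cfDNA-change call); one TMB-high responder lacks
# the baseline plasma sample (detection known, increase and cfDNA change
# not). Nine patients are ctDNA-undetectable at both timepoints (six
# responders, three non-responders).

.fixture_patients <- function() {
  # per patient: response, TMB passenger/driver counts (NA = QC failure),
  # ctDNA droplet counts at baseline/follow-up (NA = sample missing),
  # cfDNA ng/ml at baseline/follow-up, covariates
  p <- function(id, resp, P, D, k0, k1, cf0, cf1, ldh, tt, sex, liver, pdl1)
    data.frame(patient_id = id, response = resp, n_passenger = P,
               n_driver = D, k0 = k0, k1 = k1, cf0 = cf0, cf1 = cf1,
               ldh_elevated = ldh, prior_targeted_therapy = tt, sex = sex,
               liver_mets = liver, pd_l1 = pdl1, stringsAsFactors = FALSE)
  R <- "responder"; N <- "non_responder"
  rows <- list(
    # --- responders, TMB-high (all male, no liver metastases) ---
    p("P01", R, 85, 3, 120,  2, 12.0,  4.0, TRUE,  TRUE,  "male", FALSE, ">=1%"),
    p("P02", R, 70, 2, 150,  1, 20.0,  8.0, TRUE,  FALSE, "male", FALSE, ">=1%"),
    p("P03", R, 60, 4,  90,  0,  9.0,  4.0, FALSE, FALSE, "male", FALSE, ">=1%"),
    p("P04", R, 100, 5, 10, 60, 10.0, 16.0, FALSE, FALSE, "male", FALSE, ">=1%"),
    p("P05", R, 65, 2, 200, 80, 10.0, 10.0, FALSE, FALSE, "male", FALSE, "<1%"),
    p("P06", R, 55, 3,  NA, 25,   NA, 11.0, FALSE, FALSE, "male", FALSE, NA),
    # --- responders, TMB low/intermediate ---
    p("P07", R,  9, 1,   0,  0, 14.0,  6.0, TRUE,  FALSE, "male",   FALSE, ">=1%"),
    p("P08", R,  4, 1,   0,  0, 11.0, 12.0, FALSE, TRUE,  "male",   FALSE, ">=1%"),
    p("P09", R, 12, 2,   0,  0,  9.0,  9.5, FALSE, FALSE, "female", TRUE,  "<1%"),
    p("P10", R,  7, 1,   0,  0,  8.0,  7.0, FALSE, FALSE, "female", FALSE, NA),
    p("P11", R,  2, 0,   0,  0, 13.0, 14.0, FALSE, FALSE, "female", FALSE, NA),
    p("P12", R, 20, 2,   5, NA, 10.0,   NA, FALSE, FALSE, "female", FALSE, NA),
    # --- responders, tumor QC failure (all male, no liver metastases) ---
    p("P13", R, NA, NA,  0,  0, 16.0,  6.0, TRUE,  FALSE, "male", FALSE, NA),
    p("P14", R, NA, NA, 130,  2, 10.0, 11.0, FALSE, TRUE, "male", FALSE, NA),
    p("P15", R, NA, NA, 150, 60, 12.0, 12.0, FALSE, FALSE, "male", FALSE, NA),
    # --- non-responders, TMB low/intermediate ---
    p("P16", N,  8, 1,   0,  0, 10.0,  4.5, FALSE, FALSE, "male",   FALSE, ">=1%"),
    p("P17", N,  3, 0,   0,  0,  9.0,  9.0, FALSE, FALSE, "female", FALSE, ">=1%"),
    p("P18", N,  6, 1,   0,  0, 11.0, 12.0, FALSE, FALSE, "female", FALSE, ">=1%"),
    p("P19", N, 14, 2,  40, 160, 10.0, 12.0, TRUE, FALSE, "male",   TRUE,  ">=1%"),
    p("P20", N, 10, 1,   0, 150, 12.0, 13.0, TRUE, FALSE, "male",   TRUE,  "<1%"),
    p("P21", N,  5, 1,  30, 200, 10.0, 18.0, TRUE, TRUE,  "male",   TRUE,  "<1%"),
    p("P22", N,  2, 0,  25, 140,  8.0, 15.0, TRUE, TRUE,  "female", TRUE,  "<1%"),
    p("P23", N,  7, 1,  60, 220, 11.0, 20.0, TRUE, TRUE,  "female", TRUE,  "<1%"),
    p("P24", N,  9, 1,  15, 100, 10.0, 17.0, TRUE, TRUE,  "female", TRUE,  "<1%"),
    p("P25", N,  4, 0,   0,  90,  9.0, 16.0, TRUE, TRUE,  "female", TRUE,  "<1%"),
    p("P26", N, 12, 2,  70, 300, 12.0, 22.0, TRUE, TRUE,  "female", TRUE,  "<1%"),
    p("P27", N,  1, 0,  20, 120, 10.0, 19.0, TRUE, TRUE,  "female", TRUE,  "<1%"),
    p("P28", N, 15, 2, 100, 40, 14.0,  5.0, FALSE, FALSE, "male",   FALSE, "<1%"),
    p("P29", N,  3, 1,  90, 90, 10.0, 10.0, FALSE, FALSE, "male",   FALSE, NA),
    p("P30", N,  6, 0, 120, 50, 11.0, 11.5, FALSE, FALSE, "female", FALSE, NA),
    p("P31", N,  8, 1, 110, 30,  9.0,  9.0, FALSE, FALSE, "female", FALSE, NA),
    p("P32", N, 10, 1,  80, NA, 10.0,   NA, FALSE, FALSE, "male",   FALSE, NA),
    p("P33", N,  2, 0,   0, NA, 12.0,   NA, FALSE, FALSE, "female", FALSE, NA),
    # --- non-responders, tumor QC failure (no liver metastases) ---
    p("P34", N, NA, NA, 120,  0, 10.0, 10.5, FALSE, FALSE, "male",   FALSE, NA),
    p("P35", N, NA, NA,  0, 160, 10.0, 17.0, TRUE, FALSE, "female", FALSE, NA))
  do.call(rbind, rows)
}

#' Deterministic golden fixture cohort
#'
#' Constructs a 35-patient cohort, down to raw tumor/normal variant tables,
#' ddPCR droplet counts and cfDNA concentrations, whose classification
#' reproduces every cell of the published marker-by-response tables and
#' combined-variable tables simultaneously (see the package vignette).
#' Running it through the full pipeline is the package's end-to-end
#' validation: the somatic filter must remove the germline decoys, the
#' counting rules the low-VAF and non-coding decoys, the Poisson
#' quantifier and classification rules must regenerate the detection /
#' increase / change calls, and the statistical layer the printed exact
#' p-values.
#'
#' @return an `"lb_cohort"` list: `patients`, `tumor_variants`,
#'   `normal_variants`, `wells`, `cfdna`.
#' @export
fixture_golden_cohort <- function() {
  plan <- .fixture_patients()
  n <- nrow(plan)
  # survival: responders mostly censored late, non-responders mostly early
  # melanoma deaths; two excellent responders died of other causes and are
  # censored
  resp_idx <- plan$response == "responder"
  os <- numeric(n); ev <- logical(n)
  os[resp_idx] <- 320 + 20 * seq_len(sum(resp_idx))
  ev[resp_idx] <- FALSE
  os[!resp_idx] <- 60 + 12 * seq_len(sum(!resp_idx))
  ev[!resp_idx] <- TRUE
  ev[match(c("P32", "P33"), plan$patient_id)] <- FALSE   # alive at last contact
  os[match(c("P14", "P15"), plan$patient_id)] <- c(150, 180)  # non-melanoma deaths

  tum <- vector("list", n); nor <- vector("list", n)
  wel <- vector("list", n); cfd <- vector("list", n)
  for (i in seq_len(n)) {
    pid <- plan$patient_id[i]
    qc <- !is.na(plan$n_passenger[i])
    sv <- .synth_variants(pid, if (qc) plan$n_passenger[i] else 0L,
                          if (qc) plan$n_driver[i] else 0L, i)
    tum[[i]] <- sv$tumor; nor[[i]] <- sv$normal
    tp <- c(0L, 23L); ks <- c(plan$k0[i], plan$k1[i])
    keep <- !is.na(ks)
    if (any(keep))
      wel[[i]] <- data.frame(patient_id = pid, timepoint_days = tp[keep],
                             assay_id = paste0("assay_", pid),
                             k_mut = ks[keep], k_wt = 1200L,
                             n_droplets = 18000L, stringsAsFactors = FALSE)
    cfs <- c(plan$cf0[i], plan$cf1[i]); keep_cf <- !is.na(cfs)
    if (any(keep_cf))
      cfd[[i]] <- data.frame(patient_id = pid, timepoint_days = tp[keep_cf],
                             ng_per_ml = cfs[keep_cf],
                             stringsAsFactors = FALSE)
  }
  patients <- data.frame(
    patient_id = plan$patient_id, response = plan$response,
    os_days = os, event = ev, ldh_elevated = plan$ldh_elevated,
    liver_mets = plan$liver_mets, sex = plan$sex,
    prior_targeted_therapy = plan$prior_targeted_therapy,
    pd_l1 = plan$pd_l1, tmb_qc_pass = !is.na(plan$n_passenger),
    stringsAsFactors = FALSE)
  structure(list(patients = patients,
                 tumor_variants = do.call(rbind, tum),
                 normal_variants = do.call(rbind, nor),
                 wells = do.call(rbind, wel),
                 cfdna = do.call(rbind, cfd)),
            class = "lb_cohort")
}
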