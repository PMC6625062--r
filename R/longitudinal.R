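#' Classify the change in total cell-free DNA concentration
#'
#' Patients are grouped by the change between baseline and first follow-up
#' cfDNA concentration: decreasing (drop of more than 50%), increasing
#' (rise of more than 50%), or stable otherwise. Exactly +/-50% is stable
#' (the bounds are strict).
#'
#' @param baseline,followup cfDNA concentrations in ng/ml plasma; baseline
#'   must be positive for the ratio to be defined.
#' @return factor with ordered levels
#'   `decrease_gt50 < stable < increase_gt50` (best prognosis first), `NA`
#'   for undefined inputs.
#' @export
classify_cfdna_change <- function(baseline, followup) {
  lv <- c("decrease_gt50", "stable", "increase_gt50")
  n <- max(length(baseline), length(followup))
  baseline <- rep_len(baseline, n); followup <- rep_len(followup, n)
  bad <- !is.na(baseline) & baseline <= 0
  if (any(bad)) warning("non-positive baseline cfDNA: change undefined")
  out <- ifelse(is.na(baseline) | is.na(followup) | bad, NA_character_,
         ifelse(followup < 0.5 * baseline, "decrease_gt50",
         ifelse(followup > 1.5 * baseline, "increase_gt50", "stable")))
  factor(out, levels = lv, ordered = TRUE)
}

#' Classify ctDNA detection and trajectory at first follow-up
#'
#' Two binary calls from a baseline and a first-follow-up ctDNA
#' measurement: whether ctDNA is detectable at follow-up, and whether it is
#' increasing (follow-up copies/ml strictly above baseline, with undetected
#' measurements counted as 0 copies/ml). A patient undetectable at both
#' timepoints is (not detectable, not increasing); a missing follow-up
#' leaves both calls missing.
#'
#' @param baseline,followup one-row ctDNA measurement data.frames as
#'   produced by [quantify_wells()] (need `copies_per_ml` and `detected`),
#'   or `NULL` when the sample is missing.
#' @return list `(detectable_fu, increasing)` of logicals (possibly `NA`).
#' @export
classify_ctdna_status <- function(baseline, followup) {
  if (is.null(followup) || nrow(as.data.frame(followup)) == 0L)
    return(list(detectable_fu = NA, increasing = NA))
  followup <- as.data.frame(followup)
  fu_copies <- if (followup$detected) followup$copies_per_ml else 0
  if (is.null(baseline) || nrow(as.data.frame(baseline)) == 0L)
    return(list(detectable_fu = followup$detected, increasing = NA))
  baseline <- as.data.frame(baseline)
  if (followup$timepoint_days <= baseline$timepoint_days)
    stop("follow-up must be later than baseline")
  base_copies <- if (baseline$detected) baseline$copies_per_ml else 0
  list(detectable_fu = followup$detected,
       increasing = fu_copies > base_copies)
}

#' Select the first follow-up measurement
#'
#' Returns the earliest post-baseline measurement whose timepoint falls in
#' the follow-up window. The default window of 14-42 days brackets the
#' typical first liquid-biopsy follow-up about three weeks after treatment
#' start.
#'
#' @param measurements data.frame with a `timepoint_days` column, sorted or
#'   not.
#' @param window_days numeric `c(min, max)` in days, both inclusive.
#' @return one-row data.frame, or `NULL` when no measurement qualifies.
#' @export
first_followup <- function(measurements, window_days = c(14, 42)) {
  m <- as.data.frame(measurements)
  if (nrow(m) == 0L) return(NULL)
  m <- m[order(m$timepoint_days), , drop = FALSE]
  ok <- m$timepoint_days > 0 & m$timepoint_days >= window_days[1] &
    m$timepoint_days <= window_days[2]
  if (!any(ok)) return(NULL)
  m[which(ok)[1L], , drop = FALSE]
}

.combined_defs <- list(
  tmb_ctdna_detect = list(
    marker = "ctdna_detectable_fu",
    levels = c("TMB>23 & ctDNA not detectable", "TMB>23 & ctDNA detectable",
               "TMB<=23 & ctDNA not detectable", "TMB<=23 & ctDNA detectable"),
    label = function(high, v) paste(ifelse(high, "TMB>23", "TMB<=23"), "&",
                                    ifelse(v, "ctDNA detectable",
                                           "ctDNA not detectable"))),
  tmb_ctdna_increase = list(
    marker = "ctdna_increasing",
    levels = c("TMB>23 & ctDNA not increasing", "TMB>23 & ctDNA increasing",
               "TMB<=23 & ctDNA not increasing", "TMB<=23 & ctDNA increasing"),
    label = function(high, v) paste(ifelse(high, "TMB>23", "TMB<=23"), "&",
                                    ifelse(v, "ctDNA increasing",
                                           "ctDNA not increasing"))),
  tmb_cfdna = list(
    marker = "cfdna_change",
    levels = c("TMB>23 & cfDNA decrease>50%", "TMB>23 & cfDNA stable",
               "TMB>23 & cfDNA increase>50%", "TMB<=23 & cfDNA decrease>50%",
               "TMB<=23 & cfDNA stable", "TMB<=23 & cfDNA increase>50%"),
    label = function(high, v) {
      nice <- c(decrease_gt50 = "cfDNA decrease>50%", stable = "cfDNA stable",
                increase_gt50 = "cfDNA increase>50%")
      paste(ifelse(high, "TMB>23", "TMB<=23"), "&", nice[as.character(v)])
    }),
  tmb_liver = list(
    marker = "liver_mets",
    levels = c("TMB>23 & no liver mets", "TMB>23 & liver mets",
               "TMB<=23 & no liver mets", "TMB<=23 & liver mets"),
    label = function(high, v) paste(ifelse(high, "TMB>23", "TMB<=23"), "&",
                                    ifelse(v, "liver mets", "no liver mets"))),
  tmb_sex = list(
    marker = "sex",
    levels = c("TMB>23 & male", "TMB>23 & female",
               "TMB<=23 & male", "TMB<=23 & female"),
    label = function(high, v) paste(ifelse(high, "TMB>23", "TMB<=23"), "&",
                                    as.character(v)))
)

#' Build combined TMB x marker variables
#'
#' Crosses the binary TMB view (high: > 23.1 Mut/Mb vs not) with each of
#' ctDNA detectability, ctDNA increase, cfDNA change class, liver
#' metastasis, and sex, producing ordered categorical variables (up to 4-6
#' levels; best prognosis first, in the conventional row order of the
#' cohort tables). These combined variables take the place of multivariate
#' models, which do not converge at this cohort size. A missing TMB or
#' missing marker yields a missing combined label. Levels never observed in
#' the cohort (e.g. TMB-high with liver metastases) are dropped from the
#' factor when `drop_empty` is `TRUE`.
#'
#' @param classification data.frame with per-patient columns `tmb_high`
#'   (logical), `ctdna_detectable_fu`, `ctdna_increasing` (logical),
#'   `cfdna_change` (factor from [classify_cfdna_change()]), `liver_mets`
#'   (logical), `sex` (`"male"`/`"female"`).
#' @param drop_empty drop unobserved levels from each combined factor.
#' @return the input data.frame with ordered factor columns
#'   `combined_tmb_ctdna_detect`, `combined_tmb_ctdna_increase`,
#'   `combined_tmb_cfdna`, `combined_tmb_liver`, `combined_tmb_sex` added.
#' @export
build_combined_variables <- function(classification, drop_empty = TRUE) {
  cl <- classification
  for (nm in names(.combined_defs)) {
    def <- .combined_defs[[nm]]
    v <- cl[[def$marker]]
    lab <- ifelse(is.na(cl$tmb_high) | is.na(v), NA_character_,
                  def$label(cl$tmb_high, v))
    f <- factor(lab, levels = def$levels, ordered = TRUE)
    if (drop_empty) f <- droplevels(f)
    cl[[paste0("combined_", nm)]] <- f
  }
  cl
}

#' Classify a cohort's longitudinal liquid-biopsy markers
#'
#' Joins the per-patient TMB results, cfDNA concentrations and ctDNA
#' measurements into one classification row per patient: binary and 3-level
#' TMB class, cfDNA change class, ctDNA detectability and increase at first
#' follow-up, and the combined TMB x marker variables. Patients lacking a
#' baseline or first-follow-up sample get missing marker values and are
#' excluded per-analysis downstream, never imputed.
#'
#' @param patients data.frame with one row per patient: `patient_id`,
#'   `response` (`"responder"`/`"non_responder"`), `os_days`, `event`
#'   (logical, melanoma-specific death), `ldh_elevated`, `liver_mets`,
#'   `sex`, `prior_targeted_therapy`, `pd_l1` (`">=1%"`, `"<1%"` or `NA`).
#' @param tmb data.frame with `patient_id`, `tmb`, `qc_pass` (as from
#'   [compute_tmb()], one row per patient).
#' @param cfdna data.frame with `patient_id`, `timepoint_days`, `ng_per_ml`.
#' @param ctdna data.frame of ctDNA measurements from [quantify_wells()].
#' @param window_days follow-up selection window for [first_followup()].
#' @param high_lower TMB-high threshold in Mut/Mb.
#' @return data.frame, one row per patient, with marker classifications and
#'   combined variables.
#' @export
classify_cohort <- function(patients, tmb, cfdna, ctdna,
                            window_days = c(14, 42), high_lower = 23.1) {
  stopifnot(nrow(patients) > 0L)
  rows <- lapply(seq_len(nrow(patients)), function(i) {
    pid <- patients$patient_id[i]
    trow <- tmb[tmb$patient_id == pid, , drop = FALSE]
    tmb_val <- if (nrow(trow) == 1L && isTRUE(trow$qc_pass)) trow$tmb else NA_real_

    cf <- cfdna[cfdna$patient_id == pid, , drop = FALSE]
    cf_base <- cf[cf$timepoint_days == 0, , drop = FALSE]
    cf_fu <- first_followup(cf, window_days)
    cf_change <- if (nrow(cf_base) == 1L && !is.null(cf_fu))
      classify_cfdna_change(cf_base$ng_per_ml, cf_fu$ng_per_ml)
    else factor(NA, levels = c("decrease_gt50", "stable", "increase_gt50"),
                ordered = TRUE)

    ct <- ctdna[ctdna$patient_id == pid, , drop = FALSE]
    ct_base <- ct[ct$timepoint_days == 0, , drop = FALSE]
    ct_fu <- first_followup(ct, window_days)
    st <- classify_ctdna_status(
      if (nrow(ct_base) == 1L) ct_base else NULL, ct_fu)

    data.frame(patient_id = pid,
               tmb = tmb_val,
               tmb_category = classify_tmb(tmb_val,
                                           c(low_upper = 3.3,
                                             high_lower = high_lower)),
               tmb_high = tmb_high(tmb_val, high_lower),
               cfdna_change = cf_change,
               ctdna_detectable_fu = st$detectable_fu,
               ctdna_increasing = st$increasing,
               stringsAsFactors = FALSE)
  })
  cl <- do.call(rbind, rows)
  keep <- setdiff(names(patients), names(cl))
  cl <- cbind(cl, patients[, keep, drop = FALSE])
  build_combined_variables(cl)
}
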