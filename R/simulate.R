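#' Simulation parameters for a synthetic biomarker cohort
#'
#' Defaults emulate a 35-patient metastatic-melanoma cohort under combined
#' CTLA-4/PD-1 therapy: lognormal TMB matched to a median of 4.7 Mut/Mb
#' with IQR 2-17, covariate prevalences of 29% liver metastases, 40%
#' elevated LDH, 54% male and 29% prior targeted therapy, a logistic
#' response model on log-TMB calibrated to roughly 43% responders, widely
#' dispersed lognormal baseline ctDNA leaving roughly a quarter to a third
#' of patients below the ddPCR detection limit (mirroring the cohort's
#' detectability fractions), ctDNA
#' follow-up fold-changes favouring clearance in responders, lognormal
#' baseline cfDNA around 10 ng/ml, exponential melanoma-specific survival
#' and independent exponential censoring. TMB and baseline ctDNA are drawn
#' independently (their true joint distribution is unknown).
#'
#' @param n_patients cohort size.
#' @param tmb_log_mu,tmb_log_sigma lognormal TMB parameters (Mut/Mb scale).
#' @param tmb_qc_fail_rate probability a tumor sample fails sequencing QC
#'   (TMB missing, not zero).
#' @param response_intercept,response_beta_tmb,response_beta_clearance
#'   logistic response-model coefficients: intercept, slope on log(TMB),
#'   and slope on the latent clearance propensity z ~ N(0,1).
#' @param baseline_ctdna_log_mu,baseline_ctdna_log_sigma lognormal baseline
#'   ctDNA (copies/ml plasma).
#' @param responder_ctdna_multiplier,nonresponder_ctdna_multiplier median
#'   follow-up/baseline fold-change of ctDNA by response status.
#' @param ctdna_fold_sdlog lognormal spread of the fold-change; the latent
#'   clearance propensity z also lowers the fold-change by `exp(-sdlog z)`.
#' @param cfdna_baseline_params list `(log_mu, log_sigma)` for baseline
#'   cfDNA in ng/ml.
#' @param cfdna_change_params list `(responder_mult, nonresponder_mult,
#'   sdlog)` for the cfDNA fold-change.
#' @param hazard_responder,hazard_nonresponder exponential melanoma-death
#'   hazards per day.
#' @param censor_rate target marginal censoring fraction.
#' @param covariate_prevalences named vector with entries `liver`, `ldh`,
#'   `male`, `prior_tt`.
#' @param followup_day day of the first follow-up liquid biopsy.
#' @param n_droplets accepted droplets per ddPCR well.
#' @param ddpcr an [assay_config()].
#' @param seed integer master seed; per-patient sub-streams are derived
#'   from it so partial reruns are stable.
#' @return list with class `"simulation_params"`.
#' @export
simulation_params <- function(
    n_patients = 35,
    tmb_log_mu = log(4.7),
    tmb_log_sigma = log(17 / 2) / (2 * stats::qnorm(0.75)),
    tmb_qc_fail_rate = 5 / 35,
    response_intercept = -1.8,
    response_beta_tmb = 1.0,
    response_beta_clearance = 0.5,
    baseline_ctdna_log_mu = log(5),
    baseline_ctdna_log_sigma = 2.5,
    responder_ctdna_multiplier = 0.2,
    nonresponder_ctdna_multiplier = 2.0,
    ctdna_fold_sdlog = 0.5,
    cfdna_baseline_params = list(log_mu = log(10), log_sigma = 0.7),
    cfdna_change_params = list(responder_mult = 0.6,
                               nonresponder_mult = 1.4, sdlog = 0.4),
    hazard_responder = log(2) / 1500,
    hazard_nonresponder = log(2) / 250,
    censor_rate = 0.4,
    covariate_prevalences = c(liver = 0.29, ldh = 0.40, male = 0.54,
                              prior_tt = 0.29),
    followup_day = 23L,
    n_droplets = 20000L,
    ddpcr = assay_config(),
    seed = 1L) {
  if (n_patients < 1) stop("n_patients must be >= 1")
  if (responder_ctdna_multiplier < 0 || nonresponder_ctdna_multiplier < 0)
    stop("ctDNA multipliers must be >= 0")
  if (hazard_responder <= 0 || hazard_nonresponder <= 0)
    stop("hazards must be > 0")
  pr <- c(tmb_qc_fail_rate, censor_rate, covariate_prevalences)
  if (any(pr < 0 | pr > 1)) stop("probabilities must be in [0, 1]")
  structure(as.list(environment()), class = "simulation_params")
}

#' Simulate one ddPCR well at a known concentration
#'
#' Droplets receive target copies by Poisson loading, so each droplet is
#' positive independently with probability `1 - exp(-c v)` with `c` the
#' reaction concentration in copies/ul and `v` the droplet volume in ul.
#' The positive count is therefore binomial. This is the exact inverse of
#' the model behind [concentration_in_reaction()].
#'
#' @param concentration copies/ul in the reaction, >= 0.
#' @param n_droplets accepted droplets.
#' @param droplet_volume_nl droplet volume in nl.
#' @param seed optional seed for a reproducible draw.
#' @return one-row data.frame `(k_mut, n_droplets, droplet_volume_nl)`.
#' @export
simulate_ddpcr <- function(concentration, n_droplets = 20000L,
                           droplet_volume_nl = 0.85, seed = NULL) {
  if (concentration < 0) stop("concentration must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  p_pos <- 1 - exp(-concentration * droplet_volume_nl / 1000)
  data.frame(k_mut = stats::rbinom(1L, n_droplets, p_pos),
             n_droplets = n_droplets,
             droplet_volume_nl = droplet_volume_nl)
}

# deterministic sub-seed per patient, kept inside 32-bit integer range
.patient_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 101L + i * 7919) %% .Machine$integer.max)
}

.synth_variants <- function(patient_id, n_passenger, n_driver, idx) {
  base <- idx * 1000000L
  n_qual <- n_passenger + n_driver
  rows <- list()
  if (n_qual > 0) {
    vaf <- rep(c(0.10, 0.25, 0.4, 0.6), length.out = n_qual)
    rows$qual <- data.frame(
      chrom = "chr1", pos = base + seq_len(n_qual),
      ref = "A", alt = "T",
      gene = sprintf("G%04d", ((base + seq_len(n_qual)) %% 710L) + 1L),
      variant_class = rep(c("SNV", "InDel", "essential_splice"),
                          length.out = n_qual),
      coding_effect = rep(c("non_synonymous", "synonymous"),
                          length.out = n_qual),
      vaf = vaf,
      is_driver = rep(c(rep(FALSE, n_passenger), rep(TRUE, n_driver))),
      stringsAsFactors = FALSE)
  }
  # noise that must be filtered out downstream
  rows$germline <- data.frame(
    chrom = "chr2", pos = base + 1:2, ref = "G", alt = "C",
    gene = c("G0001", "G0002"), variant_class = "SNV",
    coding_effect = "non_synonymous", vaf = c(0.48, 0.52),
    is_driver = FALSE, stringsAsFactors = FALSE)
  rows$lowvaf <- data.frame(
    chrom = "chr3", pos = base + 1L, ref = "A", alt = "G", gene = "G0003",
    variant_class = "SNV", coding_effect = "non_synonymous", vaf = 0.05,
    is_driver = FALSE, stringsAsFactors = FALSE)
  rows$noncoding <- data.frame(
    chrom = "chr4", pos = base + 1L, ref = "T", alt = "C", gene = "G0004",
    variant_class = "SNV", coding_effect = "non_coding", vaf = 0.40,
    is_driver = FALSE, stringsAsFactors = FALSE)
  tumor <- do.call(rbind, rows)
  tumor <- cbind(patient_id = patient_id, tumor)
  normal <- cbind(patient_id = patient_id, rows$germline)
  rownames(tumor) <- rownames(normal) <- NULL
  list(tumor = tumor, normal = normal)
}

.wells_for_copies <- function(patient_id, timepoint, copies_ml, wt_copies_ml,
                              params) {
  cfg <- params$ddpcr
  to_conc <- function(c_ml) c_ml * cfg$plasma_volume_ml *
    cfg$reaction_input_fraction / cfg$reaction_volume_ul
  k_mut <- simulate_ddpcr(to_conc(copies_ml), params$n_droplets,
                          cfg$droplet_volume_nl)$k_mut
  k_wt <- simulate_ddpcr(to_conc(wt_copies_ml), params$n_droplets,
                         cfg$droplet_volume_nl)$k_mut
  data.frame(patient_id = patient_id, timepoint_days = timepoint,
             assay_id = paste0("assay_", patient_id),
             k_mut = k_mut, k_wt = k_wt, n_droplets = params$n_droplets,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic biomarker cohort
#'
#' Draws a full cohort with every raw layer the analysis pipeline consumes:
#' per-patient tumor/normal variant tables (constructed to realize the
#' drawn TMB through the panel extrapolation, with germline, low-VAF and
#' non-coding decoys that the somatic filter and counting rules must
#' remove), droplet-level ddPCR wells at baseline and first follow-up,
#' cfDNA concentrations, response labels from the logistic model, and
#' censored melanoma-specific survival. Fully reproducible given
#' `params$seed`.
#'
#' @param params a [simulation_params()].
#' @return list with class `"lb_cohort"`: `patients`, `tumor_variants`,
#'   `normal_variants`, `wells`, `cfdna`, `params`.
#' @export
generate_cohort <- function(params = simulation_params()) {
  stopifnot(inherits(params, "simulation_params"))
  n <- params$n_patients
  prev <- params$covariate_prevalences
  E <- 35.0; S <- 2.1   # exome / panel coding Mb used for the inverse draw

  pat <- vector("list", n)
  tum <- vector("list", n)
  nor <- vector("list", n)
  wel <- vector("list", n)
  cfd <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(.patient_seed(params$seed, i))
    pid <- sprintf("S%03d", i)

    sex <- if (stats::runif(1) < prev[["male"]]) "male" else "female"
    liver <- stats::runif(1) < prev[["liver"]]
    ldh <- stats::runif(1) < prev[["ldh"]]
    tt <- stats::runif(1) < prev[["prior_tt"]]
    pd_l1 <- sample(c(">=1%", "<1%", NA), 1L, prob = c(0.29, 0.31, 0.40))

    tmb_target <- stats::rlnorm(1, params$tmb_log_mu, params$tmb_log_sigma)
    n_driver <- stats::rpois(1, 2)
    n_passenger <- max(0L, round((tmb_target - n_driver / E) * S))
    tmb_real <- n_passenger / S + n_driver / E
    qc_pass <- stats::runif(1) >= params$tmb_qc_fail_rate

    z <- stats::rnorm(1)
    eta <- params$response_intercept +
      params$response_beta_tmb * log(tmb_real + 0.1) +
      params$response_beta_clearance * z
    responder <- stats::runif(1) < stats::plogis(eta)

    base_ct <- stats::rlnorm(1, params$baseline_ctdna_log_mu,
                             params$baseline_ctdna_log_sigma)
    mult <- if (responder) params$responder_ctdna_multiplier
            else params$nonresponder_ctdna_multiplier
    fold <- mult * exp(params$ctdna_fold_sdlog * (stats::rnorm(1) - z))
    fu_ct <- base_ct * fold

    cfp <- params$cfdna_baseline_params
    base_cf <- stats::rlnorm(1, cfp$log_mu, cfp$log_sigma)
    chp <- params$cfdna_change_params
    cf_mult <- if (responder) chp$responder_mult else chp$nonresponder_mult
    fu_cf <- base_cf * cf_mult * exp(stats::rnorm(1, 0, chp$sdlog))

    haz <- if (responder) params$hazard_responder else params$hazard_nonresponder
    t_death <- stats::rexp(1, haz)
    cr <- params$censor_rate
    haz_c <- if (cr <= 0) Inf else haz * cr / (1 - cr)
    t_cens <- if (is.finite(haz_c)) stats::rexp(1, haz_c) else Inf
    os <- min(t_death, t_cens)
    event <- t_death <= t_cens

    # total cfDNA genome copies per ml set the wild-type background
    wt_base <- base_cf * 1000 / params$ddpcr$haploid_genome_mass_pg
    wt_fu <- fu_cf * 1000 / params$ddpcr$haploid_genome_mass_pg

    pat[[i]] <- data.frame(
      patient_id = pid,
      response = if (responder) "responder" else "non_responder",
      os_days = os, event = event, ldh_elevated = ldh, liver_mets = liver,
      sex = sex, prior_targeted_therapy = tt, pd_l1 = pd_l1,
      tmb_qc_pass = qc_pass, tmb_true = tmb_real,
      stringsAsFactors = FALSE)
    sv <- .synth_variants(pid, n_passenger, n_driver, i)
    tum[[i]] <- sv$tumor
    nor[[i]] <- sv$normal
    wel[[i]] <- rbind(
      .wells_for_copies(pid, 0L, base_ct, wt_base, params),
      .wells_for_copies(pid, params$followup_day, fu_ct, wt_fu, params))
    cfd[[i]] <- data.frame(patient_id = pid,
                           timepoint_days = c(0L, params$followup_day),
                           ng_per_ml = c(base_cf, fu_cf),
                           stringsAsFactors = FALSE)
  }
  structure(list(patients = do.call(rbind, pat),
                 tumor_variants = do.call(rbind, tum),
                 normal_variants = do.call(rbind, nor),
                 wells = do.call(rbind, wel),
                 cfdna = do.call(rbind, cfd),
                 params = params),
            class = "lb_cohort")
}

#' @export
print.lb_cohort <- function(x, ...) {
  cat("liquid-biopsy cohort:", nrow(x$patients), "patients,",
      nrow(x$wells), "ddPCR wells,", nrow(x$tumor_variants),
      "tumor variant calls\n")
  invisible(x)
}
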