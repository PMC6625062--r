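#' Per-patient TMB for a whole cohort
#'
#' Applies the panel-TMB chain ([compute_tmb()]) to every patient's tumor
#' and matched-normal variant tables. QC-failed samples propagate as
#' missing TMB.
#'
#' @param cohort an `"lb_cohort"` (from [generate_cohort()],
#'   [fixture_golden_cohort()] or [read_cohort()]).
#' @param panel a [panel_definition()].
#' @param min_vaf minimum variant allele fraction.
#' @return data.frame: `patient_id`, `passenger_count`, `driver_count`,
#'   `tmb`, `category`, `qc_pass`.
#' @export
cohort_tmb <- function(cohort, panel = default_panel(), min_vaf = 0.10) {
  pts <- cohort$patients
  rows <- lapply(seq_len(nrow(pts)), function(i) {
    pid <- pts$patient_id[i]
    tv <- cohort$tumor_variants[cohort$tumor_variants$patient_id == pid,
                                , drop = FALSE]
    nv <- cohort$normal_variants[cohort$normal_variants$patient_id == pid,
                                 , drop = FALSE]
    res <- compute_tmb(tv, nv, panel, min_vaf = min_vaf,
                       qc_pass = isTRUE(pts$tmb_qc_pass[i]))
    cbind(patient_id = pid, res)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Default 710-gene panel definition
#'
#' Synthetic placeholder gene symbols `G0001`-`G0710` with the panel and
#' exome coding sizes used throughout (2.1 and 35 Mb).
#'
#' @param exome_coding_size_mb coding exome size in Mb.
#' @return a [panel_definition()].
#' @export
default_panel <- function(exome_coding_size_mb = 35.0) {
  panel_definition(sprintf("G%04d", 1:710),
                   panel_coding_size_mb = 2.1,
                   exome_coding_size_mb = exome_coding_size_mb)
}

#' Run the full biomarker analysis on a cohort
#'
#' Executes the stages in order: panel TMB (germline subtraction,
#' counting, extrapolation, classification), ddPCR quantification
#' (droplet counts to copies/ml plasma and detection calls), longitudinal
#' marker classification (cfDNA change, ctDNA detectability/increase at
#' first follow-up, combined TMB x marker variables), and the cohort
#' statistics tables. Deterministic for fixed inputs and seed.
#'
#' @param cohort an `"lb_cohort"`.
#' @param cfg an [assay_config()].
#' @param panel a [panel_definition()].
#' @param mc_reps Monte-Carlo permutations for the exact trend tests.
#' @param seed seed for the Monte-Carlo stream.
#' @param window_days first-follow-up selection window (days).
#' @return list: `tmb`, `ctdna`, `classification`, `marker_table`, `combined_table`,
#'   `denominators` (patients contributing to each marker analysis).
#' @export
analyze_cohort <- function(cohort, cfg = assay_config(),
                           panel = default_panel(), mc_reps = 1e5,
                           seed = 1L, window_days = c(14, 42)) {
  stopifnot(inherits(cohort, "lb_cohort") || is.list(cohort))
  if (nrow(cohort$patients) == 0L) stop("empty cohort")
  tmb <- cohort_tmb(cohort, panel)
  ctdna <- quantify_wells(cohort$wells, cfg)
  cl <- classify_cohort(cohort$patients, tmb, cohort$cfdna, ctdna,
                        window_days = window_days)
  t2 <- marker_association_table(cl, mc_reps = mc_reps, seed = seed)
  t3 <- combined_variable_table(cl, mc_reps = mc_reps, seed = seed)
  denom <- c(n_patients = nrow(cl),
             tmb = sum(!is.na(cl$tmb_high)),
             ctdna_detection = sum(!is.na(cl$ctdna_detectable_fu)),
             ctdna_increase = sum(!is.na(cl$ctdna_increasing)),
             cfdna_change = sum(!is.na(cl$cfdna_change)))
  list(tmb = tmb, ctdna = ctdna, classification = cl, marker_table = t2,
       combined_table = t3, denominators = denom)
}

#' Write a cohort's raw tables to a directory
#'
#' @param cohort an `"lb_cohort"`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$patients, file.path(dir, "patients.csv"),
                   row.names = FALSE)
  utils::write.table(cohort$tumor_variants,
                     file.path(dir, "tumor_variants.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(cohort$normal_variants,
                     file.path(dir, "normal_variants.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$wells, file.path(dir, "wells.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$cfdna, file.path(dir, "cfdna.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a cohort from a directory written by [write_cohort()]
#'
#' @param dir directory holding `patients.csv`, `tumor_variants.tsv`,
#'   `normal_variants.tsv`, `wells.csv`, `cfdna.csv`.
#' @return an `"lb_cohort"`.
#' @export
read_cohort <- function(dir) {
  need <- c("patients.csv", "tumor_variants.tsv", "normal_variants.tsv",
            "wells.csv", "cfdna.csv")
  paths <- file.path(dir, need)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0L)
    stop("cohort input file not found: ", paste(missing, collapse = ", "))
  structure(list(
    patients = utils::read.csv(paths[1], stringsAsFactors = FALSE),
    tumor_variants = utils::read.delim(paths[2], stringsAsFactors = FALSE),
    normal_variants = utils::read.delim(paths[3], stringsAsFactors = FALSE),
    wells = utils::read.csv(paths[4], stringsAsFactors = FALSE),
    cfdna = utils::read.csv(paths[5], stringsAsFactors = FALSE)),
    class = "lb_cohort")
}

#' Run the pipeline from a configuration and write a report bundle
#'
#' File-level orchestration: reads the cohort tables named in the config,
#' runs [analyze_cohort()], and writes per-patient TMB and classification
#' tables, the two statistics tables, per-group survival curves, and a run
#' manifest (package version, seed, Monte-Carlo replicates, config hash,
#' per-analysis denominators) so any re-analysis is auditable. Idempotent
#' for fixed inputs, config and seed.
#'
#' @param config a list (or path to a YAML file) with entries `cohort_dir`
#'   (directory of input tables, see [read_cohort()]), `out_dir`, and
#'   optionally `seed`, `mc_reps`, `exome_coding_size_mb`,
#'   `followup_window_days` (length 2), and the [assay_config()] fields
#'   under `assay`.
#' @return the [analyze_cohort()] result, invisibly; files under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$cohort_dir) || is.null(config$out_dir))
    stop("config needs cohort_dir and out_dir")
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  mc_reps <- if (is.null(config$mc_reps)) 1e5 else config$mc_reps
  window <- if (is.null(config$followup_window_days)) c(14, 42)
            else config$followup_window_days
  cfg <- do.call(assay_config, if (is.null(config$assay)) list()
                               else config$assay)
  panel <- default_panel(
    if (is.null(config$exome_coding_size_mb)) 35.0
    else config$exome_coding_size_mb)

  cohort <- read_cohort(config$cohort_dir)
  res <- analyze_cohort(cohort, cfg = cfg, panel = panel,
                        mc_reps = mc_reps, seed = seed,
                        window_days = window)

  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(res$tmb, file.path(out, "tmb_per_sample.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.csv(res$ctdna, file.path(out, "ctdna_measurements.csv"),
                   row.names = FALSE)
  cl_out <- res$classification
  cl_out$tmb_category <- as.character(cl_out$tmb_category)
  utils::write.csv(cl_out, file.path(out, "classification.csv"),
                   row.names = FALSE)
  utils::write.table(res$marker_table, file.path(out, "marker_association.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(res$combined_table, file.path(out, "combined_variables.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)

  cl <- res$classification
  curves <- list(responder = cl$response == "responder",
                 non_responder = cl$response == "non_responder",
                 tmb_high = !is.na(cl$tmb_high) & cl$tmb_high,
                 tmb_not_high = !is.na(cl$tmb_high) & !cl$tmb_high)
  km <- lapply(names(curves), function(nm) {
    idx <- curves[[nm]]
    if (!any(idx)) return(NULL)
    cv <- kaplan_meier(cl$os_days[idx], cl$event[idx])
    data.frame(group = nm, time = cv$time, n_risk = cv$n_risk,
               n_event = cv$n_event, surv = cv$surv)
  })
  utils::write.table(do.call(rbind, km),
                     file.path(out, "survival_curves.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  cfg_file <- file.path(out, "config_used.yaml")
  yaml::write_yaml(config, cfg_file)
  manifest <- list(
    package = "tmbliquid",
    version = as.character(utils::packageVersion("tmbliquid")),
    seed = seed, mc_reps = mc_reps,
    config_md5 = unname(tools::md5sum(cfg_file)),
    denominators = as.list(res$denominators))
  yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))
  invisible(res)
}
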