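#' ddPCR assay configuration
#'
#' Volumes and conventions for converting droplet counts into plasma
#' concentrations. Defaults follow the QX200 workflow: 0.85 nl droplets,
#' 20 ul reactions, cell-free DNA extracted from 4 ml plasma, 5 ng input
#' per reaction, and a detection threshold of 3 mutant-positive droplets.
#'
#' @param plasma_volume_ml plasma volume the cfDNA was extracted from (ml).
#' @param elution_volume_ul eluate volume after extraction (ul).
#' @param reaction_input_fraction fraction of the eluate loaded into one
#'   reaction (or merged set of replicate reactions).
#' @param reaction_volume_ul ddPCR reaction volume (ul).
#' @param droplet_volume_nl droplet partition volume (nl).
#' @param input_mass_ng cfDNA mass loaded per reaction (ng).
#' @param detection_threshold_droplets minimum mutant-positive droplets for
#'   a detection call.
#' @param haploid_genome_mass_pg mass of one haploid genome copy (pg).
#' @return list with class `"assay_config"`.
#' @export
assay_config <- function(plasma_volume_ml = 4,
                         elution_volume_ul = 50,
                         reaction_input_fraction = 1,
                         reaction_volume_ul = 20,
                         droplet_volume_nl = 0.85,
                         input_mass_ng = 5,
                         detection_threshold_droplets = 3,
                         haploid_genome_mass_pg = 3.3) {
  vols <- c(plasma_volume_ml, elution_volume_ul, reaction_volume_ul,
            droplet_volume_nl, haploid_genome_mass_pg)
  if (any(vols <= 0)) stop("all volumes and masses must be > 0")
  if (reaction_input_fraction <= 0 || reaction_input_fraction > 1)
    stop("reaction_input_fraction must be in (0, 1]")
  if (detection_threshold_droplets < 1)
    stop("detection_threshold_droplets must be >= 1")
  structure(list(plasma_volume_ml = plasma_volume_ml,
                 elution_volume_ul = elution_volume_ul,
                 reaction_input_fraction = reaction_input_fraction,
                 reaction_volume_ul = reaction_volume_ul,
                 droplet_volume_nl = droplet_volume_nl,
                 input_mass_ng = input_mass_ng,
                 detection_threshold_droplets = detection_threshold_droplets,
                 haploid_genome_mass_pg = haploid_genome_mass_pg),
            class = "assay_config")
}

#' Poisson concentration estimate from droplet counts
#'
#' Digital PCR partitions the reaction into droplets; a droplet is positive
#' if it received at least one target copy. Under Poisson loading the mean
#' copies per droplet is `lambda = -ln(1 - k/n)`, and the reaction
#' concentration is `lambda` divided by the droplet volume. The estimate
#' exceeds the naive `k/(n v)` for k > 0 because positive droplets can hold
#' more than one copy.
#'
#' @param k positive-droplet count (mutant or wild-type channel).
#' @param n_droplets total accepted droplets.
#' @param droplet_volume_nl droplet volume in nl (default 0.85).
#' @return concentration in copies per microliter of reaction.
#' @export
concentration_in_reaction <- function(k, n_droplets, droplet_volume_nl = 0.85) {
  if (n_droplets <= 0) stop("n_droplets must be > 0")
  if (k < 0 || k > n_droplets) stop("k must be in [0, n_droplets]")
  if (k == n_droplets)
    stop("all droplets positive: concentration not quantifiable (saturation)")
  v_ul <- droplet_volume_nl / 1000
  -log(1 - k / n_droplets) / v_ul
}

#' Convert a reaction concentration to copies per ml plasma
#'
#' Back-calculates through the extraction: the reaction holds
#' `reaction_input_fraction` of the eluate, which holds all template from
#' `plasma_volume_ml` of plasma.
#'
#' @param conc_reaction copies/ul in the reaction.
#' @param cfg an [assay_config()].
#' @return copies per ml plasma.
#' @export
copies_per_ml_plasma <- function(conc_reaction, cfg) {
  stopifnot(inherits(cfg, "assay_config"))
  if (any(conc_reaction < 0)) stop("conc_reaction must be >= 0")
  conc_reaction * cfg$reaction_volume_ul / cfg$reaction_input_fraction /
    cfg$plasma_volume_ml
}

#' Mutant allele frequency from absolute copy numbers
#'
#' Mutant copies divided by total (mutant + wild-type) copies. Undefined
#' when no copies of either allele were observed; returned as `NA` rather
#' than 0 in that case.
#'
#' @param mut_copies,wt_copies non-negative copy numbers (any common unit).
#' @return fraction in \[0, 1\], or `NA` when both inputs are zero.
#' @export
mutant_allele_frequency <- function(mut_copies, wt_copies) {
  if (any(mut_copies < 0, na.rm = TRUE) || any(wt_copies < 0, na.rm = TRUE))
    stop("copy numbers must be >= 0")
  total <- mut_copies + wt_copies
  ifelse(is.na(total) | total == 0, NA_real_, mut_copies / total)
}

#' ctDNA detection call from mutant droplet counts
#'
#' A measurement is called detected when at least
#' `detection_threshold_droplets` mutant-positive droplets (default 3
#' independent observations) were counted. Wild-type droplets never affect
#' the call.
#'
#' @param k_mut mutant-positive droplet count(s).
#' @param cfg an [assay_config()].
#' @return logical.
#' @export
call_detection <- function(k_mut, cfg = assay_config()) {
  stopifnot(inherits(cfg, "assay_config"))
  if (any(k_mut < 0, na.rm = TRUE)) stop("k_mut must be >= 0")
  k_mut >= cfg$detection_threshold_droplets
}

#' Analytic minimum detectable allele fraction
#'
#' With `m` ng of cfDNA in the reaction there are about
#' `m * 1000 / haploid_genome_mass_pg` genome copies available; requiring
#' at least the detection threshold of mutant droplets means the smallest
#' detectable allele fraction is threshold / copies. At the default 3
#' droplets and 5 ng input this is 0.00198, i.e. about 0.2%.
#'
#' @param input_mass_ng cfDNA mass in the reaction (ng).
#' @param cfg an [assay_config()].
#' @return minimum detectable allele fraction.
#' @export
min_detectable_af <- function(input_mass_ng, cfg = assay_config()) {
  stopifnot(inherits(cfg, "assay_config"))
  if (any(input_mass_ng <= 0)) stop("input_mass_ng must be > 0")
  genome_copies <- input_mass_ng * 1000 / cfg$haploid_genome_mass_pg
  cfg$detection_threshold_droplets / genome_copies
}

#' Quantify ctDNA from a table of ddPCR wells
#'
#' Replicate wells of the same patient, timepoint and assay are merged by
#' summing droplet counts, then converted to copies per ml plasma through
#' the Poisson estimate and the assay volumes. The reported `copies_per_ml`
#' is 0 for measurements below the detection threshold (the raw estimate is
#' kept in `copies_per_ml_raw` for audit); `maf` is mutant / (mutant +
#' wild-type) concentration and is `NA` when no droplets of either channel
#' were positive.
#'
#' @param wells data.frame with columns `patient_id`, `timepoint_days`,
#'   `assay_id`, `k_mut`, `k_wt`, `n_droplets`.
#' @param cfg an [assay_config()].
#' @return data.frame of ctDNA measurements, one row per patient x
#'   timepoint x assay, with columns `patient_id`, `timepoint_days`,
#'   `assay_id`, `k_mut`, `k_wt`, `n_droplets`, `copies_per_ml_raw`,
#'   `copies_per_ml`, `wt_copies_per_ml`, `maf`, `detected`, `saturated`.
#'   A saturated channel (every droplet positive) has no finite Poisson
#'   estimate; it is quantified at one half droplet below saturation,
#'   flagged in `saturated`, and warned about — the value is a lower bound.
#' @export
quantify_wells <- function(wells, cfg = assay_config()) {
  stopifnot(inherits(cfg, "assay_config"))
  req <- c("patient_id", "timepoint_days", "assay_id", "k_mut", "k_wt",
           "n_droplets")
  miss <- setdiff(req, names(wells))
  if (length(miss) > 0L)
    stop("wells table is missing columns: ", paste(miss, collapse = ", "))
  if (any(wells$k_mut > wells$n_droplets | wells$k_wt > wells$n_droplets))
    stop("positive-droplet counts exceed total droplets")
  agg <- stats::aggregate(
    cbind(k_mut, k_wt, n_droplets) ~ patient_id + timepoint_days + assay_id,
    data = wells, FUN = sum)
  agg <- agg[order(agg$patient_id, agg$timepoint_days, agg$assay_id), ,
             drop = FALSE]
  # a saturated channel (every droplet positive) has no finite Poisson
  # estimate; quantify at k - 0.5 so the merged measurement stays usable
  # and flag it for audit
  saturated <- agg$k_mut == agg$n_droplets | agg$k_wt == agg$n_droplets
  if (any(saturated))
    warning(sum(saturated), " saturated measurement(s): ",
            "concentration is a lower bound")
  conc_of <- function(k, n) concentration_in_reaction(
    min(k, n - 0.5), n, droplet_volume_nl = cfg$droplet_volume_nl)
  conc_mut <- mapply(conc_of, agg$k_mut, agg$n_droplets)
  conc_wt <- mapply(conc_of, agg$k_wt, agg$n_droplets)
  raw <- copies_per_ml_plasma(conc_mut, cfg)
  wt <- copies_per_ml_plasma(conc_wt, cfg)
  det <- call_detection(agg$k_mut, cfg)
  data.frame(agg,
             copies_per_ml_raw = raw,
             copies_per_ml = ifelse(det, raw, 0),
             wt_copies_per_ml = wt,
             maf = mutant_allele_frequency(raw, wt),
             detected = det,
             saturated = saturated,
             row.names = NULL)
}

#' Read a ddPCR well table from CSV
#'
#' @param path CSV with columns `patient_id`, `timepoint_days`, `assay_id`,
#'   `k_mut`, `k_wt`, `n_droplets`.
#' @return data.frame of wells.
#' @export
read_wells_csv <- function(path) {
  if (!file.exists(path)) stop("wells file not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
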