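#' Targeted panel definition for TMB estimation
#'
#' Describes the gene panel the tumor was sequenced with and the exome size
#' used for extrapolation. The defaults describe a 710-gene panel covering
#' 2.1 Mb of coding sequence; the coding exome size is set to 35 Mb and can
#' be changed to match another annotation release.
#'
#' @param gene_list character vector of panel gene symbols.
#' @param panel_coding_size_mb coding megabases captured by the panel.
#' @param exome_coding_size_mb coding megabases of the whole exome the
#'   passenger count is extrapolated to; must be at least the panel size.
#' @param driver_genes optional character vector of gene symbols whose
#'   variants are treated as drivers when a variant table lacks per-variant
#'   `is_driver` annotation (see [count_tmb_variants()]).
#' @return list with class `"panel_definition"`.
#' @export
panel_definition <- function(gene_list,
                             panel_coding_size_mb = 2.1,
                             exome_coding_size_mb = 35.0,
                             driver_genes = NULL) {
  if (length(gene_list) == 0L) stop("gene_list must be non-empty")
  if (!is.numeric(panel_coding_size_mb) || panel_coding_size_mb <= 0)
    stop("panel_coding_size_mb must be > 0")
  if (!is.numeric(exome_coding_size_mb) ||
      exome_coding_size_mb < panel_coding_size_mb)
    stop("exome_coding_size_mb must be >= panel_coding_size_mb")
  structure(list(gene_list = unique(as.character(gene_list)),
                 panel_coding_size_mb = panel_coding_size_mb,
                 exome_coding_size_mb = exome_coding_size_mb,
                 driver_genes = driver_genes),
            class = "panel_definition")
}

#' Count TMB-qualifying somatic variants
#'
#' Counts somatic variants that enter the mutation-burden estimate: coding
#' variants (synonymous as well as non-synonymous; deep-intronic and other
#' non-coding changes are excluded) of class SNV, InDel or essential splice
#' with variant allele fraction at or above `min_vaf`. The qualifying set is
#' partitioned into passengers and drivers by the `is_driver` flag.
#'
#' @param somatic variant table of somatic calls (after [filter_somatic()]).
#' @param min_vaf minimum variant allele fraction, inclusive; default 0.10.
#' @param driver_genes optional character vector; when given, a variant is a
#'   driver if its `is_driver` flag is set or its gene is in this list.
#' @return named integer vector `c(passenger = P, driver = D)`.
#' @export
count_tmb_variants <- function(somatic, min_vaf = 0.10, driver_genes = NULL) {
  somatic <- variant_table(as.data.frame(somatic))
  if (!is.numeric(min_vaf) || length(min_vaf) != 1L ||
      min_vaf < 0 || min_vaf > 1)
    stop("min_vaf must be a single value in [0, 1]")
  if (nrow(somatic) == 0L) return(c(passenger = 0L, driver = 0L))
  if (anyNA(somatic$vaf)) stop("missing vaf in somatic variant table")
  qual <- somatic$vaf >= min_vaf &
    somatic$variant_class %in% c("SNV", "InDel", "essential_splice") &
    somatic$coding_effect != "non_coding"
  drv <- somatic$is_driver
  if (!is.null(driver_genes)) drv <- drv | somatic$gene %in% driver_genes
  c(passenger = sum(qual & !drv), driver = sum(qual & drv))
}

#' Extrapolate panel mutation counts to an exome-wide TMB
#'
#' Passenger mutations are assumed to occur at equal density across the
#' coding genome, so the panel passenger count is scaled up by the ratio of
#' exome to panel size; driver mutations are assumed confined to the
#' tumor-associated genes on the panel and are not scaled. The estimated
#' exome-wide total is then normalized per coding megabase:
#' \deqn{TMB = (P \cdot E/S + D) / E = P/S + D/E}
#' with `P` passengers, `D` drivers, `S` the panel and `E` the exome coding
#' size in Mb.
#'
#' @param passenger_count,driver_count non-negative integers from
#'   [count_tmb_variants()].
#' @param panel a [panel_definition()].
#' @return TMB in mutations per coding megabase (Mut/Mb).
#' @export
estimate_tmb <- function(passenger_count, driver_count, panel) {
  stopifnot(inherits(panel, "panel_definition"))
  if (passenger_count < 0 || driver_count < 0) stop("counts must be >= 0")
  S <- panel$panel_coding_size_mb
  E <- panel$exome_coding_size_mb
  if (S <= 0 || E <= 0) stop("panel and exome sizes must be > 0")
  (passenger_count * (E / S) + driver_count) / E
}

#' Classify a TMB value into low / intermediate / high
#'
#' Default category boundaries: low below 3.3 Mut/Mb, intermediate from 3.3
#' to 23.1 Mut/Mb (both bounds included), high strictly above 23.1 Mut/Mb.
#'
#' @param tmb TMB value(s) in Mut/Mb, non-negative.
#' @param cutoffs numeric `c(low_upper, high_lower)`.
#' @return factor with ordered levels `low < intermediate < high`.
#' @export
classify_tmb <- function(tmb, cutoffs = c(low_upper = 3.3, high_lower = 23.1)) {
  if (any(!is.na(tmb) & tmb < 0)) stop("tmb must be >= 0")
  if (cutoffs[1] > cutoffs[2]) stop("cutoffs must be non-decreasing")
  out <- ifelse(is.na(tmb), NA_character_,
         ifelse(tmb < cutoffs[1], "low",
         ifelse(tmb > cutoffs[2], "high", "intermediate")))
  factor(out, levels = c("low", "intermediate", "high"), ordered = TRUE)
}

#' Binary high / not-high view of a TMB value
#'
#' @param tmb TMB value(s) in Mut/Mb.
#' @param high_lower threshold; values strictly above are `TRUE`.
#' @return logical: `TRUE` for TMB-high, `NA` propagated.
#' @export
tmb_high <- function(tmb, high_lower = 23.1) {
  ifelse(is.na(tmb), NA, tmb > high_lower)
}

#' Per-sample TMB from tumor and normal variant tables
#'
#' Runs the full panel-TMB chain: germline subtraction, qualifying-variant
#' counting, exome extrapolation, and 3-level classification. Samples that
#' failed sequencing QC are carried through with `qc_pass = FALSE` and
#' missing TMB so that downstream analyses can exclude them rather than
#' treat them as mutation-free.
#'
#' @param tumor variant table of tumor calls.
#' @param normal variant table (or key vector) of matched-normal calls.
#' @param panel a [panel_definition()].
#' @param min_vaf minimum variant allele fraction (default 0.10).
#' @param cutoffs category boundaries passed to [classify_tmb()].
#' @param qc_pass logical; `FALSE` marks a failed sample.
#' @return one-row data.frame with `passenger_count`, `driver_count`,
#'   `tmb`, `category`, `qc_pass`.
#' @export
compute_tmb <- function(tumor, normal, panel, min_vaf = 0.10,
                        cutoffs = c(low_upper = 3.3, high_lower = 23.1),
                        qc_pass = TRUE) {
  if (!isTRUE(qc_pass)) {
    return(data.frame(passenger_count = NA_integer_, driver_count = NA_integer_,
                      tmb = NA_real_,
                      category = factor(NA, levels = c("low", "intermediate", "high"),
                                        ordered = TRUE),
                      qc_pass = FALSE))
  }
  somatic <- filter_somatic(tumor, normal)
  counts <- count_tmb_variants(somatic, min_vaf = min_vaf,
                               driver_genes = panel$driver_genes)
  tmb <- estimate_tmb(counts[["passenger"]], counts[["driver"]], panel)
  data.frame(passenger_count = counts[["passenger"]],
             driver_count = counts[["driver"]],
             tmb = tmb, category = classify_tmb(tmb, cutoffs), qc_pass = TRUE)
}
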