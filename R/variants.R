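#' Construct and validate a somatic variant table
#'
#' A variant table holds one row per variant allele with the annotation the
#' TMB counting rules need. Multi-allelic records must already be split into
#' one row per alternate allele (the VCF reader does this).
#'
#' @param df data.frame with columns `chrom`, `pos`, `ref`, `alt`, `gene`,
#'   `variant_class` (one of `"SNV"`, `"InDel"`, `"essential_splice"`,
#'   `"other"`), `coding_effect` (one of `"synonymous"`, `"non_synonymous"`,
#'   `"splice"`, `"non_coding"`), `vaf` (fraction in \[0, 1\]) and `is_driver`
#'   (logical).
#' @return The validated data.frame with class `"variant_table"` prepended.
#' @export
variant_table <- function(df) {
  req <- c("chrom", "pos", "ref", "alt", "gene", "variant_class",
           "coding_effect", "vaf", "is_driver")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0L)
    stop("variant table is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(df) > 0L) {
    bad_class <- setdiff(unique(df$variant_class),
                         c("SNV", "InDel", "essential_splice", "other"))
    if (length(bad_class) > 0L)
      stop("unknown variant_class: ", paste(bad_class, collapse = ", "))
    bad_eff <- setdiff(unique(df$coding_effect),
                       c("synonymous", "non_synonymous", "splice", "non_coding"))
    if (length(bad_eff) > 0L)
      stop("unknown coding_effect: ", paste(bad_eff, collapse = ", "))
    ok_vaf <- is.na(df$vaf) | (df$vaf >= 0 & df$vaf <= 1)
    if (!all(ok_vaf)) stop("vaf outside [0, 1]")
    if (any(df$ref == df$alt)) stop("ref and alt alleles must differ")
    keys <- variant_keys(df)
    if (anyDuplicated(keys)) {
      dup <- keys[duplicated(keys)][1L]
      stop("duplicate variant key within one sample: ", dup)
    }
  }
  class(df) <- unique(c("variant_table", class(df)))
  df
}

#' Genomic keys identifying variant alleles
#'
#' @param df a variant table (or any data.frame with `chrom`, `pos`, `ref`,
#'   `alt` columns).
#' @return character vector `chrom:pos:ref:alt`, one per row.
#' @export
variant_keys <- function(df) {
  if (nrow(df) == 0L) return(character(0))
  paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
}

#' Subtract germline variants from a tumor variant list
#'
#' Tumor and matched-normal calls are compared by genomic key
#' (chrom, pos, ref, alt); tumor variants whose key also occurs in the
#' normal sample are removed as germline. A different alternate allele at
#' the same position is a different key and is retained. Row order of the
#' tumor table is preserved.
#'
#' @param tumor variant table of tumor calls.
#' @param normal variant table of matched-normal calls, or a character
#'   vector of keys as produced by [variant_keys()].
#' @return The somatic subset of `tumor`.
#' @export
filter_somatic <- function(tumor, normal) {
  tumor <- variant_table(as.data.frame(tumor))
  if (is.character(normal)) {
    normal_keys <- normal
    if (anyDuplicated(normal_keys))
      stop("duplicate variant key within one sample: ",
           normal_keys[duplicated(normal_keys)][1L])
  } else {
    normal_keys <- variant_keys(variant_table(as.data.frame(normal)))
  }
  keep <- !(variant_keys(tumor) %in% normal_keys)
  out <- tumor[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a variant table from TSV
#'
#' Expects the tabular interchange format with columns `chrom`, `pos`,
#' `ref`, `alt`, `gene`, `variant_class`, `coding_effect`, `vaf`,
#' `is_driver`.
#'
#' @param path path to a tab-separated file.
#' @return a validated variant table.
#' @export
read_variants_tsv <- function(path) {
  if (!file.exists(path)) stop("variant file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$is_driver <- as.logical(df$is_driver)
  variant_table(df)
}

#' Read a variant table from VCF
#'
#' Multi-allelic records are split into one row per alternate allele. The
#' variant allele fraction is taken from the INFO field named by
#' `af_field` (a comma-separated per-allele value for split records);
#' gene, class, effect and driver status come from INFO fields with the
#' given names, defaulting to `GENE`, `VCLASS`, `EFFECT`, `DRIVER`
#' (values 0/1). Fields absent from a record yield `NA`.
#'
#' @param path path to a VCF (v4.x) file, plain or bgzipped.
#' @param af_field INFO key carrying the per-allele allele fraction.
#' @param gene_field,class_field,effect_field,driver_field INFO keys for
#'   the annotation columns.
#' @return a validated variant table.
#' @export
read_variants_vcf <- function(path, af_field = "AF", gene_field = "GENE",
                              class_field = "VCLASS", effect_field = "EFFECT",
                              driver_field = "DRIVER") {
  if (!file.exists(path)) stop("VCF not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    return(variant_table(data.frame(
      chrom = character(0), pos = integer(0), ref = character(0),
      alt = character(0), gene = character(0), variant_class = character(0),
      coding_effect = character(0), vaf = numeric(0), is_driver = logical(0))))
  }
  info1 <- function(key) vcfR::extract.info(v, element = key)
  af <- info1(af_field)
  gene <- info1(gene_field)
  vclass <- info1(class_field)
  effect <- info1(effect_field)
  driver <- info1(driver_field)

  rows <- lapply(seq_len(nrow(fix)), function(i) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    afs <- if (is.na(af[i])) rep(NA_real_, length(alts)) else
      as.numeric(strsplit(af[i], ",", fixed = TRUE)[[1]])
    if (length(afs) == 1L && length(alts) > 1L) afs <- rep(afs, length(alts))
    data.frame(
      chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]), ref = fix$REF[i],
      alt = alts, gene = gene[i],
      variant_class = vclass[i], coding_effect = effect[i],
      vaf = afs, is_driver = !is.na(driver)[i] & driver[i] %in% c("1", "TRUE"),
      stringsAsFactors = FALSE)
  })
  variant_table(do.call(rbind, rows))
}
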