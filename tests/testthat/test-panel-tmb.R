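make_variants <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(chrom = r[["chrom"]] %||% "chr1",
               pos = as.integer(r[["pos"]]),
               ref = r[["ref"]] %||% "A", alt = r[["alt"]] %||% "T",
               gene = r[["gene"]] %||% "BRAF",
               variant_class = r[["variant_class"]] %||% "SNV",
               coding_effect = r[["coding_effect"]] %||% "non_synonymous",
               vaf = as.numeric(r[["vaf"]] %||% 0.5),
               is_driver = isTRUE(r[["is_driver"]]),
               stringsAsFactors = FALSE)))
  df
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("germline subtraction keeps exactly the tumor-private keys", {
  tumor <- make_variants(list(pos = 1), list(pos = 2), list(pos = 3))
  normal <- make_variants(list(pos = 2))
  out <- filter_somatic(tumor, normal)
  expect_equal(out$pos, c(1L, 3L))

  # empty tumor list stays empty
  expect_equal(nrow(filter_somatic(tumor[0, ], normal)), 0L)

  # a different alt allele at the same position is a different variant
  tumor2 <- make_variants(list(pos = 140453136, alt = "T"))
  normal2 <- make_variants(list(pos = 140453136, alt = "G"))
  expect_equal(nrow(filter_somatic(tumor2, normal2)), 1L)
})

test_that("duplicate variant keys within one sample are rejected by key", {
  dup <- make_variants(list(pos = 5), list(pos = 5))
  expect_error(filter_somatic(dup, dup[0, ]), "chr1:5:A:T")
})

test_that("qualifying-variant counting applies VAF, class and coding rules", {
  # inclusive 10% VAF threshold
  v <- make_variants(list(pos = 1, vaf = 0.09), list(pos = 2, vaf = 0.10),
                     list(pos = 3, vaf = 0.50))
  expect_equal(count_tmb_variants(v), c(passenger = 2L, driver = 0L))

  # synonymous coding variants count
  syn <- make_variants(list(pos = 1, coding_effect = "synonymous", vaf = 0.3))
  expect_equal(count_tmb_variants(syn), c(passenger = 1L, driver = 0L))

  # non-coding variants never count
  nc <- make_variants(list(pos = 1, coding_effect = "non_coding", vaf = 0.4))
  expect_equal(count_tmb_variants(nc), c(passenger = 0L, driver = 0L))

  # counts partition by driver flag
  mix <- make_variants(list(pos = 1, vaf = 0.3, is_driver = TRUE),
                       list(pos = 2, vaf = 0.3))
  expect_equal(count_tmb_variants(mix), c(passenger = 1L, driver = 1L))

  expect_error(count_tmb_variants(v, min_vaf = 1.2), "min_vaf")
  v$vaf[1] <- NA
  expect_error(count_tmb_variants(v), "vaf")
})

test_that("counting matches the brute-force oracle on random variant lists", {
  set.seed(42)
  for (rep in 1:30) {
    df <- random_variant_table(sample(0:40, 1))
    expect_identical(unname(count_tmb_variants(df)),
                     unname(as.integer(oracle_count_tmb(df))))
  }
})

test_that("exome extrapolation scales passengers but not drivers", {
  panel <- panel_definition("BRAF", panel_coding_size_mb = 2.1,
                            exome_coding_size_mb = 35)
  expect_equal(estimate_tmb(20, 2, panel), 9.581, tolerance = 5e-4)
  expect_equal(estimate_tmb(0, 0, panel), 0)
  expect_equal(estimate_tmb(21, 0, panel), 10.0)

  # linear in the passenger count
  expect_equal(estimate_tmb(40, 0, panel), 2 * estimate_tmb(20, 0, panel))
  # monotone in both arguments
  expect_gt(estimate_tmb(5, 3, panel), estimate_tmb(0, 3, panel))
  expect_gt(estimate_tmb(5, 3, panel), estimate_tmb(5, 2, panel))
  # no-extrapolation limit: exome size equal to panel size
  eq <- panel_definition("BRAF", panel_coding_size_mb = 2.1,
                         exome_coding_size_mb = 2.1)
  expect_equal(estimate_tmb(7, 3, eq), 10 / 2.1)
  expect_error(estimate_tmb(-1, 0, panel), ">= 0")
})

test_that("TMB categories partition the value range", {
  expect_equal(as.character(classify_tmb(2.0)), "low")
  expect_equal(as.character(classify_tmb(23.1)), "intermediate")
  expect_equal(as.character(classify_tmb(23.2)), "high")
  expect_equal(as.character(classify_tmb(3.3)), "intermediate")

  grid <- c(0, 1, 3.29, 3.3, 3.31, 10, 23.09, 23.1, 23.11, 50, 200)
  cats <- classify_tmb(grid)
  expect_false(anyNA(cats))          # every value gets exactly one category
  expect_true(all(cats[grid < 3.3] == "low"))
  expect_true(all(cats[grid > 23.1] == "high"))
  expect_true(all(cats[grid >= 3.3 & grid <= 23.1] == "intermediate"))
  expect_error(classify_tmb(-1), ">= 0")
})

test_that("per-sample TMB chain composes, with QC failure as missing", {
  panel <- default_panel()
  tumor <- make_variants(list(pos = 1, vaf = 0.3),
                         list(pos = 2, vaf = 0.4, is_driver = TRUE),
                         list(pos = 3, vaf = 0.05),
                         list(pos = 4, vaf = 0.6, coding_effect = "non_coding"),
                         list(pos = 9, vaf = 0.5))  # germline below
  normal <- make_variants(list(pos = 9, vaf = 0.5))
  res <- compute_tmb(tumor, normal, panel)
  expect_equal(res$passenger_count, 1L)
  expect_equal(res$driver_count, 1L)
  expect_equal(res$tmb, 1 / 2.1 + 1 / 35)

  qc <- compute_tmb(tumor, normal, panel, qc_pass = FALSE)
  expect_false(qc$qc_pass)
  expect_true(is.na(qc$tmb))      # missing, not zero
})

test_that("variant tables round-trip through TSV and VCF readers", {
  df <- make_variants(list(pos = 10, vaf = 0.25),
                      list(pos = 20, vaf = 0.5, is_driver = TRUE))
  tsv <- tempfile(fileext = ".tsv")
  write.table(df, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  back <- read_variants_tsv(tsv)
  expect_equal(back$pos, df$pos)
  expect_equal(back$vaf, df$vaf)

  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele fraction\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene\">",
    "##INFO=<ID=VCLASS,Number=1,Type=String,Description=\"Class\">",
    "##INFO=<ID=EFFECT,Number=1,Type=String,Description=\"Effect\">",
    "##INFO=<ID=DRIVER,Number=1,Type=Integer,Description=\"Driver\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr7\t140453136\t.\tA\tT\t.\tPASS\tAF=0.31;GENE=BRAF;VCLASS=SNV;EFFECT=non_synonymous;DRIVER=1",
    "chr1\t100\t.\tG\tA,C\t.\tPASS\tAF=0.20,0.15;GENE=G0001;VCLASS=SNV;EFFECT=synonymous;DRIVER=0"),
    vcf)
  vt <- read_variants_vcf(vcf)
  expect_equal(nrow(vt), 3L)             # multi-allelic record split
  expect_equal(vt$vaf, c(0.31, 0.20, 0.15))
  expect_true(vt$is_driver[1])
  expect_equal(vt$alt[2:3], c("A", "C"))
})
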