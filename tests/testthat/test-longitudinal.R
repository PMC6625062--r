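test_that("cfDNA change classes use strict 50% bounds", {
  expect_equal(as.character(classify_cfdna_change(10, 4.9)), "decrease_gt50")
  expect_equal(as.character(classify_cfdna_change(10, 15.0)), "stable")
  expect_equal(as.character(classify_cfdna_change(10, 15.1)), "increase_gt50")

  # boundary grid: exactly one class per ratio, strict at both bounds
  ratios <- c(0.49, 0.5, 0.51, 1.0, 1.49, 1.5, 1.51)
  got <- as.character(classify_cfdna_change(rep(8, length(ratios)),
                                            8 * ratios))
  expect_equal(got, c("decrease_gt50", "stable", "stable", "stable",
                      "stable", "stable", "increase_gt50"))
  expect_false(anyNA(got))

  expect_warning(out <- classify_cfdna_change(0, 5), "baseline")
  expect_true(is.na(out))
})

measurement <- function(t, copies, detected) {
  data.frame(timepoint_days = t, copies_per_ml = copies, detected = detected)
}

test_that("ctDNA status calls detection and strict increase", {
  # detected baseline, undetected follow-up: not detectable, not increasing
  st <- classify_ctdna_status(measurement(0, 100, TRUE),
                              measurement(23, 0, FALSE))
  expect_false(st$detectable_fu); expect_false(st$increasing)

  # undetected baseline counts as 0 copies
  st <- classify_ctdna_status(measurement(0, 0, FALSE),
                              measurement(23, 50, TRUE))
  expect_true(st$detectable_fu); expect_true(st$increasing)

  # equal copies are not increasing (strict inequality)
  st <- classify_ctdna_status(measurement(0, 100, TRUE),
                              measurement(23, 100, TRUE))
  expect_true(st$detectable_fu); expect_false(st$increasing)

  # undetectable at both timepoints
  st <- classify_ctdna_status(measurement(0, 0, FALSE),
                              measurement(23, 0, FALSE))
  expect_false(st$detectable_fu); expect_false(st$increasing)

  # missing follow-up leaves both calls missing
  st <- classify_ctdna_status(measurement(0, 100, TRUE), NULL)
  expect_true(is.na(st$detectable_fu)); expect_true(is.na(st$increasing))

  # increasing is never TRUE when the follow-up is undetected
  for (base in list(c(0, FALSE), c(10, TRUE), c(500, TRUE))) {
    st <- classify_ctdna_status(measurement(0, base[1], as.logical(base[2])),
                                measurement(23, 0, FALSE))
    expect_false(st$increasing)
  }
  expect_error(classify_ctdna_status(measurement(23, 1, TRUE),
                                     measurement(0, 1, TRUE)), "later")
})

test_that("first follow-up selection respects the window", {
  m <- data.frame(timepoint_days = c(0, 23, 45), x = 1:3)
  expect_equal(first_followup(m)$timepoint_days, 23)
  expect_null(first_followup(data.frame(timepoint_days = 0)))
  expect_null(first_followup(data.frame(timepoint_days = c(0, 50))))
  # inclusive bounds, earliest qualifying wins
  m2 <- data.frame(timepoint_days = c(0, 14, 42))
  expect_equal(first_followup(m2)$timepoint_days, 14)
})

test_that("combined variables cross binary TMB with each marker", {
  cl <- data.frame(
    tmb_high = c(TRUE, FALSE, NA, TRUE),
    ctdna_detectable_fu = c(FALSE, TRUE, TRUE, NA),
    ctdna_increasing = c(FALSE, TRUE, FALSE, FALSE),
    cfdna_change = factor(c("decrease_gt50", "increase_gt50", "stable",
                            "decrease_gt50"),
                          levels = c("decrease_gt50", "stable",
                                     "increase_gt50"), ordered = TRUE),
    liver_mets = c(FALSE, TRUE, FALSE, FALSE),
    sex = c("male", "female", "male", "male"))
  out <- build_combined_variables(cl, drop_empty = FALSE)
  expect_equal(as.character(out$combined_tmb_ctdna_detect[1]),
               "TMB>23 & ctDNA not detectable")
  expect_equal(as.character(out$combined_tmb_ctdna_detect[2]),
               "TMB<=23 & ctDNA detectable")
  # top-ranked combined cfDNA level: TMB-high with a deep cfDNA decrease
  expect_equal(which(levels(out$combined_tmb_cfdna) ==
                       as.character(out$combined_tmb_cfdna[1])), 1L)
  # missing TMB or missing marker yields a missing combined label
  expect_true(is.na(out$combined_tmb_ctdna_detect[3]))
  expect_true(all(is.na(out[3, grepl("^combined", names(out))])))
  expect_true(is.na(out$combined_tmb_ctdna_detect[4]))
  expect_equal(as.character(out$combined_tmb_sex[4]), "TMB>23 & male")
})

test_that("combined category counts equal a brute-force grouping", {
  co <- fixture_golden_cohort()
  res <- analyze_cohort(co, mc_reps = 1e4, seed = 1)
  cl <- res$classification
  # independent grouping straight from the raw columns
  for (resp in c("responder", "non_responder")) {
    sub <- cl[cl$response == resp & !is.na(cl$tmb_high) &
                !is.na(cl$ctdna_detectable_fu), ]
    brute <- table(factor(paste(ifelse(sub$tmb_high, "H", "L"),
                                ifelse(sub$ctdna_detectable_fu, "D", "U")),
                          levels = c("H U", "H D", "L U", "L D")))
    tab <- response_table(cl, "combined_tmb_ctdna_detect")
    expect_equal(unname(tab[, resp]),
                 unname(c(brute["H U"], brute["H D"], brute["L U"],
                          brute["L D"])))
  }
})
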