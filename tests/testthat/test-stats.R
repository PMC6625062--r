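test_that("two-sided Fisher p matches enumeration on the cohort tables", {
  # TMB-high vs response: 6/6 responders vs 0/18 non-responders
  ft <- fisher_exact_two_sided(matrix(c(6, 6, 0, 18), 2))
  expect_equal(ft$p_value, 0.001556, tolerance = 1e-3)
  expect_equal(round(ft$p_value, 3), 0.002)
  # equally extreme 2x2 has p = 1
  expect_equal(fisher_exact_two_sided(matrix(c(1, 0, 0, 1), 2))$p_value, 1)
  expect_error(fisher_exact_two_sided(matrix(c(0, 0, 3, 4), 2)),
               "degenerate")
  expect_error(fisher_exact_two_sided(matrix(1:6, 3)), "2x2")
})

test_that("Fisher implementation agrees with oracles on random tables", {
  set.seed(11)
  n_checked <- 0
  while (n_checked < 120) {
    N <- sample(4:40, 1)
    cells <- as.vector(stats::rmultinom(1, N, prob = runif(4, 0.05, 1)))
    tab <- matrix(cells, 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    p <- fisher_exact_two_sided(tab)$p_value
    expect_equal(p, oracle_fisher_p(tab), tolerance = 1e-10)
    expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-7)
    n_checked <- n_checked + 1
  }
})

test_that("Fisher test keeps nominal type-I error under the null", {
  # exact tests are conservative: rejection rate at alpha = 0.05 stays
  # at or below 0.05 when rows and columns are independent
  set.seed(5)
  rej <- 0; reps <- 400
  for (i in seq_len(reps)) {
    x <- rbinom(30, 1, 0.5); y <- rbinom(30, 1, 0.4)
    tab <- table(factor(x, 0:1), factor(y, 0:1))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    if (fisher_exact_two_sided(tab)$p_value <= 0.05) rej <- rej + 1
  }
  expect_lte(rej / reps, 0.05)
})

test_that("Monte-Carlo trend test tracks the exhaustive permutation p", {
  # proportional rows carry no trend
  flat <- matrix(c(4, 8, 2, 2, 4, 1), ncol = 2)
  expect_gt(exact_trend_test(flat, reps = 1e4, seed = 2)$p_value, 0.9)

  # small tables: MC p within 3 MC standard errors of exhaustive p
  set.seed(21)
  for (i in 1:8) {
    repeat {
      tab <- matrix(rmultinom(1, sample(6:10, 1), runif(6, 0.1, 1)), ncol = 2)
      if (sum(rowSums(tab) > 0) >= 2 && all(colSums(tab) > 0)) break
    }
    p_ex <- oracle_trend_p(tab)
    mc <- exact_trend_test(tab, reps = 2e4, seed = 100 + i)
    se <- sqrt(p_ex * (1 - p_ex) / mc$mc_reps)
    expect_lt(abs(mc$p_value - p_ex), 3 * se + 2 / mc$mc_reps)
  }

  # statistic agrees with the subject-level (n-1) r^2 formulation
  tab <- matrix(c(5, 7, 1, 2, 8, 8), ncol = 2)
  expect_equal(trend_statistic(tab), oracle_lbl_stat(tab), tolerance = 1e-12)

  # two rows with scores 0,1 converge to the two-sided exact 2x2 test
  tab2 <- matrix(c(9, 2, 3, 8), 2)
  p2 <- exact_trend_test(tab2, reps = 1e5, seed = 9)$p_value
  p_exact <- oracle_trend_p(tab2)
  expect_lt(abs(p2 - p_exact), 3 * sqrt(p_exact * (1 - p_exact) / 1e5))

  expect_error(exact_trend_test(matrix(c(5, 0, 3, 0), ncol = 2)),
               "informative")
  expect_error(exact_trend_test(tab, reps = 100), "10\\^4")
})

test_that("Monte-Carlo p is reproducible by seed and never exactly 0", {
  tab <- matrix(c(3, 3, 5, 0, 0, 0, 3, 13), ncol = 2)
  a <- exact_trend_test(tab, reps = 1e4, seed = 42)
  b <- exact_trend_test(tab, reps = 1e4, seed = 42)
  expect_identical(a$p_value, b$p_value)
  expect_gt(a$p_value, 0)              # (b+1)/(reps+1) estimator
  expect_lte(a$p_value, 1)
})

test_that("Wilcoxon rank-sum behaves as the exact small-sample test", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p_value, 0.1)
  expect_equal(wilcoxon_rank_sum(c(2, 3, 2), c(2, 3, 2))$p_value, 1.0)
  # rank statistic: shift invariance
  x <- c(1.2, 5.3, 2.2, 8); y <- c(3.3, 9.1, 0.4)
  expect_equal(wilcoxon_rank_sum(x, y)$p_value,
               wilcoxon_rank_sum(x + 100, y + 100)$p_value)
  expect_error(wilcoxon_rank_sum(numeric(0), y), "non-empty")
})

test_that("Kaplan-Meier estimate matches hand-computed product limits", {
  # all censored: flat at 1
  cv <- kaplan_meier(c(5, 10, 15), c(FALSE, FALSE, FALSE))
  expect_equal(surv_prob(cv, c(0, 20)), c(1, 1))

  # all events at 1,2,3: S(2) = 1/3, S(3) = 0
  cv <- kaplan_meier(c(1, 2, 3), c(TRUE, TRUE, TRUE))
  expect_equal(surv_prob(cv, 2), 1 / 3)
  expect_equal(surv_prob(cv, 3), 0)

  # first event drops the curve by 1/n
  cv <- kaplan_meier(c(4, 9, 11, 20), c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(surv_prob(cv, 4), 1 - 1 / 4)

  # without censoring the curve is the empirical survival function
  set.seed(3)
  t <- sample(1:50, 12)
  cv <- kaplan_meier(t, rep(TRUE, 12))
  for (tt in c(0, 10, 25, 50))
    expect_equal(surv_prob(cv, tt), mean(t > tt))
  expect_error(kaplan_meier(c(-1, 2), c(TRUE, TRUE)), ">= 0")
})

test_that("log-rank statistic matches a hand-computed O-E sum", {
  # identical groups: statistic 0, p = 1
  t <- c(2, 4, 6); e <- c(TRUE, TRUE, FALSE)
  lr <- logrank(c(t, t), c(e, e), rep(c("a", "b"), each = 3))
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1)

  # 6-subject worked example, events in A at 1,2; B censored at 10:
  # at t=1: 6 at risk (3 A), E_A = 1/2; at t=2: 5 at risk (2 A), E_A = 2/5;
  # O_A - E_A = 2 - 0.9 = 1.1; V = sum d (n1/n)(1 - n1/n) = 0.25 + 0.24
  lr <- logrank(c(1, 2, 8, 10, 10, 10),
                c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
                rep(c("A", "B"), each = 3))
  expect_equal(lr$statistic, 1.1^2 / 0.49, tolerance = 1e-6)
  expect_gt(lr$statistic, 0)

  # trend variant on 3 ordered groups runs and orders with the hazard
  set.seed(8)
  g <- rep(1:3, each = 15)
  tm <- rexp(45, rate = c(0.01, 0.02, 0.05)[g])
  lr3 <- logrank(tm, rep(TRUE, 45), factor(g), trend_scores = 0:2)
  expect_lt(lr3$p_value, 0.05)

  expect_warning(
    out <- logrank(c(1, 2, 3, 4), c(FALSE, FALSE, FALSE, FALSE),
                   c("a", "a", "b", "b")), "no events")
  expect_true(is.na(out$p_value))
})

test_that("characteristic tables assemble with per-analysis denominators", {
  co <- fixture_golden_cohort()
  res <- analyze_cohort(co, mc_reps = 1e4, seed = 1)
  t2 <- res$marker_table
  tmb_rows <- t2[t2$characteristic == "TMB [Mut/Mb]", ]
  expect_equal(sum(tmb_rows$total), 30)   # 5 QC failures excluded
  det_rows <- t2[grepl("detection", t2$characteristic), ]
  expect_equal(sum(det_rows$total), 32)
  cf_rows <- t2[t2$characteristic == "Cell-free DNA change", ]
  expect_equal(sum(cf_rows$total), 31)
  expect_equal(t2$response_method[t2$characteristic == "TMB [Mut/Mb]"][1],
               "Fisher exact")
  expect_equal(cf_rows$response_method[1],
               "Exact chi-square trend (Monte-Carlo)")
  expect_true(all(na.omit(t2$p_response) >= 0 & na.omit(t2$p_response) <= 1))
  expect_error(marker_association_table(res$classification[0, ]), "empty")
})
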