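#' Test-result container
#'
#' @param statistic test statistic, or `NA` when the test has none.
#' @param p_value p-value in \[0, 1\] (or `NA` when undefined).
#' @param method method name.
#' @param n_used number of subjects entering the test.
#' @param mc_reps,seed Monte-Carlo replicate count and seed, present only
#'   for Monte-Carlo methods.
#' @return list with class `"tl_test"`.
#' @export
test_result <- function(statistic, p_value, method, n_used,
                        mc_reps = NULL, seed = NULL) {
  if (!is.na(p_value) && (p_value < 0 || p_value > 1))
    stop("p_value outside [0, 1]")
  structure(list(statistic = statistic, p_value = p_value, method = method,
                 n_used = n_used, mc_reps = mc_reps, seed = seed),
            class = "tl_test")
}

#' @export
print.tl_test <- function(x, ...) {
  cat(x$method, "\n")
  if (!is.na(x$statistic)) cat("  statistic =", format(x$statistic), "\n")
  cat("  p =", format.pval(x$p_value, digits = 4), " (n =", x$n_used, ")\n")
  if (!is.null(x$mc_reps))
    cat("  Monte-Carlo reps =", x$mc_reps, " seed =", x$seed, "\n")
  invisible(x)
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Exact test of association in a 2x2 contingency table. Conditional on
#' both margins the first cell follows a hypergeometric distribution; the
#' two-sided p-value sums the probabilities of all tables with the same
#' margins that are no more probable than the observed one (probability
#' ordering, the convention of most statistical software).
#'
#' @param table 2x2 matrix of non-negative integer counts (rows =
#'   characteristic levels, columns = outcome groups).
#' @return a [test_result()].
#' @export
fisher_exact_two_sided <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("table must be 2x2")
  if (any(table < 0)) stop("counts must be >= 0")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("degenerate table: a zero row or column margin")
  m <- sum(table[1, ])          # row-1 total
  n <- sum(table[2, ])          # row-2 total
  k <- sum(table[, 1])          # column-1 total
  support <- max(0L, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(table[1, 1], m, n, k)
  # relative tolerance guards against ties broken by floating-point noise
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  test_result(NA_real_, p, "Fisher exact test (two-sided)", sum(table))
}

#' Linear-by-linear trend statistic for a k x 2 table
#'
#' @param table k x 2 matrix; rows ordered categories, columns outcome
#'   groups.
#' @param scores numeric row scores, strictly increasing; default 0..k-1.
#' @return the chi-square trend statistic (1 df),
#'   `(T - E[T])^2 / Var[T]` with `T` the score total of column 1 under the
#'   permutation (fixed-margins) null.
#' @export
trend_statistic <- function(table, scores = seq_len(nrow(table)) - 1) {
  table <- as.matrix(table)
  if (ncol(table) != 2L) stop("table must have 2 columns")
  if (any(diff(scores) <= 0)) stop("scores must be strictly increasing")
  n <- sum(table)
  rt <- rowSums(table)
  c1 <- sum(table[, 1])
  c2 <- n - c1
  Sx <- sum(scores * rt)
  Sxx <- sum(scores^2 * rt)
  vx <- Sxx - Sx^2 / n
  if (vx <= 0 || c1 == 0 || c2 == 0) return(0)
  T1 <- sum(scores * table[, 1])
  VT <- c1 * c2 / (n * (n - 1)) * vx
  (T1 - c1 * Sx / n)^2 / VT
}

#' Exact chi-square test for trend by Monte-Carlo permutation
#'
#' Tests for a monotone association between an ordered characteristic
#' (rows, with numeric scores) and a binary outcome (columns) using the
#' linear-by-linear (Cochran-Armitage-type) chi-square statistic. The
#' reference distribution is the permutation null with both margins fixed,
#' sampled by Monte-Carlo; the p-value uses the add-one estimator
#' `(b + 1) / (reps + 1)` where `b` counts permuted statistics at least as
#' large as the observed one, so a Monte-Carlo p is never exactly 0.
#'
#' @param table k x 2 matrix of counts, rows in their natural order.
#' @param scores strictly increasing row scores; default 0..k-1.
#' @param reps number of Monte-Carlo permutations (>= 10^4).
#' @param seed integer seed making the permutation stream reproducible.
#' @return a [test_result()] with `mc_reps` and `seed` recorded.
#' @export
exact_trend_test <- function(table, scores = seq_len(nrow(table)) - 1,
                             reps = 1e5, seed = 1L) {
  table <- as.matrix(table)
  if (ncol(table) != 2L) stop("table must have 2 columns")
  if (any(table < 0)) stop("counts must be >= 0")
  informative <- rowSums(table) > 0
  if (sum(informative) < 2L) stop("fewer than 2 informative rows")
  if (reps < 1e4) stop("reps must be at least 10^4")
  obs <- trend_statistic(table, scores)
  rt <- rowSums(table)
  ct <- colSums(table)
  n <- sum(table)
  # statistic is a fixed monotone transform of |T - E[T]|, T = score total
  # of column 1, so only T needs simulating
  Sx <- sum(scores * rt)
  ET <- ct[1] * Sx / n
  T_obs_dev <- abs(sum(scores * table[, 1]) - ET)
  b <- 0
  set.seed(seed)
  remaining <- reps
  chunk <- 100000L
  while (remaining > 0) {
    nr <- min(chunk, remaining)
    tabs <- stats::r2dtable(nr, rt, ct)
    Ts <- vapply(tabs, function(tb) sum(scores * tb[, 1]), numeric(1))
    b <- b + sum(abs(Ts - ET) >= T_obs_dev - 1e-9)
    remaining <- remaining - nr
  }
  p <- (b + 1) / (reps + 1)
  test_result(obs, p,
              "Exact chi-square test for trend (Monte-Carlo permutation)",
              n, mc_reps = reps, seed = seed)
}

#' Wilcoxon rank-sum test
#'
#' Two-sided rank-sum comparison of two independent samples: exact
#' enumeration for small untied samples, normal approximation with tie
#' correction otherwise (the behaviour of [stats::wilcox.test()], which
#' performs the computation).
#'
#' @param x,y numeric samples, both non-empty.
#' @return a [test_result()] (statistic = rank-sum W of `x`).
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be non-empty")
  wt <- suppressWarnings(stats::wilcox.test(x, y))
  test_result(unname(wt$statistic), wt$p.value,
              "Wilcoxon rank-sum test (two-sided)", length(x) + length(y))
}

#' Kaplan-Meier product-limit survival curve
#'
#' Estimates melanoma-specific survival: subjects with `event = FALSE`
#' (alive at last contact, or death from another cause) are censored and
#' leave the risk set without a drop in the curve. Computation is by
#' [survival::survfit()].
#'
#' @param times follow-up times in days, non-negative.
#' @param events logical (or 0/1): `TRUE` for a melanoma death.
#' @return list with class `"survival_curve"`: `time`, `n_risk`, `n_event`,
#'   `surv` (estimate after each time), evaluable via `summary`.
#' @export
kaplan_meier <- function(times, events) {
  if (any(times < 0)) stop("times must be >= 0")
  if (length(times) != length(events)) stop("times/events length mismatch")
  fit <- survival::survfit(survival::Surv(times, as.integer(events)) ~ 1,
                           conf.type = "none")
  structure(list(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
                 surv = fit$surv, n = length(times)),
            class = "survival_curve")
}

#' Evaluate a survival curve at given times
#'
#' @param curve a [kaplan_meier()] result.
#' @param t times (days).
#' @return survival probabilities S(t) (right-continuous step function,
#'   S(0) = 1).
#' @export
surv_prob <- function(curve, t) {
  stopifnot(inherits(curve, "survival_curve"))
  vapply(t, function(tt) {
    idx <- which(curve$time <= tt)
    if (length(idx) == 0L) 1 else curve$surv[max(idx)]
  }, numeric(1))
}

#' Log-rank test, optionally for trend
#'
#' Without scores: the standard k-sample log-rank chi-square on k - 1
#' degrees of freedom. With scores (for 3+ ordered groups): the log-rank
#' test for trend, `(s'(O - E))^2 / (s' V s)` on 1 df, built from the
#' observed-minus-expected vector and covariance of [survival::survdiff()].
#' P-values come from the asymptotic chi-square reference distribution.
#'
#' @param times,events follow-up times and melanoma-death indicators.
#' @param group group membership (factor or ordered factor); subjects with
#'   `NA` group are dropped.
#' @param trend_scores optional strictly increasing scores, one per group
#'   level, selecting the trend variant.
#' @return a [test_result()]; `NA` p with a warning when no events occur.
#' @export
logrank <- function(times, events, group, trend_scores = NULL) {
  keep <- !is.na(group) & !is.na(times) & !is.na(events)
  times <- times[keep]; events <- events[keep]
  group <- droplevels(factor(group[keep]))
  if (nlevels(group) < 2L) stop("need at least 2 non-empty groups")
  if (sum(events) == 0) {
    warning("no events in any group: log-rank p undefined")
    return(test_result(NA_real_, NA_real_, "Log-rank test", length(times)))
  }
  sd <- survival::survdiff(
    survival::Surv(times, as.integer(events)) ~ group)
  if (is.null(trend_scores)) {
    df <- nlevels(group) - 1L
    stat <- sd$chisq
    p <- stats::pchisq(stat, df, lower.tail = FALSE)
    return(test_result(stat, p, "Log-rank test", length(times)))
  }
  if (length(trend_scores) != nlevels(group))
    stop("need one trend score per group level")
  if (any(diff(trend_scores) <= 0)) stop("trend scores must be increasing")
  s <- as.numeric(trend_scores)
  d <- sd$obs - sd$exp
  V <- sd$var
  num <- sum(s * d)^2
  den <- drop(t(s) %*% V %*% s)
  if (den <= 0) {
    warning("zero variance in log-rank trend")
    return(test_result(NA_real_, NA_real_, "Log-rank test for trend",
                       length(times)))
  }
  stat <- num / den
  test_result(stat, stats::pchisq(stat, 1, lower.tail = FALSE),
              "Log-rank test for trend", length(times))
}
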