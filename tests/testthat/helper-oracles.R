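# Independent brute-force oracles, deliberately coded along different
# routes than the package implementations they check.

# row-by-row filter-and-count, no vectorization
oracle_count_tmb <- function(df, min_vaf = 0.10) {
  p <- 0L; d <- 0L
  for (i in seq_len(nrow(df))) {
    v <- df[i, ]
    if (is.na(v$vaf) || v$vaf < min_vaf) next
    if (!(v$variant_class %in% c("SNV", "InDel", "essential_splice"))) next
    if (v$coding_effect == "non_coding") next
    if (v$is_driver) d <- d + 1L else p <- p + 1L
  }
  c(passenger = p, driver = d)
}

# two-sided Fisher p by explicit enumeration with binomial coefficients
oracle_fisher_p <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  pr <- vapply(support, function(a)
    exp(lchoose(m, a) + lchoose(n, k - a) - lchoose(m + n, k)), numeric(1))
  p_obs <- pr[support == tab[1, 1]]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
}

# subject-level linear-by-linear statistic: (n-1) * cor(score, outcome)^2
oracle_lbl_stat <- function(tb, scores = seq_len(nrow(tb)) - 1) {
  x <- rep(scores, tb[, 1] + tb[, 2])
  y <- unlist(mapply(function(a, b) c(rep(1, a), rep(0, b)),
                     tb[, 1], tb[, 2], SIMPLIFY = FALSE))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  (length(x) - 1) * stats::cor(x, y)^2
}

# exhaustive two-sided permutation p for a k x 2 table with fixed margins
oracle_trend_p <- function(tab, scores = seq_len(nrow(tab)) - 1) {
  rt <- rowSums(tab); n <- sum(tab); c1 <- sum(tab[, 1])
  obs <- oracle_lbl_stat(tab, scores)
  total_p <- 0
  rec <- function(row, remaining, acc) {
    if (row == length(rt)) {
      if (remaining > rt[row]) return(invisible())
      a <- c(acc, remaining)
      pr <- exp(sum(lchoose(rt, a)) - lchoose(n, c1))
      tb <- cbind(a, rt - a)
      if (oracle_lbl_stat(tb, scores) >= obs - 1e-9)
        total_p <<- total_p + pr
      invisible()
    } else {
      for (ai in 0:min(rt[row], remaining))
        rec(row + 1L, remaining - ai, c(acc, ai))
      invisible()
    }
  }
  rec(1L, c1, integer(0))
  min(1, total_p)
}

# small random variant table generator used by several property tests
random_variant_table <- function(n) {
  data.frame(
    chrom = "chr1", pos = seq_len(n), ref = "A", alt = "G",
    gene = sprintf("G%04d", sample(710, n, replace = TRUE)),
    variant_class = sample(c("SNV", "InDel", "essential_splice", "other"),
                           n, replace = TRUE),
    coding_effect = sample(c("synonymous", "non_synonymous", "splice",
                             "non_coding"), n, replace = TRUE),
    vaf = round(stats::runif(n), 3),
    is_driver = sample(c(TRUE, FALSE), n, replace = TRUE),
    stringsAsFactors = FALSE)
}
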