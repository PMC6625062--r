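#' Cross-tabulate a patient characteristic against response
#'
#' @param classification classified cohort (one row per patient) with a
#'   `response` column (`"responder"` / `"non_responder"`).
#' @param var name of the characteristic column.
#' @param levels row order for the table (best prognosis first); defaults
#'   to factor levels or sorted unique values.
#' @return k x 2 integer matrix, columns `responder`, `non_responder`;
#'   patients with a missing characteristic are excluded (per-analysis
#'   denominators therefore vary).
#' @export
response_table <- function(classification, var, levels = NULL) {
  v <- classification[[var]]
  if (is.null(v)) stop("no such column: ", var)
  if (is.logical(v)) v <- factor(v, levels = c(TRUE, FALSE))
  if (is.null(levels)) {
    levels <- if (is.factor(v)) base::levels(v) else sort(unique(v[!is.na(v)]))
  }
  v <- factor(as.character(v), levels = as.character(levels))
  resp <- factor(classification$response,
                 levels = c("responder", "non_responder"))
  keep <- !is.na(v) & !is.na(resp)
  tab <- table(v[keep], resp[keep])
  m <- matrix(as.integer(tab), nrow = nlevels(v),
              dimnames = list(levels(v), c("responder", "non_responder")))
  m
}

.marker_rows <- list(
  list(characteristic = "TMB [Mut/Mb]", var = "tmb_high",
       levels = c("TRUE", "FALSE"), labels = c("> 23", "<= 23")),
  list(characteristic = "ctDNA detection at first follow-up",
       var = "ctdna_detectable_fu",
       levels = c("FALSE", "TRUE"),
       labels = c("Not detectable", "Detectable")),
  list(characteristic = "ctDNA increase at first follow-up",
       var = "ctdna_increasing",
       levels = c("FALSE", "TRUE"),
       labels = c("Not increasing", "Increasing")),
  list(characteristic = "Cell-free DNA change", var = "cfdna_change",
       levels = c("decrease_gt50", "stable", "increase_gt50"),
       labels = c("Decrease > 50%", "Stable", "Increase > 50%")),
  list(characteristic = "LDH baseline elevated", var = "ldh_elevated",
       levels = c("FALSE", "TRUE"), labels = c("No", "Yes")),
  list(characteristic = "Targeted therapy before",
       var = "prior_targeted_therapy",
       levels = c("FALSE", "TRUE"), labels = c("No", "Yes")),
  list(characteristic = "Sex", var = "sex",
       levels = c("male", "female"), labels = c("Male", "Female")),
  list(characteristic = "Liver metastasis baseline", var = "liver_mets",
       levels = c("FALSE", "TRUE"), labels = c("No", "Yes")),
  list(characteristic = "PD-L1 expression", var = "pd_l1",
       levels = c(">=1%", "<1%"), labels = c(">= 1%", "< 1%"))
)

.analyze_characteristic <- function(classification, var, levels,
                                    mc_reps, seed) {
  tab <- response_table(classification, var, levels)
  informative <- rowSums(tab) > 0
  p_resp <- resp_method <- NA
  if (sum(informative) >= 2L && all(colSums(tab) > 0)) {
    if (nrow(tab) == 2L && all(informative)) {
      ft <- fisher_exact_two_sided(tab)
      p_resp <- ft$p_value; resp_method <- "Fisher exact"
    } else {
      tt <- exact_trend_test(tab[informative, , drop = FALSE],
                             reps = mc_reps, seed = seed)
      p_resp <- tt$p_value
      resp_method <- "Exact chi-square trend (Monte-Carlo)"
    }
  }
  v <- classification[[var]]
  if (is.logical(v)) v <- factor(v, levels = c(TRUE, FALSE))
  v <- factor(as.character(v), levels = levels)
  p_os <- os_method <- NA
  grp_n <- table(v[!is.na(classification$os_days)])
  if (sum(grp_n > 0) >= 2L && sum(classification$event[!is.na(v)],
                                  na.rm = TRUE) > 0) {
    scores <- if (sum(grp_n > 0) > 2L) seq_along(levels)[grp_n > 0] else NULL
    lr <- tryCatch(
      logrank(classification$os_days, classification$event, v,
              trend_scores = scores),
      warning = function(w) NULL, error = function(e) NULL)
    if (!is.null(lr)) {
      p_os <- lr$p_value
      os_method <- if (is.null(scores)) "Log-rank" else "Log-rank for trend"
    }
  }
  list(table = tab, p_response = p_resp, response_method = resp_method,
       p_os = p_os, os_method = os_method)
}

#' Response and survival associations of patient characteristics
#'
#' Reproduces the structure of the cohort characteristics table: for each
#' marker or clinical covariate it reports the responder / non-responder
#' counts per level, the exact association p-value with response (Fisher
#' for 2-level characteristics, Monte-Carlo exact chi-square trend for
#' ordered 3-level ones), and the overall-survival p-value (log-rank, or
#' log-rank for trend for 3+ ordered levels). Patients missing a
#' characteristic are excluded from that row block only. No
#' multiple-testing adjustment is applied.
#'
#' @param classification classified cohort from [classify_cohort()].
#' @param mc_reps Monte-Carlo permutations for trend tests.
#' @param seed seed for the Monte-Carlo stream.
#' @return data.frame with columns `characteristic`, `level`, `total`,
#'   `responder`, `non_responder`, `p_response`, `response_method`,
#'   `p_os`, `os_method` (test results on the first row of each block).
#' @export
marker_association_table <- function(classification, mc_reps = 1e5, seed = 1L) {
  if (nrow(classification) == 0L) stop("empty cohort")
  blocks <- lapply(.marker_rows, function(row) {
    res <- .analyze_characteristic(classification, row$var, row$levels,
                                   mc_reps, seed)
    k <- nrow(res$table)
    data.frame(characteristic = row$characteristic,
               level = row$labels,
               total = rowSums(res$table),
               responder = res$table[, "responder"],
               non_responder = res$table[, "non_responder"],
               p_response = c(res$p_response, rep(NA, k - 1L)),
               response_method = c(res$response_method, rep(NA, k - 1L)),
               p_os = c(res$p_os, rep(NA, k - 1L)),
               os_method = c(res$os_method, rep(NA, k - 1L)),
               row.names = NULL)
  })
  do.call(rbind, blocks)
}

#' Response and survival associations of combined TMB x marker variables
#'
#' Same layout as [marker_association_table()] for the five ordered combined variables
#' (TMB x ctDNA detection, TMB x ctDNA increase, TMB x cfDNA change,
#' TMB x liver metastases, TMB x sex), tested with the Monte-Carlo exact
#' chi-square trend test for response and the log-rank test for trend for
#' survival. Combined levels not observed in the cohort are omitted.
#'
#' @inheritParams marker_association_table
#' @return data.frame in the same format as [marker_association_table()].
#' @export
combined_variable_table <- function(classification, mc_reps = 1e5, seed = 1L) {
  if (nrow(classification) == 0L) stop("empty cohort")
  vars <- c("combined_tmb_ctdna_detect", "combined_tmb_ctdna_increase",
            "combined_tmb_cfdna", "combined_tmb_liver", "combined_tmb_sex")
  titles <- c("TMB x ctDNA detection", "TMB x ctDNA increase",
              "TMB x cfDNA change", "TMB x liver metastases", "TMB x sex")
  blocks <- Map(function(var, title) {
    lev <- levels(droplevels(classification[[var]]))
    res <- .analyze_characteristic(classification, var, lev, mc_reps, seed)
    k <- nrow(res$table)
    data.frame(characteristic = title,
               level = rownames(res$table),
               total = rowSums(res$table),
               responder = res$table[, "responder"],
               non_responder = res$table[, "non_responder"],
               p_response = c(res$p_response, rep(NA, k - 1L)),
               response_method = c(res$response_method, rep(NA, k - 1L)),
               p_os = c(res$p_os, rep(NA, k - 1L)),
               os_method = c(res$os_method, rep(NA, k - 1L)),
               row.names = NULL)
  }, vars, titles)
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}
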