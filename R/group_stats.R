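# Descriptive stratum summaries and the between-group rank-sum comparison.

#' Stratum-level descriptive summary with group comparison
#'
#' Per sex/age stratum and test: sample size, mean and sample SD (n-1
#' denominator) of the per-side minima in each group, and the two-sided
#' Wilcoxon rank-sum p-value for the control-vs-DCM comparison. Cells with a
#' single subject carry `NA` SD; strata missing a group are reported with
#' `NA` p-value and a message.
#'
#' @param data cohort data frame (raw or scored).
#' @return object of class `dcm_summary_table`: data frame with columns
#'   `test`, `sex`, `age_band`, `n_control`, `n_dcm`, `mean_control`,
#'   `sd_control`, `mean_dcm`, `sd_dcm`, `p_value`.
#' @examples
#' coh <- simulate_cohort(seed = 7)
#' summarize_cohort(coh)
#' @export
summarize_cohort <- function(data) {
  sc <- score_cohort(data)
  if (!nrow(sc)) insufficient_data_error("empty cohort")
  st <- strata()
  present <- unique(stratum_label(sc$sex, sc$age_band))
  st <- st[stratum_label(st$sex, st$age_band) %in% present, , drop = FALSE]
  rows <- list()
  for (test in c("grt", "grip")) {
    val <- if (test == "grt") sc$grt_min else sc$grip_min
    for (i in seq_len(nrow(st))) {
      in_st <- sc$sex == st$sex[i] & sc$age_band == st$age_band[i]
      ctrl <- val[in_st & sc$group == "control"]
      dcm <- val[in_st & sc$group == "dcm"]
      if (!length(ctrl) || !length(dcm)) {
        message(sprintf("stratum %s lacks a %s group; p-value omitted",
                        stratum_label(st$sex[i], st$age_band[i]),
                        if (length(ctrl)) "DCM" else "control"))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        test = test, sex = st$sex[i], age_band = st$age_band[i],
        n_control = length(ctrl), n_dcm = length(dcm),
        mean_control = if (length(ctrl)) mean(ctrl) else NA_real_,
        sd_control = if (length(ctrl) > 1L) stats::sd(ctrl) else NA_real_,
        mean_dcm = if (length(dcm)) mean(dcm) else NA_real_,
        sd_dcm = if (length(dcm) > 1L) stats::sd(dcm) else NA_real_,
        p_value = if (length(ctrl) && length(dcm)) rank_sum_test(ctrl, dcm)
                  else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("dcm_summary_table", "data.frame")
  out
}

#' @export
print.dcm_summary_table <- function(x, ...) {
  df <- data.frame(
    test = x$test, sex = x$sex, age_band = x$age_band,
    n = sprintf("%d/%d", x$n_control, x$n_dcm),
    control = fmt_mean_sd(x$mean_control, x$sd_control),
    dcm = fmt_mean_sd(x$mean_dcm, x$sd_dcm),
    p = ifelse(is.na(x$p_value), "-",
               ifelse(x$p_value < 1e-4, "<0.0001", sprintf("%.4f", x$p_value))),
    stringsAsFactors = FALSE)
  cat("Stratum summaries (per-side minima, mean ± SD, control/DCM)\n")
  print(df, row.names = FALSE)
  invisible(x)
}

fmt_mean_sd <- function(m, s) {
  ifelse(is.na(m), "-",
         ifelse(is.na(s), sprintf("%.1f ± NA", m),
                sprintf("%.1f ± %.1f", m, s)))
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Mid-rank tie handling throughout. When both groups have at most 10
#' observations the two-sided p-value is computed by full enumeration of all
#' rank assignments (exact even in the presence of ties, where
#' [stats::wilcox.test()] cannot be exact); otherwise it delegates to the
#' normal approximation of [stats::wilcox.test()] with tie-corrected
#' variance and continuity correction - appropriate here because integer GRT
#' counts are heavily tied. If every value in both groups is identical the
#' p-value is 1 by convention.
#'
#' @param a,b numeric vectors, both nonempty.
#' @return two-sided p-value.
#' @examples
#' rank_sum_test(1:3, 4:6)  # 0.1, the smallest attainable for 3 vs 3
#' @export
rank_sum_test <- function(a, b) {
  if (!length(a) || !length(b)) {
    insufficient_data_error("both groups must be nonempty")
  }
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1L) return(1)
  n1 <- length(a)
  if (n1 <= 10L && length(b) <= 10L) {
    r <- rank(pooled)
    w_obs <- sum(r[seq_len(n1)])
    combs <- utils::combn(length(pooled), n1)
    w_all <- colSums(matrix(r[combs], nrow = n1))
    e <- n1 * (length(pooled) + 1) / 2
    mean(abs(w_all - e) >= abs(w_obs - e) - 1e-9)
  } else {
    suppressWarnings(
      stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
  }
}
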