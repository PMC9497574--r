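# Empirical ROC analysis for negatively-oriented tests: lower values indicate
# disease, and a value at or below the threshold is called abnormal.

#' Empirical (Mann-Whitney) AUC for a negatively-oriented test
#'
#' AUC = P(case < control) + 1/2 P(case = control) over all case x control
#' pairs, computed from the joint rank statistic (ties get weight 1/2, the
#' standard Mann-Whitney convention - relevant because GRT counts are
#' integers with many ties). Identical to the trapezoidal area under
#' [roc_curve()].
#'
#' @param case_values numeric scores of the condition-positive (DCM) group.
#' @param control_values numeric scores of the control group.
#' @return list with `auc`, `n_cases`, `n_controls`.
#' @examples
#' empirical_auc(c(10, 15, 21), c(20, 22, 25))$auc  # 8/9
#' @export
empirical_auc <- function(case_values, control_values) {
  n1 <- length(case_values)
  n0 <- length(control_values)
  if (n1 == 0L || n0 == 0L) {
    insufficient_data_error("both case and control groups must be nonempty")
  }
  r <- rank(c(case_values, control_values))
  # U = number of (control > case) pairs, ties counted half
  r_ctrl <- sum(r[(n1 + 1L):(n1 + n0)])
  u <- r_ctrl - as.numeric(n0) * (n0 + 1) / 2
  list(auc = u / (as.numeric(n1) * n0), n_cases = n1, n_controls = n0)
}

#' Empirical ROC curve
#'
#' Candidate thresholds are the distinct observed values; at each threshold
#' `t`, sensitivity is the fraction of cases with value `<= t` and the false
#' positive rate is the fraction of controls with value `<= t`. A sentinel
#' below the minimum contributes the (0, 0) corner; the largest observed
#' value contributes (1, 1). The curve is a monotone staircase.
#'
#' @inheritParams empirical_auc
#' @return object of class `dcm_roc`: list with `thresholds` (ascending,
#'   first entry `-Inf` for the sentinel), `fpr`, `tpr`, and `auc`
#'   (trapezoidal area).
#' @export
roc_curve <- function(case_values, control_values) {
  if (!length(case_values) || !length(control_values)) {
    insufficient_data_error("both case and control groups must be nonempty")
  }
  thr <- sort(unique(c(case_values, control_values)))
  sc <- sort(case_values)
  sk <- sort(control_values)
  tpr <- findInterval(thr, sc) / length(sc)
  fpr <- findInterval(thr, sk) / length(sk)
  thr <- c(-Inf, thr)
  tpr <- c(0, tpr)
  fpr <- c(0, fpr)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  structure(list(thresholds = thr, fpr = fpr, tpr = tpr, auc = auc),
            class = "dcm_roc")
}

#' @export
print.dcm_roc <- function(x, ...) {
  cat(sprintf("Empirical ROC curve: %d threshold(s), AUC = %.4f\n",
              length(x$thresholds) - 1L, x$auc))
  invisible(x)
}

#' @export
plot.dcm_roc <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "s", xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "1 - specificity", ylab = "sensitivity", ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  invisible(x)
}

#' Positive and negative likelihood ratios
#'
#' `lr_pos = sensitivity / (1 - specificity)` and
#' `lr_neg = (1 - sensitivity) / specificity`. At specificity 1 the positive
#' likelihood ratio is undefined (zero false-positive rate) and is reported
#' as `Inf`; serializers print it as `"inf"`.
#'
#' @param sensitivity,specificity proportions in \[0, 1\].
#' @return list with `lr_pos` and `lr_neg`.
#' @examples
#' likelihood_ratios(0.68, 0.85)  # lr_pos 4.53, lr_neg 0.38 (2 dp)
#' @export
likelihood_ratios <- function(sensitivity, specificity) {
  lr_pos <- ifelse(specificity < 1, sensitivity / (1 - specificity), Inf)
  lr_neg <- ifelse(specificity > 0, (1 - sensitivity) / specificity, NaN)
  list(lr_pos = lr_pos, lr_neg = lr_neg)
}

#' Youden-index optimal cutoff
#'
#' Scans every distinct observed value as a candidate cutoff under the
#' "value <= cutoff is abnormal" orientation and returns the one maximizing
#' the Youden index J = sensitivity + specificity - 1. Ties in J are broken
#' by preferring, under the default `"sensitivity"` rule, the higher
#' sensitivity and then the larger cutoff - a screening tool should miss as
#' few cases as possible; `"specificity"` prefers the higher specificity and
#' then the smaller cutoff.
#'
#' @inheritParams empirical_auc
#' @param tie_break `"sensitivity"` (default) or `"specificity"`.
#' @return object of class `dcm_cutoff`: list with `cutoff`, `youden_j`,
#'   `sensitivity`, `specificity`, `lr_pos`, `lr_neg`.
#' @examples
#' youden_cutoff(c(10, 15, 19, 21), c(18, 20, 22, 25))  # cutoff 21, J 0.5
#' @export
youden_cutoff <- function(case_values, control_values,
                          tie_break = c("sensitivity", "specificity")) {
  tie_break <- match.arg(tie_break)
  if (!length(case_values) || !length(control_values)) {
    insufficient_data_error("both case and control groups must be nonempty")
  }
  thr <- sort(unique(c(case_values, control_values)))
  sens <- findInterval(thr, sort(case_values)) / length(case_values)
  spec <- 1 - findInterval(thr, sort(control_values)) / length(control_values)
  j <- sens + spec - 1
  best <- which(j >= max(j) - 1e-12)
  if (tie_break == "sensitivity") {
    best <- best[sens[best] >= max(sens[best]) - 1e-12]
    pick <- best[which.max(thr[best])]
  } else {
    best <- best[spec[best] >= max(spec[best]) - 1e-12]
    pick <- best[which.min(thr[best])]
  }
  lr <- likelihood_ratios(sens[pick], spec[pick])
  structure(list(cutoff = thr[pick], youden_j = j[pick],
                 sensitivity = sens[pick], specificity = spec[pick],
                 lr_pos = lr$lr_pos, lr_neg = lr$lr_neg),
            class = "dcm_cutoff")
}

#' @export
print.dcm_cutoff <- function(x, ...) {
  cat(sprintf(
    "Youden cutoff %.4g (J = %.3f): sensitivity %.2f, specificity %.2f, LR+ %s, LR- %.2f\n",
    x$cutoff, x$youden_j, x$sensitivity, x$specificity,
    fmt_lr(x$lr_pos), x$lr_neg))
  invisible(x)
}

fmt_lr <- function(x) ifelse(is.infinite(x), "inf", sprintf("%.2f", x))

# Round half-up for display (Table-style formatting); internal values keep
# full precision.
round_half_up <- function(x, digits = 2L) {
  s <- sign(x)
  s * floor(abs(x) * 10^digits + 0.5) / 10^digits
}
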