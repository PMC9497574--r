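# The fitting function: derive a stratified screening tool from a labelled
# case-control cohort.

#' Derive a stratified DCM screening tool from a cohort
#'
#' For every sex/age stratum present in the cohort, derives a Youden-index
#' optimal cutoff independently for each test (GRT repetitions and grip
#' strength, both on per-side minima, both with the "at or below the cutoff
#' is abnormal" orientation) together with the stratum's empirical ROC curve
#' and AUC. The fitted object is the screening tool itself: a per-stratum
#' cutoff pair, applied downstream with the OR-combination rule (positive if
#' either test is abnormal).
#'
#' Strata entirely absent from the cohort are dropped with a warning; a
#' stratum present with only one group is an error, since no cutoff can be
#' derived there.
#'
#' @param data cohort data frame with raw bilateral measurements (see
#'   [read_cohort()]) or an already scored cohort (see [score_cohort()]).
#' @param tie_break Youden tie-breaking rule, see [youden_cutoff()].
#' @return object of class `dcm_tool`, a list with components:
#'   \describe{
#'     \item{cutoffs}{data frame `sex`, `age_band`, `grt_cutoff`,
#'       `grip_cutoff` - the tool.}
#'     \item{detail}{per (test, stratum) row: `auc`, `cutoff`, `youden_j`,
#'       `sensitivity`, `specificity`, `lr_pos`, `lr_neg`, `n_cases`,
#'       `n_controls` (resubstitution metrics at the derived cutoff).}
#'     \item{roc}{named list of [roc_curve()] objects, one per
#'       test/stratum.}
#'     \item{scores}{the scored cohort used for fitting.}
#'   }
#' @examples
#' coh <- simulate_cohort(seed = 42)
#' fit <- dcm_tool(coh)
#' fit                 # Table-3 style cutoff table
#' coef(fit)           # cutoff matrix
#' summary(fit)        # per-test ROC detail + combined-rule performance
#' head(predict(fit))  # resubstitution classifications
#' @seealso [evaluate_performance()], [table3_cutoffs()] for the shipped
#'   published tool.
#' @export
dcm_tool <- function(data, tie_break = c("sensitivity", "specificity")) {
  tie_break <- match.arg(tie_break)
  scores <- score_cohort(data)
  if (!nrow(scores)) insufficient_data_error("empty cohort")

  st <- strata()
  present <- stratum_label(scores$sex, scores$age_band)
  keep <- stratum_label(st$sex, st$age_band) %in% present
  if (!all(keep)) {
    warning(sprintf("no subjects in stratum(s): %s; omitted from the tool",
                    paste(stratum_label(st$sex, st$age_band)[!keep],
                          collapse = "; ")))
    st <- st[keep, , drop = FALSE]
  }

  detail <- list()
  roc <- list()
  cut <- st
  cut$grt_cutoff <- NA_real_
  cut$grip_cutoff <- NA_real_
  for (i in seq_len(nrow(st))) {
    in_st <- scores$sex == st$sex[i] & scores$age_band == st$age_band[i]
    for (test in c("grt", "grip")) {
      val <- if (test == "grt") scores$grt_min else scores$grip_min
      cases <- val[in_st & scores$group == "dcm"]
      controls <- val[in_st & scores$group == "control"]
      if (!length(cases) || !length(controls)) {
        insufficient_data_error(sprintf(
          "stratum %s has no %s; cannot derive a cutoff",
          stratum_label(st$sex[i], st$age_band[i]),
          if (length(cases)) "controls" else "cases"))
      }
      yc <- youden_cutoff(cases, controls, tie_break = tie_break)
      auc <- empirical_auc(cases, controls)
      detail[[length(detail) + 1L]] <- data.frame(
        test = test, sex = st$sex[i], age_band = st$age_band[i],
        auc = auc$auc, cutoff = yc$cutoff, youden_j = yc$youden_j,
        sensitivity = yc$sensitivity, specificity = yc$specificity,
        lr_pos = yc$lr_pos, lr_neg = yc$lr_neg,
        n_cases = auc$n_cases, n_controls = auc$n_controls,
        stringsAsFactors = FALSE)
      roc[[paste(test, stratum_label(st$sex[i], st$age_band[i]))]] <-
        roc_curve(cases, controls)
      cut[[paste0(test, "_cutoff")]][i] <- yc$cutoff
    }
  }
  structure(list(cutoffs = cut,
                 detail = do.call(rbind, detail),
                 roc = roc,
                 scores = scores,
                 tie_break = tie_break,
                 call = match.call()),
            class = "dcm_tool")
}

#' @export
print.dcm_tool <- function(x, ...) {
  cat("Stratified DCM screening tool (abnormal if value <= cutoff;\n")
  cat("positive if either test abnormal)\n\n")
  df <- x$cutoffs
  names(df) <- c("Sex", "Age (y)", "GRT (times)", "Grip strength (kg)")
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
coef.dcm_tool <- function(object, ...) {
  m <- as.matrix(object$cutoffs[, c("grt_cutoff", "grip_cutoff")])
  rownames(m) <- stratum_label(object$cutoffs$sex, object$cutoffs$age_band)
  colnames(m) <- c("grt", "grip")
  m
}

#' @rdname dcm_tool
#' @param object,x a fitted `dcm_tool`.
#' @param ... unused.
#' @export
summary.dcm_tool <- function(object, ...) {
  structure(list(detail = object$detail,
                 performance = evaluate_performance(object, object$scores),
                 n = nrow(object$scores),
                 call = object$call),
            class = "summary.dcm_tool")
}

#' @export
print.summary.dcm_tool <- function(x, ...) {
  cat("Stratified DCM screening tool -", x$n, "subjects\n\n")
  cat("Per-test ROC analysis (resubstitution, per stratum):\n")
  df <- x$detail
  for (col in c("auc", "youden_j", "sensitivity", "specificity", "lr_neg")) {
    df[[col]] <- sprintf("%.2f", round_half_up(df[[col]], 2L))
  }
  df$lr_pos <- fmt_lr(round_half_up(df$lr_pos, 2L))
  print(df, row.names = FALSE)
  cat("\nRule performance (single tests and OR combination):\n")
  print(x$performance)
  invisible(x)
}

#' Predict screening classes for new subjects
#'
#' Applies the fitted tool's cutoffs and the OR rule to `newdata` (or, by
#' default, resubstitutes the training cohort).
#'
#' @param object a fitted [dcm_tool()].
#' @param newdata cohort data frame (raw or scored); default: training data.
#' @param type `"class"` for a factor of `"negative"`/`"positive"`,
#'   `"detail"` for the full per-subject classification data frame.
#' @param ... unused.
#' @return factor or data frame, see `type`.
#' @export
predict.dcm_tool <- function(object, newdata = NULL,
                             type = c("class", "detail"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) newdata <- object$scores
  cls <- classify_cohort(object, newdata)
  if (type == "class") {
    factor(cls$class, levels = c("negative", "positive"))
  } else {
    cls
  }
}

#' Plot the fitted per-stratum ROC curves
#'
#' One panel per stratum with the GRT and grip-strength staircases and their
#' AUCs; the derived cutoff's operating point is marked.
#'
#' @param x a fitted [dcm_tool()].
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.dcm_tool <- function(x, ...) {
  st <- x$cutoffs
  old <- graphics::par(mfrow = c(2L, ceiling(nrow(st) / 2)),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (i in seq_len(nrow(st))) {
    lab <- stratum_label(st$sex[i], st$age_band[i])
    r_grt <- x$roc[[paste("grt", lab)]]
    r_grip <- x$roc[[paste("grip", lab)]]
    graphics::plot(r_grt$fpr, r_grt$tpr, type = "s", col = "steelblue",
                   xlim = c(0, 1), ylim = c(0, 1), main = lab,
                   xlab = "1 - specificity", ylab = "sensitivity", ...)
    graphics::lines(r_grip$fpr, r_grip$tpr, type = "s", col = "firebrick")
    graphics::abline(0, 1, lty = 3, col = "grey60")
    d <- x$detail[x$detail$sex == st$sex[i] & x$detail$age_band == st$age_band[i], ]
    graphics::points(1 - d$specificity, d$sensitivity, pch = 19,
                     col = c("steelblue", "firebrick"))
    graphics::legend("bottomright", bty = "n", cex = 0.8,
                     legend = sprintf("%s AUC %.2f", d$test, d$auc),
                     col = c("steelblue", "firebrick"), lty = 1)
  }
  invisible(x)
}
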