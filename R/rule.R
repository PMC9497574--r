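# The screening rule: a test is abnormal when the per-side minimum is at or
# below the stratum cutoff; the combined tool is positive when either test is
# abnormal (parallel / OR combination). Performance is summarized per stratum
# and pooled from summed confusion counts.

resolve_cutoffs <- function(cutoffs) {
  if (inherits(cutoffs, "dcm_tool")) cutoffs <- cutoffs$cutoffs
  req <- c("sex", "age_band", "grt_cutoff", "grip_cutoff")
  if (!is.data.frame(cutoffs) || !all(req %in% names(cutoffs))) {
    config_error(
      "cutoffs must be a dcm_tool or a data frame with sex, age_band, grt_cutoff, grip_cutoff")
  }
  cutoffs
}

#' Classify subjects with a cutoff table
#'
#' Applies the abnormal-if-at-or-below rule per test and the OR combination
#' across tests, using each subject's stratum row of `cutoffs`.
#'
#' @param cutoffs a [dcm_tool()] fit or a cutoff data frame such as
#'   [table3_cutoffs()].
#' @param data cohort data frame (raw bilateral columns or already scored).
#' @return data frame with columns `id`, `sex`, `age_band`, `grt_min`,
#'   `grip_min`, `grt_abnormal`, `grip_abnormal`, and `class`
#'   (`"positive"`/`"negative"`).
#' @examples
#' coh <- simulate_cohort(seed = 1)
#' head(classify_cohort(table3_cutoffs(), coh))
#' @export
classify_cohort <- function(cutoffs, data) {
  cutoffs <- resolve_cutoffs(cutoffs)
  sc <- score_cohort(data)
  key <- stratum_label(sc$sex, sc$age_band)
  ckey <- stratum_label(cutoffs$sex, cutoffs$age_band)
  idx <- match(key, ckey)
  if (anyNA(idx)) {
    config_error(sprintf("no cutoffs for stratum(s): %s",
                         paste(unique(key[is.na(idx)]), collapse = "; ")))
  }
  grt_ab <- sc$grt_min <= cutoffs$grt_cutoff[idx]
  grip_ab <- sc$grip_min <= cutoffs$grip_cutoff[idx]
  data.frame(
    id = sc$id, group = sc$group, sex = sc$sex, age_band = sc$age_band,
    grt_min = sc$grt_min, grip_min = sc$grip_min,
    grt_abnormal = grt_ab, grip_abnormal = grip_ab,
    class = ifelse(grt_ab | grip_ab, "positive", "negative"),
    stringsAsFactors = FALSE
  )
}

confusion_metrics <- function(tp, fp, fn, tn) {
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  lr <- if (is.na(sens) || is.na(spec)) list(lr_pos = NA_real_, lr_neg = NA_real_)
        else likelihood_ratios(sens, spec)
  list(sensitivity = sens, specificity = spec,
       lr_pos = lr$lr_pos, lr_neg = lr$lr_neg)
}

#' Evaluate screening performance per stratum and pooled
#'
#' Builds a confusion table per sex/age stratum (DCM is the
#' condition-positive class) for each requested rule - each test alone and
#' the OR combination - and appends a pooled `"total"` row per rule computed
#' from the summed counts (not from averaged stratum metrics). A stratum with
#' no cases or no controls keeps its counts but has its undefined metrics
#' flagged as `NA`.
#'
#' @inheritParams classify_cohort
#' @param tests subset of `c("grt", "grip", "combined")`.
#' @return object of class `dcm_performance`: data frame with columns `test`,
#'   `sex`, `age_band`, `tp`, `fp`, `fn`, `tn`, `sensitivity`, `specificity`,
#'   `lr_pos`, `lr_neg`; pooled rows have `age_band == "total"`.
#' @examples
#' coh <- simulate_cohort(seed = 1)
#' evaluate_performance(table3_cutoffs(), coh)
#' @export
evaluate_performance <- function(cutoffs, data,
                                 tests = c("grt", "grip", "combined")) {
  tests <- match.arg(tests, several.ok = TRUE)
  cls <- classify_cohort(cutoffs, data)
  if (!nrow(cls)) insufficient_data_error("empty cohort")
  st <- strata()
  st <- st[stratum_label(st$sex, st$age_band) %in%
             unique(stratum_label(cls$sex, cls$age_band)), , drop = FALSE]

  rows <- list()
  for (test in tests) {
    pos <- switch(test,
                  grt = cls$grt_abnormal,
                  grip = cls$grip_abnormal,
                  combined = cls$grt_abnormal | cls$grip_abnormal)
    is_case <- cls$group == "dcm"
    for (i in seq_len(nrow(st))) {
      in_st <- cls$sex == st$sex[i] & cls$age_band == st$age_band[i]
      tp <- sum(in_st & is_case & pos)
      fn <- sum(in_st & is_case & !pos)
      fp <- sum(in_st & !is_case & pos)
      tn <- sum(in_st & !is_case & !pos)
      m <- confusion_metrics(tp, fp, fn, tn)
      rows[[length(rows) + 1L]] <- data.frame(
        test = test, sex = st$sex[i], age_band = st$age_band[i],
        tp = tp, fp = fp, fn = fn, tn = tn,
        sensitivity = m$sensitivity, specificity = m$specificity,
        lr_pos = m$lr_pos, lr_neg = m$lr_neg, stringsAsFactors = FALSE)
    }
    tot <- colSums(do.call(rbind, lapply(
      rows[(length(rows) - nrow(st) + 1L):length(rows)],
      function(r) unlist(r[c("tp", "fp", "fn", "tn")]))))
    m <- confusion_metrics(tot["tp"], tot["fp"], tot["fn"], tot["tn"])
    rows[[length(rows) + 1L]] <- data.frame(
      test = test, sex = NA_character_, age_band = "total",
      tp = tot[["tp"]], fp = tot[["fp"]], fn = tot[["fn"]], tn = tot[["tn"]],
      sensitivity = m$sensitivity, specificity = m$specificity,
      lr_pos = m$lr_pos, lr_neg = m$lr_neg, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("dcm_performance", "data.frame")
  out
}

#' @export
print.dcm_performance <- function(x, digits = 2L, ...) {
  cat("Screening performance (DCM = condition positive)\n")
  df <- as.data.frame(x)
  for (col in c("sensitivity", "specificity", "lr_neg")) {
    df[[col]] <- sprintf(paste0("%.", digits, "f"), round_half_up(df[[col]], digits))
  }
  df$lr_pos <- fmt_lr(round_half_up(df$lr_pos, digits))
  df$sex[is.na(df$sex)] <- ""
  print(df, row.names = FALSE)
  if (any(is.infinite(x$lr_pos))) {
    cat("LR+ = inf: specificity 1 (no false positives); division by zero.\n")
  }
  invisible(x)
}

#' Classify one subject with the screening tool
#'
#' Convenience single-subject interface for bedside use: takes the raw
#' bilateral measurements, forms per-side minima, locates the sex/age
#' stratum, applies both cutoffs and the OR rule.
#'
#' @param sex `"male"` or `"female"`.
#' @param age integer age in years, 40-89.
#' @param grt_left,grt_right GRT repetition counts per 10 s.
#' @param grip_left,grip_right grip strength in kg.
#' @param cutoffs a [dcm_tool()] fit or cutoff table; defaults to the
#'   shipped tool [table3_cutoffs()].
#' @return object of class `dcm_verdict`: list with the stratum, minima,
#'   applied cutoffs, per-test abnormal flags and overall
#'   `"positive"`/`"negative"` class.
#' @examples
#' classify_subject("male", 72, grt_left = 16, grt_right = 14,
#'                  grip_left = 22, grip_right = 20.5)
#' @export
classify_subject <- function(sex, age, grt_left, grt_right,
                             grip_left, grip_right,
                             cutoffs = table3_cutoffs()) {
  df <- data.frame(id = "subject", group = "dcm", sex = sex, age = age,
                   grt_left = grt_left, grt_right = grt_right,
                   grip_left = grip_left, grip_right = grip_right,
                   stringsAsFactors = FALSE)
  cls <- classify_cohort(cutoffs, df)
  ct <- resolve_cutoffs(cutoffs)
  i <- match(stratum_label(cls$sex, cls$age_band),
             stratum_label(ct$sex, ct$age_band))
  structure(list(sex = cls$sex, age = age, age_band = cls$age_band,
                 grt_min = cls$grt_min, grip_min = cls$grip_min,
                 grt_cutoff = ct$grt_cutoff[i], grip_cutoff = ct$grip_cutoff[i],
                 grt_abnormal = cls$grt_abnormal,
                 grip_abnormal = cls$grip_abnormal,
                 class = cls$class),
            class = "dcm_verdict")
}

#' @export
print.dcm_verdict <- function(x, ...) {
  cat(sprintf("Stratum: %s %s\n", x$sex, x$age_band))
  cat(sprintf("  GRT  min %g vs cutoff %g -> %s\n", x$grt_min, x$grt_cutoff,
              if (x$grt_abnormal) "abnormal" else "normal"))
  cat(sprintf("  Grip min %g kg vs cutoff %g kg -> %s\n", x$grip_min,
              x$grip_cutoff, if (x$grip_abnormal) "abnormal" else "normal"))
  cat(sprintf("Screening result: %s\n", toupper(x$class)))
  cat("Note: this is a screening support tool only; a positive result\n")
  cat("warrants specialist referral, not a diagnosis.\n")
  invisible(x)
}
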