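# Published stratum-level inputs: descriptive parameters, shipped cutoffs and
# reported diagnostic performance. These are the printed numbers the package
# treats as inputs -- the generator's defaults, the shipped screening tool and
# the reference values its arithmetic is checked against.

#' Default stratum parameters for the synthetic cohort generator
#'
#' One row per (sex, age band, group) cell with the published sample size and
#' the mean and standard deviation of the per-side minimum GRT repetition
#' count and grip strength (kg). These define the study conditions the
#' generator emulates: 247 DCM and 721 control subjects across 8 strata.
#'
#' @return data frame with columns `sex`, `age_band`, `group`, `n`,
#'   `grt_mean`, `grt_sd`, `grip_mean`, `grip_sd`.
#' @examples
#' p <- table1_params()
#' sum(p$n[p$group == "dcm"])      # 247
#' sum(p$n[p$group == "control"])  # 721
#' @export
table1_params <- function() {
  g <- strata()
  data.frame(
    sex = rep(g$sex, times = 2L),
    age_band = rep(g$age_band, times = 2L),
    group = rep(c("control", "dcm"), each = 8L),
    n = c(82, 62, 97, 34, 119, 132, 154, 41,
          62, 48, 43, 12, 22, 18, 27, 15),
    grt_mean = c(27.0, 23.5, 20.2, 20.1, 23.5, 20.7, 19.2, 17.8,
                 18.5, 13.9, 15.0, 11.4, 16.6, 12.5, 12.2, 9.5),
    grt_sd = c(5.6, 4.7, 5.2, 5.0, 4.8, 4.7, 4.8, 4.3,
               8.2, 6.0, 5.4, 4.7, 5.3, 4.8, 3.9, 3.8),
    grip_mean = c(42.6, 35.5, 30.1, 26.0, 25.6, 20.3, 17.6, 15.2,
                  23.3, 16.5, 16.5, 10.8, 14.5, 10.0, 8.5, 4.4),
    grip_sd = c(7.7, 7.8, 7.5, 5.7, 6.8, 4.6, 4.8, 3.8,
                12.1, 9.1, 8.0, 6.6, 7.4, 6.2, 4.9, 4.0),
    stringsAsFactors = FALSE
  )
}

#' The shipped screening-tool cutoffs
#'
#' The published per-stratum cutoffs of the diagnostic support tool: a GRT
#' repetition count and a grip strength in kg per sex/age stratum. A measured
#' per-side minimum at or below the cutoff is abnormal; the combined tool is
#' positive if either test is abnormal.
#'
#' @return data frame with columns `sex`, `age_band`, `grt_cutoff`,
#'   `grip_cutoff`.
#' @examples
#' table3_cutoffs()
#' @export
table3_cutoffs <- function() {
  g <- strata()
  data.frame(
    sex = g$sex,
    age_band = g$age_band,
    grt_cutoff = c(21, 17, 15, 11, 18, 17, 15, 12),
    grip_cutoff = c(32, 29, 21, 19, 20, 13, 15, 10),
    stringsAsFactors = FALSE
  )
}

#' Published single-test diagnostic performance
#'
#' Per-stratum AUC, Youden cutoff, sensitivity, specificity and likelihood
#' ratios for each test used alone, plus the pooled "total" sensitivity /
#' specificity / LR rows (`age_band == "total"`). `lr_pos` is `Inf` where the
#' published table prints a division-by-zero marker (specificity 1).
#'
#' The grip male 40-59 row is flagged `lr_consistent = FALSE`: its printed
#' sensitivity/specificity (0.68/0.85) do not reproduce its printed
#' likelihood ratios (11.57/0.20) and appear copied from the GRT table. The
#' pooled rows are also flagged: their LRs were evidently computed from
#' unrounded counts, so the rounded printed sensitivity/specificity do not
#' reproduce them to 2 decimals.
#'
#' @return data frame with columns `test` (`"grt"`/`"grip"`), `sex`,
#'   `age_band`, `auc`, `cutoff`, `sensitivity`, `specificity`, `lr_pos`,
#'   `lr_neg`, `lr_consistent`.
#' @export
table2_reported <- function() {
  g <- strata()
  grt <- data.frame(
    test = "grt", sex = c(g$sex, NA), age_band = c(g$age_band, "total"),
    auc = c(0.82, 0.91, 0.75, 0.90, 0.84, 0.91, 0.87, 0.92, NA),
    cutoff = c(21, 17, 15, 11, 18, 17, 15, 12, NA),
    sensitivity = c(0.68, 0.79, 0.58, 0.67, 0.73, 0.94, 0.78, 0.87, 0.73),
    specificity = c(0.85, 0.90, 0.85, 1.00, 0.89, 0.64, 0.75, 0.93, 0.83),
    lr_pos = c(4.53, 7.90, 3.87, Inf, 6.64, 2.61, 3.12, 12.43, 4.31),
    lr_neg = c(0.38, 0.23, 0.49, 0.33, 0.30, 0.09, 0.29, 0.14, 0.33),
    lr_consistent = c(rep(TRUE, 8L), FALSE),
    stringsAsFactors = FALSE
  )
  grip <- data.frame(
    test = "grip", sex = c(g$sex, NA), age_band = c(g$age_band, "total"),
    auc = c(0.92, 0.94, 0.89, 0.97, 0.87, 0.91, 0.91, 0.97, NA),
    cutoff = c(32, 29, 21, 19, 20, 13, 15, 10, NA),
    sensitivity = c(0.68, 0.96, 0.70, 0.83, 0.73, 0.78, 0.96, 0.93, 0.83),
    specificity = c(0.85, 0.81, 0.91, 0.94, 0.82, 0.96, 0.71, 0.90, 0.86),
    lr_pos = c(11.57, 5.05, 7.78, 13.83, 4.06, 19.50, 3.31, 9.30, 5.78),
    lr_neg = c(0.20, 0.05, 0.33, 0.18, 0.33, 0.23, 0.06, 0.08, 0.19),
    lr_consistent = c(FALSE, rep(TRUE, 7L), FALSE),
    stringsAsFactors = FALSE
  )
  rbind(grt, grip)
}

#' Published combined-tool diagnostic performance
#'
#' Per-stratum and pooled sensitivity, specificity and likelihood ratios of
#' the OR-combination screening rule.
#'
#' @return data frame with columns `sex`, `age_band` (including a `"total"`
#'   row), `sensitivity`, `specificity`, `lr_pos`, `lr_neg`.
#' @export
table4_reported <- function() {
  g <- strata()
  data.frame(
    sex = c(g$sex, NA), age_band = c(g$age_band, "total"),
    sensitivity = c(0.90, 0.96, 0.79, 0.92, 0.91, 0.94, 1.00, 0.93, 0.91),
    specificity = c(0.82, 0.74, 0.78, 0.94, 0.77, 0.70, 0.56, 0.83, 0.73),
    lr_pos = c(4.94, 3.71, 3.65, 15.58, 4.01, 3.20, 2.26, 5.47, 3.37),
    lr_neg = c(0.12, 0.06, 0.27, 0.09, 0.12, 0.08, 0.00, 0.08, 0.12),
    stringsAsFactors = FALSE
  )
}

#' Recruitment-flow count arithmetic
#'
#' Reconstructs the analyzable sample sizes from the published recruitment
#' flow: screened totals minus the exclusion counts for each group. The DCM
#' group excluded 100 subjects for clinical history (plus duplicates) and 14
#' for missing test data; the control group excluded 7 for cerebrovascular
#' history, 212 for possible myelopathy and 55 for missing grip data.
#'
#' @return list with components `dcm` and `control`, each a list of
#'   `screened`, `excluded` (named integer vector) and `analyzed`
#'   (screened minus all exclusions).
#' @examples
#' recruitment_counts()$control$analyzed  # 721
#' @export
recruitment_counts <- function() {
  dcm <- list(
    screened = 361L,
    excluded = c(clinical_history = 100L, missing_measurements = 14L)
  )
  ctrl <- list(
    screened = 995L,
    excluded = c(cerebrovascular_disease = 7L, possible_myelopathy = 212L,
                 missing_measurements = 55L)
  )
  dcm$analyzed <- dcm$screened - sum(dcm$excluded)
  ctrl$analyzed <- ctrl$screened - sum(ctrl$excluded)
  list(dcm = dcm, control = ctrl)
}
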