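# Cohort table I/O and validation.
#
# A cohort table has one row per subject with the raw bilateral measurements:
#   id, group (control/dcm), sex, age, grt_left, grt_right, grip_left, grip_right
# GRT values are counts of complete open-close hand cycles in 10 s; grip values
# are kg from an analog dynamometer with 0.5-kg resolution.

#' Canonical cohort columns
#'
#' @return character vector of the canonical column names, in canonical order.
#' @export
cohort_columns <- function() {
  c("id", "group", "sex", "age",
    "grt_left", "grt_right", "grip_left", "grip_right")
}

.measure_cols <- c("grt_left", "grt_right", "grip_left", "grip_right")

is_half_kg <- function(x) abs(x * 2 - round(x * 2)) < 1e-8
is_whole <- function(x) abs(x - round(x)) < 1e-8

#' Read and validate a cohort CSV
#'
#' Reads a UTF-8 comma-separated file with a header row, optionally renaming
#' columns through `schema`, and validates each row against the subject-record
#' invariants: group is control/dcm, age is an integer in \[40, 89\], GRT
#' counts are nonnegative integers, grip values are nonnegative multiples of
#' 0.5 kg. Rows with a missing measurement are rejected (dropped) and logged
#' with a reason, mirroring the exclusion of participants with missing test
#' data; invalid values are errors, not silent fixes, to protect against unit
#' mistakes.
#'
#' @param path path to a CSV file.
#' @param schema optional named character vector mapping canonical column
#'   names to the file's column names, e.g.
#'   `c(grt_left = "GRT_L", grip_left = "GripL")`. Unmapped canonical names
#'   must be present verbatim.
#' @param strict if `TRUE` (default) enforce the measurement invariants
#'   (nonnegative, integer GRT, 0.5-kg grip). `FALSE` accepts arbitrary
#'   numeric measurements, as produced by the raw (untruncated, unrounded)
#'   simulation mode.
#' @return data frame in canonical column order. Rejected rows (missing
#'   measurements) are attached as the `"rejected"` attribute, a data frame
#'   with the offending rows plus a `reason` column.
#' @seealso [write_cohort()], [validate_cohort()], [simulate_cohort()]
#' @export
read_cohort <- function(path, schema = NULL, strict = TRUE) {
  if (!file.exists(path)) config_error(sprintf("cohort file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (!is.null(schema)) {
    bad <- setdiff(names(schema), cohort_columns())
    if (length(bad)) {
      config_error(sprintf("schema maps unknown column(s): %s",
                           paste(bad, collapse = ", ")))
    }
    for (canon in names(schema)) {
      src <- schema[[canon]]
      if (!src %in% names(df)) {
        config_error(sprintf("schema column '%s' (for '%s') not in file",
                             src, canon))
      }
      names(df)[names(df) == src] <- canon
    }
  }
  missing_cols <- setdiff(cohort_columns(), names(df))
  if (length(missing_cols)) {
    config_error(sprintf("missing required column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  }
  validate_cohort(df[cohort_columns()], strict = strict)
}

#' Validate an in-memory cohort table
#'
#' @param df data frame with the canonical cohort columns.
#' @inheritParams read_cohort
#' @return the validated data frame (see [read_cohort()] for the `"rejected"`
#'   attribute).
#' @export
validate_cohort <- function(df, strict = TRUE) {
  missing_cols <- setdiff(cohort_columns(), names(df))
  if (length(missing_cols)) {
    config_error(sprintf("missing required column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  }
  df <- df[cohort_columns()]
  df$group <- tolower(as.character(df$group))
  if (!all(df$group %in% c("control", "dcm"))) {
    validation_error(sprintf(
      "group must be 'control' or 'dcm'; found: %s",
      paste(setdiff(unique(df$group), c("control", "dcm")), collapse = ", ")))
  }
  df$sex <- normalize_sex(df$sex)

  for (col in c("age", .measure_cols)) {
    if (!is.numeric(df[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))) & !is.na(df[[col]]))
      if (length(bad)) {
        validation_error(sprintf("non-numeric %s in row(s): %s", col,
                                 paste(bad, collapse = ", ")))
      }
      df[[col]] <- as.numeric(df[[col]])
    }
  }
  if (anyNA(df$age)) validation_error("missing age is not allowed")
  bad_age <- which(df$age < 40 | df$age > 89 | !is_whole(df$age))
  if (length(bad_age)) {
    validation_error(sprintf(
      "age outside [40, 89] (or non-integer) in row(s): %s",
      paste(bad_age, collapse = ", ")))
  }

  # Missing measurements reject the whole record (no imputation).
  miss <- !stats::complete.cases(df[.measure_cols])
  rejected <- df[miss, , drop = FALSE]
  if (nrow(rejected)) {
    rejected$reason <- apply(is.na(rejected[.measure_cols]), 1L, function(z) {
      sprintf("missing %s", paste(.measure_cols[z], collapse = ", "))
    })
    message(sprintf("rejected %d row(s) with missing measurements: %s",
                    nrow(rejected),
                    paste(rejected$id, collapse = ", ")))
    df <- df[!miss, , drop = FALSE]
  }

  if (strict) {
    for (col in .measure_cols) {
      bad <- which(df[[col]] < 0)
      if (length(bad)) {
        validation_error(sprintf("negative %s in row(s): %s", col,
                                 paste(bad, collapse = ", ")))
      }
    }
    for (col in c("grt_left", "grt_right")) {
      bad <- which(!is_whole(df[[col]]))
      if (length(bad)) {
        validation_error(sprintf(
          "%s must be an integer repetition count; row(s): %s", col,
          paste(bad, collapse = ", ")))
      }
    }
    for (col in c("grip_left", "grip_right")) {
      bad <- which(!is_half_kg(df[[col]]))
      if (length(bad)) {
        validation_error(sprintf(
          "%s must be a multiple of 0.5 kg (dynamometer resolution); row(s): %s",
          col, paste(bad, collapse = ", ")))
      }
    }
  }
  df$id <- as.character(df$id)
  rownames(df) <- NULL
  attr(df, "rejected") <- if (nrow(rejected)) rejected else NULL
  df
}

#' Write a cohort CSV in canonical form
#'
#' Columns are written in canonical order, UTF-8, comma-separated, with a
#' header row, so that `read_cohort(write_cohort(x, f))` round-trips the
#' validated rows exactly.
#'
#' @param df cohort data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(df, path) {
  utils::write.csv(df[cohort_columns()], path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Score subjects: per-side minimum and stratum assignment
#'
#' For both tests the subject's score is the lower of the left and right
#' measurements (the worse hand). Scores are attached to the subject's
#' sex/age stratum; the result is the unit of analysis for all downstream ROC
#' and classification work.
#'
#' @param df validated cohort data frame (see [read_cohort()]). A data frame
#'   that already carries `grt_min`/`grip_min`/`age_band` columns is returned
#'   as is.
#' @return data frame with columns `id`, `group`, `sex`, `age`, `age_band`,
#'   `grt_min`, `grip_min`.
#' @examples
#' coh <- simulate_cohort(seed = 1)
#' head(score_cohort(coh))
#' @export
score_cohort <- function(df) {
  if (all(c("grt_min", "grip_min", "age_band") %in% names(df))) {
    return(df)
  }
  st <- assign_stratum(df$sex, df$age)
  data.frame(
    id = as.character(df$id),
    group = df$group,
    sex = st$sex,
    age = df$age,
    age_band = st$age_band,
    grt_min = pmin(df$grt_left, df$grt_right),
    grip_min = pmin(df$grip_left, df$grip_right),
    stringsAsFactors = FALSE
  )
}
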