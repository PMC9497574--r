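#' @keywords internal
"_PACKAGE"

# Condition constructors: the CLI maps these classes to exit codes, and tests
# assert on them.
validation_error <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("dcm_validation_error", "error", "condition")))
}
config_error <- function(msg) {
  stop(errorCondition(msg, class = c("dcm_config_error", "error", "condition")))
}
insufficient_data_error <- function(msg) {
  stop(errorCondition(msg, class = c("dcm_insufficient_data", "error", "condition")))
}

#' Sex and age-band strata
#'
#' The screening tool stratifies by sex and decade-style age band. The four
#' bands are the closed integer intervals 40-59, 60-69, 70-79 and 80-89 years,
#' giving 8 strata in total (2 sexes x 4 bands). Ages outside 40-89 are not
#' supported by the tool.
#'
#' @return `age_bands()` returns the four band labels in ascending order;
#'   `strata()` returns a data frame of the 8 (sex, age_band) combinations,
#'   males first, each band ascending.
#' @examples
#' age_bands()
#' strata()
#' @export
age_bands <- function() c("40-59", "60-69", "70-79", "80-89")

#' @rdname age_bands
#' @export
strata <- function() {
  data.frame(
    sex = rep(c("male", "female"), each = 4L),
    age_band = rep(age_bands(), times = 2L),
    stringsAsFactors = FALSE
  )
}

.sexes <- c("male", "female")

normalize_sex <- function(sex) {
  s <- tolower(as.character(sex))
  s[s %in% c("m", "male")] <- "male"
  s[s %in% c("f", "female")] <- "female"
  bad <- !(s %in% .sexes)
  if (any(bad)) {
    validation_error(sprintf("unrecognized sex value(s): %s",
                             paste(unique(sex[bad]), collapse = ", ")))
  }
  s
}

#' Assign a subject to a sex/age stratum
#'
#' Bands are closed integer intervals: \[40,59\], \[60,69\], \[70,79\],
#' \[80,89\]. Every integer age in 40-89 maps to exactly one band; ages
#' outside that range raise a validation error (the tool's cutoffs are not
#' defined there).
#'
#' @param sex character vector, `"male"`/`"female"` (or `"M"`/`"F"`).
#' @param age integer vector of ages in years.
#' @return data frame with columns `sex` and `age_band`, one row per input.
#' @examples
#' assign_stratum("male", 59)    # upper edge of the first band
#' assign_stratum("female", 60)
#' @export
assign_stratum <- function(sex, age) {
  sex <- normalize_sex(sex)
  if (length(sex) != length(age)) {
    if (length(sex) == 1L) sex <- rep(sex, length(age))
    else if (length(age) == 1L) age <- rep(age, length(sex))
    else config_error("sex and age must have matching lengths")
  }
  if (!is.numeric(age) || anyNA(age) || any(age != floor(age))) {
    validation_error("age must be an integer number of years")
  }
  if (any(age < 40 | age > 89)) {
    validation_error(sprintf(
      "age outside the supported range [40, 89]: %s",
      paste(unique(age[age < 40 | age > 89]), collapse = ", ")))
  }
  band <- age_bands()[findInterval(age, c(40, 60, 70, 80))]
  data.frame(sex = sex, age_band = band, stringsAsFactors = FALSE)
}

stratum_label <- function(sex, age_band) paste(sex, age_band)
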