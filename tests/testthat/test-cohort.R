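test_that("stratum assignment uses closed integer bands and partitions 40-89", {
  expect_equal(assign_stratum("male", 59)$age_band, "40-59")
  expect_equal(assign_stratum("female", 60)$age_band, "60-69")
  expect_equal(assign_stratum("male", 89)$age_band, "80-89")

  ages <- 40:89
  bands <- assign_stratum(rep("female", length(ages)), ages)$age_band
  expect_true(all(bands %in% age_bands()))
  # exhaustive and disjoint: every age maps to exactly one band and the band
  # boundaries are where the label changes
  expect_equal(unname(table(bands)[age_bands()]), c(20L, 10L, 10L, 10L),
               ignore_attr = TRUE)

  expect_error(assign_stratum("male", 39), class = "dcm_validation_error")
  expect_error(assign_stratum("male", 90), class = "dcm_validation_error")
  expect_error(assign_stratum("dog", 50), class = "dcm_validation_error")
})

test_that("per-side minimum scoring is a min and is left/right symmetric", {
  r <- make_cohort_row("a", "dcm", "male", 55, 18, 22, 30.0, 28.5)
  sc <- score_cohort(r)
  expect_equal(sc$grt_min, 18)
  expect_equal(sc$grip_min, 28.5)

  set.seed(11)
  for (i in 1:25) {
    grt <- sample(0:30, 2)
    grip <- sample(seq(0, 50, by = 0.5), 2)
    a <- make_cohort_row("x", "control", "female", sample(40:89, 1),
                         grt[1], grt[2], grip[1], grip[2])
    b <- a
    b[c("grt_left", "grt_right")] <- a[c("grt_right", "grt_left")]
    b[c("grip_left", "grip_right")] <- a[c("grip_right", "grip_left")]
    expect_identical(score_cohort(a)[c("grt_min", "grip_min", "age_band")],
                     score_cohort(b)[c("grt_min", "grip_min", "age_band")])
  }
})

test_that("cohort CSV loading validates records and round-trips exactly", {
  coh <- toy_cohort()
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, f)
  got <- read_cohort(f)
  expect_equal(as.data.frame(got), coh, ignore_attr = TRUE)

  # round-trip is bit-identical on the file level too
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(got, f2)
  expect_identical(readLines(f), readLines(f2))

  # schema remapping of third-party column names
  renamed <- coh
  names(renamed)[names(renamed) == "grt_left"] <- "GRT_L"
  f3 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(renamed, f3, row.names = FALSE)
  got3 <- read_cohort(f3, schema = c(grt_left = "GRT_L"))
  expect_equal(as.data.frame(got3), coh, ignore_attr = TRUE)

  expect_error(read_cohort(f3), class = "dcm_config_error") # unmapped column
})

test_that("invalid measurements error; missing measurements reject the row", {
  coh <- toy_cohort()

  bad_grip <- coh
  bad_grip$grip_left[1] <- 17.3  # not a 0.5-kg multiple
  expect_error(validate_cohort(bad_grip), class = "dcm_validation_error")

  bad_grt <- coh
  bad_grt$grt_left[2] <- 14.5    # not an integer count
  expect_error(validate_cohort(bad_grt), class = "dcm_validation_error")

  neg <- coh
  neg$grip_right[1] <- -3
  expect_error(validate_cohort(neg), class = "dcm_validation_error")

  old <- coh
  old$age[1] <- 95
  expect_error(validate_cohort(old), class = "dcm_validation_error")

  # raw mode admits non-quantized and negative values
  expect_silent(validate_cohort(bad_grip, strict = FALSE))
  expect_silent(validate_cohort(neg, strict = FALSE))

  miss <- coh
  miss$grip_right[3] <- NA
  expect_message(got <- validate_cohort(miss), "rejected 1 row")
  expect_equal(nrow(got), 3L)
  rej <- attr(got, "rejected")
  expect_equal(rej$id, "d1")
  expect_match(rej$reason, "grip_right")
})
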