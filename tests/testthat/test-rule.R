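test_that("single-subject classification follows the <= orientation and OR rule", {
  # male 70-79 shipped cutoffs: GRT 15, grip 21
  v <- classify_subject("male", 72, 16, 14, 22.0, 20.5)
  expect_true(v$grt_abnormal)   # min 14 <= 15
  expect_true(v$grip_abnormal)  # min 20.5 <= 21
  expect_equal(v$class, "positive")

  # female 40-59 cutoffs: GRT 18, grip 20
  v <- classify_subject("female", 45, 25, 24, 26.0, 25.5)
  expect_false(v$grt_abnormal)
  expect_false(v$grip_abnormal)
  expect_equal(v$class, "negative")

  # exactly at both cutoffs is positive ("equal to or less than")
  v <- classify_subject("male", 65, 17, 17, 29.0, 29.0)
  expect_true(v$grt_abnormal && v$grip_abnormal)
  expect_equal(v$class, "positive")

  # one abnormal test suffices; strictly above both is negative
  v <- classify_subject("male", 65, 18, 18, 28.5, 30.0)
  expect_equal(v$class, "positive")  # grip min 28.5 <= 29
  v <- classify_subject("male", 65, 18, 18, 30.0, 31.0)
  expect_equal(v$class, "negative")

  expect_error(classify_subject("male", 92, 10, 10, 10, 10),
               class = "dcm_validation_error")
})

test_that("classification requires cutoffs for every stratum present", {
  coh <- toy_cohort()
  partial <- table3_cutoffs()[1, ]  # male 40-59 only; cohort is male 60-69
  expect_error(classify_cohort(partial, coh), class = "dcm_config_error")
})

test_that("confusion counts conserve subjects and pool by summation", {
  coh <- simulate_cohort(seed = 13)
  perf <- evaluate_performance(table3_cutoffs(), coh)
  sc <- score_cohort(coh)
  for (test in unique(perf$test)) {
    p <- perf[perf$test == test & perf$age_band != "total", ]
    expect_equal(p$tp + p$fp + p$fn + p$tn,
                 as.vector(table(stratum_label(sc$sex, sc$age_band))[
                   stratum_label(p$sex, p$age_band)]))
    tot <- perf[perf$test == test & perf$age_band == "total", ]
    expect_equal(tot$tp, sum(p$tp))
    expect_equal(tot$fp, sum(p$fp))
    expect_equal(tot$fn, sum(p$fn))
    expect_equal(tot$tn, sum(p$tn))
    expect_equal(tot$tp + tot$fp + tot$fn + tot$tn, nrow(sc))
  }
})

test_that("OR-rule monotonicity holds in every stratum and in the pooled total", {
  for (seed in c(2, 29)) {
    coh <- simulate_cohort(seed = seed)
    fit <- dcm_tool(coh)
    perf <- evaluate_performance(fit, coh)
    wide_sens <- reshape(perf[c("test", "sex", "age_band", "sensitivity")],
                         idvar = c("sex", "age_band"), timevar = "test",
                         direction = "wide")
    expect_true(all(wide_sens$sensitivity.combined >=
                      pmax(wide_sens$sensitivity.grt, wide_sens$sensitivity.grip)))
    wide_spec <- reshape(perf[c("test", "sex", "age_band", "specificity")],
                         idvar = c("sex", "age_band"), timevar = "test",
                         direction = "wide")
    expect_true(all(wide_spec$specificity.combined <=
                      pmin(wide_spec$specificity.grt, wide_spec$specificity.grip)))
  }
})

test_that("undefined metrics are flagged NA, not fabricated", {
  coh <- toy_cohort()
  controls_only <- coh[coh$group == "control", ]
  perf <- evaluate_performance(table3_cutoffs(), controls_only)
  expect_true(all(is.na(perf$sensitivity)))
  expect_false(anyNA(perf$specificity))

  expect_error(evaluate_performance(table3_cutoffs(), coh[0, ]),
               class = "dcm_insufficient_data")
})

test_that("specificity 1 yields the infinite LR+ sentinel in evaluation", {
  # controls all strictly above cutoffs, one case below: spec = 1
  coh <- rbind(
    make_cohort_row("c1", "control", "male", 62, 30, 30, 40.0, 40.0),
    make_cohort_row("c2", "control", "male", 63, 28, 29, 41.0, 42.0),
    make_cohort_row("d1", "dcm", "male", 65, 10, 10, 15.0, 15.0)
  )
  perf <- evaluate_performance(table3_cutoffs(), coh)
  comb <- perf[perf$test == "combined" & perf$age_band == "60-69", ]
  expect_equal(comb$specificity, 1)
  expect_identical(comb$lr_pos, Inf)
})
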