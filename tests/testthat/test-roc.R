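test_that("empirical AUC matches brute-force pair counting", {
  # 9 pairs, 8 concordant (case below control)
  expect_equal(empirical_auc(c(10, 15, 21), c(20, 22, 25))$auc, 8 / 9)
  expect_equal(oracle_auc(c(10, 15, 21), c(20, 22, 25)), 8 / 9)

  expect_equal(empirical_auc(c(1, 2, 3), c(1, 2, 3))$auc, 0.5)
  expect_equal(empirical_auc(1:5, 6:10)$auc, 1)
  expect_equal(empirical_auc(c(5), c(5))$auc, 0.5)

  set.seed(101)
  for (i in 1:50) {
    cases <- sample(0:20, sample(2:15, 1), replace = TRUE)
    controls <- sample(5:25, sample(2:15, 1), replace = TRUE)
    expect_equal(empirical_auc(cases, controls)$auc,
                 oracle_auc(cases, controls))
  }

  expect_error(empirical_auc(numeric(0), 1:3), class = "dcm_insufficient_data")
})

test_that("ROC curve is a monotone staircase from (0,0) to (1,1)", {
  r <- roc_curve(10, 20)
  expect_equal(r$fpr, c(0, 0, 1))
  expect_equal(r$tpr, c(0, 1, 1))

  set.seed(202)
  for (i in 1:25) {
    cases <- sample(0:15, sample(3:20, 1), replace = TRUE)
    controls <- sample(5:20, sample(3:20, 1), replace = TRUE)
    r <- roc_curve(cases, controls)
    expect_equal(r$fpr[1], 0)
    expect_equal(r$tpr[1], 0)
    expect_equal(r$fpr[length(r$fpr)], 1)
    expect_equal(r$tpr[length(r$tpr)], 1)
    expect_true(all(diff(r$fpr) >= 0))
    expect_true(all(diff(r$tpr) >= 0))
    # AUC duality: trapezoidal area equals Mann-Whitney pair counting
    expect_equal(r$auc, empirical_auc(cases, controls)$auc)
  }
})

test_that("Youden cutoff maximizes J with the screening tie rule", {
  yc <- youden_cutoff(c(10, 15, 19, 21), c(18, 20, 22, 25))
  # brute-force scan: J = 0.5 at thresholds 15, 19 and 21
  scan <- oracle_youden_scan(c(10, 15, 19, 21), c(18, 20, 22, 25))
  expect_equal(max(scan$j), 0.5)
  expect_equal(scan$threshold[scan$j == 0.5], c(15, 19, 21))
  # tie rule: highest sensitivity, then largest cutoff
  expect_equal(yc$cutoff, 21)
  expect_equal(yc$sensitivity, 1.0)
  expect_equal(yc$specificity, 0.5)
  expect_equal(yc$youden_j, 0.5)

  # the alternative rule prefers specificity, hence the smallest tied cutoff
  yc2 <- youden_cutoff(c(10, 15, 19, 21), c(18, 20, 22, 25),
                       tie_break = "specificity")
  expect_equal(yc2$cutoff, 15)
  expect_equal(yc2$specificity, 1.0)

  # complete separation: J = 1, largest case value chosen
  yc3 <- youden_cutoff(c(3, 7, 9), c(12, 15, 20))
  expect_equal(yc3$youden_j, 1)
  expect_equal(yc3$cutoff, 9)
})

test_that("Youden cutoff agrees with exhaustive maximization on random data", {
  set.seed(303)
  for (i in 1:200) {
    cases <- sample(0:25, sample(3:30, 1), replace = TRUE)
    controls <- sample(5:30, sample(3:30, 1), replace = TRUE)
    yc <- youden_cutoff(cases, controls)
    scan <- oracle_youden_scan(cases, controls)
    expect_equal(yc$youden_j, max(scan$j), tolerance = 1e-12)
    # identity J = sens + spec - 1 at the returned operating point
    expect_equal(yc$youden_j, yc$sensitivity + yc$specificity - 1)
    # returned cutoff is among the brute-force maximizers
    expect_true(yc$cutoff %in% scan$threshold[scan$j >= max(scan$j) - 1e-12])
  }
})

test_that("translation invariance: shifting values shifts only the cutoff", {
  set.seed(404)
  cases <- rnorm(40, 10, 3)
  controls <- rnorm(60, 16, 3)
  base <- youden_cutoff(cases, controls)
  shifted <- youden_cutoff(cases + 7.5, controls + 7.5)
  expect_equal(shifted$cutoff, base$cutoff + 7.5)
  expect_equal(shifted$youden_j, base$youden_j)
  expect_equal(shifted$sensitivity, base$sensitivity)
  expect_equal(shifted$specificity, base$specificity)
  expect_equal(empirical_auc(cases + 7.5, controls + 7.5)$auc,
               empirical_auc(cases, controls)$auc)
})

test_that("AUC agrees with pROC as an independent reference", {
  set.seed(505)
  for (i in 1:10) {
    cases <- round(rnorm(30, 12, 4))
    controls <- round(rnorm(45, 20, 5))
    ours <- empirical_auc(cases, controls)$auc
    ref <- suppressMessages(pROC::auc(
      response = c(rep(1, length(cases)), rep(0, length(controls))),
      predictor = c(cases, controls), direction = ">"))
    expect_equal(ours, as.numeric(ref))
  }
})

test_that("likelihood ratios follow the 2x2 definitions with the Inf sentinel", {
  lr <- likelihood_ratios(0.68, 0.85)
  expect_equal(lr$lr_pos, 0.68 / 0.15)
  expect_equal(lr$lr_neg, 0.32 / 0.85)
  expect_identical(likelihood_ratios(0.67, 1)$lr_pos, Inf)
  expect_equal(likelihood_ratios(1, 0.56)$lr_neg, 0)
})
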