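# Independent brute-force oracles, kept deliberately naive: O(n^2) pair
# counting for the AUC and an exhaustive scan over every observed value for
# the Youden maximizer.

oracle_auc <- function(cases, controls) {
  s <- 0
  for (x in cases) {
    s <- s + sum(x < controls) + 0.5 * sum(x == controls)
  }
  s / (length(cases) * length(controls))
}

# Exhaustive J over all observed thresholds under the "<= is abnormal" rule.
oracle_youden_scan <- function(cases, controls) {
  thr <- sort(unique(c(cases, controls)))
  sens <- vapply(thr, function(t) mean(cases <= t), numeric(1))
  spec <- vapply(thr, function(t) mean(controls > t), numeric(1))
  data.frame(threshold = thr, sens = sens, spec = spec, j = sens + spec - 1)
}

make_cohort_row <- function(id, group, sex, age, grt_l, grt_r, grip_l, grip_r) {
  data.frame(id = id, group = group, sex = sex, age = age,
             grt_left = grt_l, grt_right = grt_r,
             grip_left = grip_l, grip_right = grip_r,
             stringsAsFactors = FALSE)
}

# Tiny hand-constructed cohort: one stratum (male 60-69), 2 cases + 2 controls.
toy_cohort <- function() {
  rbind(
    make_cohort_row("c1", "control", "male", 62, 24, 25, 36.0, 35.5),
    make_cohort_row("c2", "control", "male", 68, 22, 21, 33.0, 34.5),
    make_cohort_row("d1", "dcm", "male", 65, 14, 15, 18.0, 17.5),
    make_cohort_row("d2", "dcm", "male", 61, 17, 18, 25.0, 26.5)
  )
}
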