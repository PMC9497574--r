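---
title: "Methods: stratified screening-tool construction for degenerative cervical myelopathy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stratified screening-tool construction for degenerative cervical myelopathy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcmscreen)
```

## The screening problem

Degenerative cervical myelopathy (DCM) — spinal cord dysfunction from
degenerative compression of the cervical spine — is frequently diagnosed
late because its early hand symptoms are subtle in primary care. Two quick
bedside measurements are sensitive to the two main early deficits: the
10-second grip and release test (GRT) counts complete open–close hand
cycles and captures loss of dexterity; maximal grip strength (kg) captures
weakness. Both are *negatively oriented*: lower is worse, and the subject's
score for each test is the per-side minimum — the worse of the left and
right hand.

`dcmscreen` implements the full construction of a stratified screening rule
from a labelled case–control cohort: per-stratum cutoff derivation, the
OR-combination of the two tests, and confusion-table performance
evaluation, plus a synthetic-cohort generator so the pipeline can be
exercised and tested without patient data.

## Statistical procedure

### Stratification

Test distributions shift strongly with sex and age, so all derivation and
evaluation is stratified into 8 cells: sex × closed integer age bands
[40, 59], [60, 69], [70, 79], [80, 89]. Age is taken as supplied (no date
arithmetic); ages outside 40–89 are rejected because the rule is undefined
there. The bands partition 40–89 exhaustively and disjointly, which the
test suite asserts over every age.

### ROC analysis and cutoff selection

Within a stratum, for one test with case scores $x_1,\dots,x_{n_1}$ (DCM)
and control scores $y_1,\dots,y_{n_0}$, candidate cutoffs are the distinct
observed values. Under the "abnormal if value $\le c$" orientation, the
operating point at $c$ is

$$\mathrm{sens}(c) = \tfrac{1}{n_1}\#\{x_i \le c\}, \qquad
  \mathrm{spec}(c) = \tfrac{1}{n_0}\#\{y_j > c\},$$

and the selected cutoff maximizes the Youden index
$J(c) = \mathrm{sens}(c) + \mathrm{spec}(c) - 1$, which weighs both error
rates equally and ignores prevalence. Discrimination is summarized by the
empirical AUC with the Mann–Whitney tie convention,
$\mathrm{AUC} = P(X < Y) + \frac12 P(X = Y)$, computed from the joint rank
statistic; it equals the trapezoidal area under the empirical ROC
staircase exactly, and the test suite asserts this duality on 1,000 random
instances.

Restricting candidates to observed values loses nothing here: with the
$\le$ orientation every half-open interval between consecutive observed
values induces the same classification as its lower endpoint, and
measurement values (integer counts, 0.5-kg multiples) are the only cutoffs
a clinician can apply.

**Tie-breaking.** $J$ is often maximized at several cutoffs, especially in
small strata. The package's default rule prefers the higher sensitivity and
then the larger cutoff — a screening tool exists to avoid missing cases, so
among equally informative cutoffs the more sensitive one is the right
default. The alternative (`tie_break = "specificity"`) prefers the higher
specificity and the smaller cutoff. The choice is surfaced in both
`youden_cutoff()` and `dcm_tool()` because it genuinely changes the derived
table on tied data.

### Combination and evaluation

The two derived cutoffs are combined with the parallel (OR) rule: the tool
is positive if either test is abnormal. Set-theoretically the positive
region of the OR rule contains each single-test positive region, so
combined sensitivity is at least each single-test sensitivity and combined
specificity at most each single-test specificity; the suite asserts this
count inequality on every evaluated cohort.

Performance is reported per stratum as a confusion table (DCM is the
condition-positive class) with sensitivity, specificity,
$LR^+ = \mathrm{sens}/(1-\mathrm{spec})$ and
$LR^- = (1-\mathrm{sens})/\mathrm{spec}$. Pooled "total" rows are computed
from the **summed counts**, not by averaging stratum metrics — the only
interpretation consistent with a single overall 2×2 table. At
specificity 1, $LR^+$ is undefined and carried as `Inf` (printed `"inf"`);
metrics with a zero denominator (e.g. sensitivity in a stratum without
cases) are flagged `NA` rather than dropped. Evaluation is resubstitution
(derive and evaluate on the same cohort) by default, matching how such
pilot screening tables are built; `evaluate_performance()` accepts any
external cutoff table — in particular the shipped `table3_cutoffs()` — so a
derived tool can be applied to new cohorts, which is its intended clinical
use.

### Group comparison

`summarize_cohort()` reports per-stratum $n$, mean and sample SD ($n-1$
denominator) per group and a two-sided Wilcoxon rank-sum p-value. The
p-value uses full enumeration of rank assignments when both groups have
$\le 10$ observations (exact even with ties, via mid-ranks) and otherwise
the normal approximation with tie-corrected variance and continuity
correction — appropriate because integer GRT scores are heavily tied. The
0.05 threshold is annotation only; no logic branches on it. All values
identical across both groups returns $p = 1$ by convention.

## The synthetic-cohort generator

No subject-level data are deposited for this design, so
`simulate_cohort()` generates cohorts with the published stratum structure:
for each of the 16 (stratum × group) cells it draws $n$ latent (GRT, grip)
pairs from a bivariate normal with the published marginal means and SDs —
721 controls and 247 cases in total under the defaults of
`table1_params()`, which **are** the study conditions and are not adjusted.

Choices made where the published description is silent:

* **Correlation `rho`.** The within-subject correlation between the two
  tests is not reported, yet combined-rule performance depends on it (at
  `rho = 1` the OR rule adds nothing; at `rho = 0` it adds most). It is a
  first-class parameter with default 0.5 — moderate concordance between
  dexterity and strength impairment, the middle of the plausible range for
  two tests of partially overlapping mechanisms.
* **Truncation by resampling.** In `realistic` mode, pairs with a negative
  component are redrawn rather than clamped: clamping would put a point
  mass at zero and distort the ROC tie structure. For strata with
  non-negligible normal mass below zero (female 80–89 cases have grip
  4.4 ± 4.0 kg, about 14% mass below zero) the realized mean therefore
  exceeds the nominal mean — documented, and asserted in the tests.
* **Instrument rounding.** `realistic` mode rounds GRT to integers and grip
  to 0.5 kg, reproducing the tie-heavy discrete data real cohorts show;
  `raw` mode skips truncation and rounding entirely and is used for
  distribution-level checks (moment recovery, the binormal AUC limit
  $\Phi(|\mu_0-\mu_1|/\sqrt{\sigma_0^2+\sigma_1^2})$).
* **Laterality.** Left and right are emitted equal to the drawn value. Only
  per-side minima are reported in the published tables, so any laterality
  model would be invented structure; the minimum-taking code path is still
  exercised.
* **Seeds.** A master seed derives one deterministic substream per
  parameter row, so a fixed request is bit-reproducible. Ages are drawn
  uniformly over the band's integer years.

What the generator does **not** emulate: comorbidity-driven grip loss,
disease progression, within-stratum age trends, non-normal tails, or any
real left/right asymmetry. Tests passing on synthetic cohorts therefore
validate the *pipeline arithmetic* under the published distributional
summary, not the clinical performance of the tool on real patients.

## Numerical and interface choices

* Validation is strict by default: grip values must be 0.5-kg multiples and
  GRT values integers, and violations are errors rather than silent
  rounding (a cheap guard against lb/kg unit mistakes). Rows missing a
  measurement are rejected wholesale and logged — no imputation, mirroring
  the exclusion of subjects with missing test data. `strict = FALSE`
  relaxes the quantization/nonnegativity invariants so `raw`-mode output
  can round-trip through CSV.
* Reports round half-up to 2 decimals (1 decimal for means) for direct
  visual comparison with published tables; all stored values keep full
  precision.
* Proportion ties in the Youden scan are compared with a $10^{-12}$
  absolute tolerance to make tie-breaking robust to floating-point noise in
  $J$.

### Known inconsistencies in the published reference values

The shipped reference tables (`table2_reported()`, `table4_reported()`)
carry two anomalies flagged with `lr_consistent = FALSE`: the grip male
40–59 row prints sensitivity/specificity 0.68/0.85 next to likelihood
ratios 11.57/0.20, which are mutually inconsistent (0.68/0.15 = 4.53) and
appear copied from the GRT table; and the pooled "total" rows print LRs
computed from unrounded counts, so they cannot be reproduced from the
rounded printed proportions. The package's LR arithmetic is verified
against the 15 internally consistent stratum rows. Likewise, only the
pooled-count "total" computation is implemented; an alternative overall
figure set whose derivation is not given is not targeted.

## Problem sizes used by the tests

The suite's randomized property checks use 1,000 instances of up to 30
values each for the Youden/AUC oracles; moment- and AUC-recovery checks use
$10^5$–$2\times10^5$ draws per group, at which the Monte-Carlo standard
error of the AUC is about $10^{-3}$ and 2-decimal agreement with the
binormal closed form is expected. The whole suite runs in well under a
minute on one CPU.

## Limitations

* Resubstitution metrics are optimistic; the package derives and evaluates
  on the same cohort by design (mirroring the pilot construction), and no
  cross-validation is provided.
* No confidence intervals for AUC or the performance metrics are computed.
* The generator's binormal assumption is a summary-level emulation; heavy
  tails, floor effects in severely affected strata, and real laterality are
  not modeled.
* The 80–89 strata have small case counts, so derived cutoffs there are
  unstable across simulated cohorts — visible when comparing `dcm_tool()`
  fits across seeds.
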