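---
title: "Methods: PE triage rules, accuracy evaluation and the synthetic AECOPD cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PE triage rules, accuracy evaluation and the synthetic AECOPD cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petriage)
```

## The problem

Ruling out acute pulmonary embolism without imaging rests on combining a
clinical pretest probability (C-PTP) with a D-dimer threshold. Five
strategies dominate practice — the Standard rule, the age-adjusted D-dimer
rule, YEARS, PERC and the graduated-D-dimer (PEGeD) strategy — and they
disagree most in exactly the populations where the decision matters, such
as patients hospitalized for an acute exacerbation of COPD (AECOPD):
chronically tachycardic, hypoxemic, often immobilized, usually over 50 and
with elevated baseline D-dimer. `petriage` implements the five rules as
pure decision functions and the apparatus for comparing them against a
confirmed-PE reference standard.

## Rule engines

Every engine is a total, deterministic function of the patient record and
a `triage_config()`; the reference-standard label is never an input. Three
conventions are applied uniformly and deserve explicit statement:

* **Strict thresholds.** Every D-dimer comparison is "less than": a value
  exactly at a cutoff goes to imaging. Likewise PERC's limits are strict
  (age < 50, SaO2 > 94 %, pulse < 100), and the tachycardia item of the
  Wells score fires at heart rate > 100. Ties therefore always resolve
  toward imaging, the conservative direction.
* **Age boundary.** "Older than 50" means the age-adjusted cutoff
  (10 ng/ml × age) applies from age 51 up; at age 50 and below the
  standard 500 ng/ml cutoff applies.
* **One shared C-PTP.** A single Wells score and classification scheme
  feeds every engine in a run, mirroring study designs in which a stored
  Wells score is reassessed under several rules.

Two genuinely open points are resolved as configuration with defaults:

* The age-adjusted rule's defining description attaches the low/moderate
  C-PTP requirement explicitly only to the under-50 branch. We apply it to
  both branches (consistent with the rule's source trial);
  `age_adjusted_requires_cptp_over_50 = FALSE` lifts it.
* PERC's leg-swelling criterion is a distinct clinical finding from the
  Wells "DVT signs" item. The record carries both booleans;
  `perc_leg_swelling_from_dvt_signs = TRUE` derives one from the other for
  data sources that only recorded DVT signs.

### Wells score and C-PTP

The Wells instrument is the canonical seven-item weighting (3, 3, 1.5,
1.5, 1.5, 1, 1 for DVT signs, PE most likely, tachycardia,
immobilization-or-surgery, prior VTE, hemoptysis, cancer), configurable via
`wells_weights()`. Three-level cut-points vary between hospitals; the
default scheme (`"peged-trial"`) is the one under which the graduated
strategy was defined — low ≤ 4.0, moderate 4.5–6.0, high ≥ 6.5 on the
half-point lattice — with the traditional scheme (low < 2, moderate 2–6,
high > 6) as a named preset, since which scheme a retrospective cohort used
is often undocumented. The scheme in force is named in every report
header. The two-level split is the canonical dichotomized Wells:
`pe_likely` iff score > 4.0, strict. Scores live on a half-point lattice,
so category boundaries need no floating-point tolerance.

## Accuracy evaluation

`imaging_required` is the positive prediction; a false negative is a
missed diagnosis. From the 2×2 table the panel is sensitivity,
specificity, PPV, NPV, PLR = sens/(1−spec), NLR = (1−sens)/spec, Youden
index = sens+spec−1 and diagnostic accuracy = (TP+TN)/N.

Two reporting conventions are provided. The default `"paper"` convention
reproduces how such panels are printed in the clinical literature:
percentages rounded half-up (away from zero) to one decimal, and the
ratio metrics computed from sensitivity and specificity *first rounded to
three-decimal proportions*, then themselves rounded to three decimals.
This pre-rounding matters: it is the only route that reproduces published
panels digit-for-digit, and `round_half_up()` exists because R's
`round()` rounds half to even. The `"exact"` convention performs no
rounding and satisfies the Bayes identity
ppv/(1−ppv) = PLR × prev/(1−prev) to floating precision; it is the right
choice for new analyses.

Undefined metrics (zero or unobservable denominators) are carried as `NA`
and rendered "N/A", never thrown. This matters for designs where one rule
defined the imaging set of the cohort: that rule's FN/TN cells are
unobservable, its sensitivity/specificity meaningless, yet its PPV and
imaging burden remain well defined. The packaged reference counts encode
exactly this situation for the Standard rule. One transcription quirk is
handled transparently: the published age-adjusted PLR reads 3.034, while
0.786/0.259 = 3.0347 rounds to 3.035 under either convention (the printed
figure appears truncated). `reproduce_reference_tables()` reports 3.035
and its `diff` table flags the one-digit mismatch rather than adding a
truncation mode.

Group comparisons (`compare_groups()`) follow the conventions of cohort
characteristic tables: two-sample t-tests for continuous variables (Welch
by default; `var_equal = TRUE` for the pooled test) and Pearson chi-square
without continuity correction for rates — the no-correction choice is what
reproduces published p-values such as 0.021 for a 275/948 vs 78/210 split.
`ttest_from_summary()` covers published tables that report only
mean ± SD. No multiplicity adjustment is applied, matching the reporting
practice the package reproduces.

## The synthetic cohort

`generate_cohort()` emulates the *marginal* structure of an AECOPD cohort
of 1158 patients with 210 confirmed PE: per-group D-dimer moments
(1191 ± 676 vs 3118 ± 1635 ng/ml), the per-group prevalence of every
boolean item, tachycardia and desaturation fractions, and the small
under-50 age fraction (2.7 % / 2.4 %). Design choices:

* **Exact prevalence allocation.** `round(n × prevalence)` positives are
  allocated and permuted, not drawn binomially, so the 948/210 split is
  reproducible.
* **Log-normal D-dimer**, moment-matched per group
  (σ² = log(1+(s/m)²), μ = log m − σ²/2): positive support and right skew
  typical of D-dimer, with only mean ± SD available as targets.
* **Mixture ages.** A normal with the target mean/SD truncated to
  [18, 100] would put far more than 2.7 % of mass below 50; ages are drawn
  as a two-component mixture (uniform on [18, 50) with the target under-50
  probability, truncated normal on [50, 100] otherwise), prioritising the
  under-50 fraction — which gates both PERC and the age-adjusted cutoff —
  over the exact age mean.
* **Dependence structure.** Only marginals are published, so booleans are
  independent within group, with two deliberate exceptions: unilateral leg
  swelling is coupled to DVT signs (P = 0.60 given signs, 0.05 otherwise),
  and "PE most likely" is generated from a logistic link on the record's
  other Wells items whose intercept is solved per group (by `uniroot`
  against the realised records) to hit the target group fractions
  (58.5 % / 84.3 %). The Wells score itself is always *computed* from
  generated items, never sampled, so records are internally consistent —
  the price is that the synthetic Wells mean need not match any published
  cohort mean, and `validate_marginals()` treats it as advisory.
* **Heart rate and SaO2** are drawn as continuous values consistent with
  the configured exceedance fractions (HR > 100, SaO2 ≤ 94); their shapes
  within each side of the threshold are uncalibrated modelling choices, as
  only the exceedance fractions enter any rule.

`validate_marginals()` checks each targeted marginal per group: exact
central binomial bounds for every proportion, a z-interval (using the
target SD) for the D-dimer mean, and an exact chi-square interval on the
*log-scale* variance for the D-dimer spread — under the moment-matched
log-normal generator this check is exactly calibrated, whereas a
normal-theory interval on the raw-scale SD would be anti-conservative
given log-normal kurtosis. Each check runs at a configurable two-sided
level (`alpha`, default 0.001); with roughly 30 checks per cohort, an
occasional boundary exceedance on some seed is the expected behaviour of a
correctly calibrated generator, not a defect.

### What passing tests do and do not show

Because the joint distribution of a real cohort (D-dimer × Wells
correlation above all) is not modelled, synthetic cohorts reproduce
marginal structure and the *qualitative* ordering of strategies — PERC
specificity collapses below 10 %, the graduated strategy images fewer
patients than the Standard rule on every seed — but not any published
cohort's exact 2×2 counts. Quantitative reproduction of the reference
accuracy panel therefore runs through the packaged printed counts, which
is an exact, deterministic computation; no attempt is made to calibrate
the simulation to it, as that would require dependence assumptions the
published marginals cannot support.

## Problem sizes and numerical checks in the test suite

The suite exercises the engines against independently coded brute-force
clause re-statements on an exhaustive grid of all 2¹⁰ boolean combinations
× 5 ages × 8 D-dimer values × 3 heart rates × 3 SaO2 values (368 640
records, straddling every threshold), verifies the rule-out set nestings
(Standard ⊆ PEGeD, Standard ⊆ Age-adjusted) and D-dimer monotonicity on
10 000 random records, and runs the generator's parameter-recovery check
at n = 1158 over 20 seeds. These sizes make the grid exhaustive at every
decision boundary while keeping the default run fast.

## Limitations

* Verdicts are binary; no probabilistic PE risk, confidence intervals or
  ROC analysis (decisions are not scores).
* The record model carries the reference standard as a single boolean;
  imaging adjudication, echocardiographic pathways for unstable patients
  and chronic-PE screening are out of scope.
* D-dimer units are fixed at ng/ml (FEU/DDU assay conventions are not
  auto-detected; a read-time flag converts µg/ml inputs).
* The Geneva C-PTP instrument is not implemented; all C-PTP derives from
  the Wells score.
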