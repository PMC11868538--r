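---
title: "Methods: biological PET staging and plasma p217+tau discrimination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: biological PET staging and plasma p217+tau discrimination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptaustage)
```

## The problem

PET imaging can stage Alzheimer's disease biologically — amyloid first, then
tau spreading from the mesial temporal lobe into neocortex — but it is costly
and scarce. Plasma phospho-tau assays (here p217+tau, in fg/ml) are cheap and
scalable. The question this package addresses is how much of the PET staging
signal a single plasma measurement carries: at the group level (can it screen
a trial cohort for a given stage?) and at the individual level (given one
concentration, what stage is this person most likely in?).

## The staging rule engine

A participant's stage is a deterministic function of four PET quantities:
amyloid burden on the Centiloid scale and tau SUVR in three composite
regions — mesial temporal (Me), temporo-parietal (Te) and rest of neocortex
(R). With the default `staging_thresholds()` (Centiloid 25; Me 1.18, Te 1.24,
R 1.08 SUVR; high-tau Te 2.68 SUVR):

| Stage | Centiloid | Me | Te | R |
|---|---|---|---|---|
| A-T- | < 25 | < 1.18 | < 1.24 | < 1.08 |
| Initial | >= 25 | < 1.18 | < 1.24 | < 1.08 |
| Early | >= 25 | >= 1.18 | < 1.24 | < 1.08 |
| Intermediate | >= 25 | any | [1.24, 2.68) | any |
| Advanced | >= 25 | any | >= 2.68 | any |

Amyloid-negative scans with any tau-positive region are labelled
`EXCLUDED_A_NEG_T_POS` and removed from every downstream analysis (the
discordant amyloid-negative/tau-positive profile, often attributed to primary
age-related tauopathy, sits outside the staging scheme). The tau positivity
thresholds correspond to the 95th percentile of amyloid-negative cognitively
unimpaired participants and the high-tau threshold to the top quartile of Te
SUVR in amyloid-positive cognitively impaired participants;
`derive_percentile_threshold()` reproduces both derivations from a reference
subcohort.

Three choices the rule table leaves open are fixed as follows:

- **Boundary inclusivity.** Positivity comparisons are inclusive
  (value >= threshold is positive), the moderate Te band is `[1.24, 2.68)`
  and Advanced is `Te >= 2.68`. This makes the seven labels a partition with
  deterministic behaviour at exact threshold values.
- **Undefined profiles.** An amyloid-positive participant with Te below
  positivity but R positive matches no row; such records are labelled
  `UNSTAGED`, counted, and excluded rather than silently coerced into a
  stage.
- **Quantile convention.** Threshold derivation uses linear interpolation at
  `h = (n - 1) p / 100 + 1` on the sorted sample (type 7), the convention is
  configurable via the `type` argument.

## The synthetic cohort

The original cohort is not publicly deposited, so the package generates
cohorts with the published per-stage structure (`default_table2_spec()`):
five strata of sizes 192/80/31/128/44, each with its printed p217+tau median
and IQR, Centiloid and Me/Te SUVR medians and IQRs, age mean and SD, and
percentages of female sex, APOE e4 carriership and cognitive impairment.

Distribution families are not published, only summaries; the generator's
choices are:

- **p217+tau, Me, Te: log-normal**, fitted by `fit_lognormal_from_quartiles()`
  (`mu = ln median`, `sigma = (ln Q3 - ln Q1) / (2 z_0.75)`). This matches
  the median-and-IQR reporting style for skewed, strictly positive markers
  and keeps a closed-form AUC oracle available (for two log-normal classes
  the population AUC is `pnorm((mu2 - mu1) / sqrt(s1^2 + s2^2))`). A
  two-parameter log-normal reproduces the median and the quartile *ratio*
  exactly but symmetrises the quartiles geometrically; the printed p217
  quartiles are log-asymmetric by 1.6-3.4%, so individual quartiles are
  matched to that accuracy, not better. Tests assert median and
  quartile-ratio recovery for every stratum and full quartile recovery for
  the log-symmetric A-T- stratum.
- **Centiloid: normal** (it can be negative), with SD = IQR/1.349, truncated
  to the stage's Centiloid range.
- **Me/Te: truncated** to the stage's SUVR ranges by inverse-CDF sampling, so
  every generated record re-classifies to its stratum by construction (the
  restaging round-trip is tested at 100%).
- **R region: normal(1.0, 0.1)** truncated to the stage constraint. The
  published table has no R summary; this is a free parameter of the
  generator, chosen as a plausible sub-positivity distribution (the
  positivity threshold 1.08 sits at the 79th percentile of the untruncated
  distribution).
- **Covariates**: age normal; sex, APOE e4 and cognitive impairment are
  independent Bernoulli draws at the printed stage percentages. The MCI vs
  dementia split within the impaired is not published per stage; the
  study-wide 144:83 ratio is applied uniformly.
- Concentrations below the assay's lower limit of quantification (37 fg/ml)
  are generated and retained, as the study retained them.

Each stratum runs on its own RNG substream derived from the seed, so cohorts
are reproducible byte-for-byte and resizing one stratum does not perturb the
others.

**What the generator does not emulate.** Within a stage, p217+tau and the
PET values are conditionally independent; real data correlate them (a
participant near the top of the Advanced tau range tends to have higher
p217+tau). Group-level quantities driven by between-stage separation — the
headline AUCs, prevalences, fold changes — are therefore emulated well, while
quantities sensitive to within-stage tails are flattened. Passing tests on
synthetic cohorts show the pipeline computes the right quantities and that
between-stage structure of the published size reproduces the published
discrimination; they do not certify performance on any real cohort.

## Group-level discrimination

`empirical_roc()` fixes the orientation (higher marker = positive class;
test-positive means value >= cutoff) and takes the distinct observed values
plus +Inf as candidate cutoffs, so every reported threshold is an observable
concentration. The AUC is the Mann-Whitney statistic with ties counted 1/2,
identical to the trapezoidal area under the empirical curve.

Operating points:

- `youden_threshold()` maximises J = sens + spec - 1, breaking ties toward
  the lowest cutoff (maximal sensitivity).
- `threshold_at_target()` returns the highest cutoff meeting a sensitivity
  target or the lowest meeting a specificity target, maximising the
  complementary metric subject to the constraint.
- `bootstrap_metrics()` attaches 95% percentile intervals from a
  class-stratified bootstrap, B = 2000 by default (the study does not state
  its scheme; stratification preserves the two class sizes and percentile
  intervals match the bracketed style of the reported values). Replicates
  with an undefined PPV or NPV (empty predicted class) are dropped from that
  metric's percentiles and counted, rather than imputed.
- PPV and NPV are computed at the sample prevalence, unadjusted.

`delong_compare_paired()` implements the structural-components estimator of
var(AUC_a - AUC_b) for two markers on the same subjects; the variance is
checked against a jackknife in the tests, and self-comparison returns p = 1
exactly. Families of DeLong tests are Holm-adjusted by default (the study
reports correction for multiple comparisons without naming a method;
Bonferroni is available).

`two_threshold_zoning()` triages records into Low / Indeterminate / High
zones from a high-sensitivity and a high-specificity cutoff and scores only
the determinate zones. `two_step_youden()` chains two Youden screens: the
step-2 ROC is computed only among records at or above the step-1 cutoff,
mirroring plasma pre-screening before confirmatory tau PET.

`fit_risk_model()` is the covariate benchmark: an IRLS logistic fit
(deviance tolerance 1e-8, at most 100 iterations) whose linear predictor is
the ROC score for the base (age, sex, APOE e4) and full (plus p217+tau)
models. Complete separation — which can terminate IRLS "converged" with a
near-zero deviance — is detected and raised rather than returned.

## Individual-level staging

Because the Initial and Early stages do not separate on p217+tau, all
probability analyses first consolidate them (`merge_initial_early()`),
leaving four categories. Two estimators are compared:

1. **One-vs-rest logistic curves** (`fit_stage_curves()`): one binary fit of
   stage membership on concentration per category, restricted to records at
   or below 500 fg/ml — above that the data are too sparse to constrain a
   slope (the study restricted its regressions identically). The four curves
   are separate one-vs-rest fits, so they need not sum to 1 and are not
   normalised; normalisation would not change which stage is most likely.
2. **Sliding-window bands** (`sliding_window_probabilities()`): sequential
   non-overlapping 80 fg/ml bands starting at 0, each estimating stage
   probabilities as within-band fractions centred at the band midpoint.
   80 fg/ml balances smoothing against noise; bands with fewer than 5
   records are omitted and counted. A `stride` argument below the band
   width gives overlapping windows for sensitivity analysis.

`crossover_points()` scans `[0, 500]` at 0.5 fg/ml, finds where the argmax
stage changes and refines each boundary by bisection to 0.01 fg/ml.
`concordance()` summarises the mean absolute difference between the two
estimators at the band centres.

**Known limitation.** On synthetic cohorts the first two crossovers
(A-T- to Initial/Early to Intermediate) are stable, but the
Intermediate-to-Advanced crossing typically falls at or beyond the upper end
of the 500 fg/ml window rather than near the middle of the range: under
conditional independence the Advanced one-vs-rest curve rises less steeply
than in real data, where within-stage correlation concentrates Advanced
records at high concentrations. The property asserted on synthetic cohorts
is therefore the monotone traversal of the stage order with increasing
boundaries, not the in-window position of the final crossing.

## Between-stage statistics

`describe_by_stage()` reproduces the summary-table layout (median/IQR for
skewed variables, mean/SD for age, percentages for categorical variables).
`kruskal_dunn()` runs the tie-corrected Kruskal-Wallis test followed by
Dunn's pairwise z tests with tie-adjusted pooled rank variance and Holm
adjustment, attaching Cohen's d (pooled n-1 SD) and the median fold change
per pair. Categorical comparisons use the Pearson chi-square without
continuity correction. The nonparametric branch is the one implemented;
ANOVA/Tukey for normally distributed demographics is out of scope here.

## Problem sizes and determinism

The test suite and the acceptance script run at the study's own scale:
cohorts of n = 475 with the published stratum sizes, averaged over 100 seeds
for stochastic quantities; calibration checks (quantile recovery, binormal
AUC oracle, logistic parameter recovery) use inflated samples of 10^4 to
10^5. Every stochastic routine takes an explicit seed, restores the caller's
RNG state, and reproduces its output exactly under the same seed; pipeline
reports serialise byte-identically on re-run.
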