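---
title: "Methods: accelerometer reduction, questionnaire scoring, and the agreement battery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actipaq)
```

`actipaq` implements, as one tested pipeline, the computation behind a
criterion-validity study of physical-activity self-reports in adolescent
boys: reduction of epoch-level accelerometer counts to intensity-classified,
wear-adjusted daily minutes; scoring of three questionnaires; and the
agreement battery comparing them. This vignette is the package's account of
the science: the models and rules, the parameters that matter, what the
synthetic generator does and does not emulate, and the choices made where
the procedure was genuinely open.

## 1. Accelerometer reduction

The device records activity counts in 15-s epochs. Because the intensity
cut-points are stated in counts per minute (cpm), epochs are first
reintegrated to 60 s by summation (`reintegrate_epochs`); classification at
15 s with thresholds rescaled by `epoch_length/60` is available through
`reduction_config(target_epoch = 15)` for sensitivity analyses. A trailing
partial block is dropped with a warning rather than extrapolated.

**Non-wear.** A maximal run of zero-count minutes lasting at least
`nonwear_zero_run = 20` min is non-wear and is excluded from all summaries.
The scan is strict — a single non-zero epoch breaks a run — because the
source procedure states no spike tolerance; the threshold is a config
parameter for users who need a different rule. Runs are detected on the
whole series, so an episode crossing midnight is excluded from both days it
touches. Gaps in the timestamp grid (possible only through the file reader;
the in-memory constructor enforces a regular grid) are zero-filled and
therefore behave as non-wear, with a warning.

**Classification.** Wear minutes are classified sedentary < 100 cpm ≤
light < 2000 cpm ≤ moderate < 4000 cpm ≤ vigorous. The source rules write
"< 100" and "> 100" (etc.), leaving the boundary values unassigned; we
assign boundaries to the upper class (lower-inclusive upper intervals),
which is the common cut-point convention and guarantees the conservation
invariant: per day, sedentary + light + moderate + vigorous minutes equal
wear minutes exactly.

**Validity and adjustment.** A day is valid at `min_wear_per_day = 480` min
(8 h) of wear; a subject is included at `min_valid_days = 3` valid days.
Averages use valid days only. To remove wear-time confounding, class
minutes are converted to adjusted minutes,

$$\text{adjusted} = \frac{\text{raw min/day}}{\text{subject mean wear}}
  \times \text{cohort mean wear},$$

so the adjustment is invariant to proportionally scaling a subject's wear.
The cohort mean wear is computed once over included subjects, and is also
an explicit parameter (`reduce_cohort(cohort_mean_wear = )`) so a
reproduction can pin the reference cohort's 769.3 min/day. MVPA is
moderate + vigorous. Steps are averaged over valid days but *not*
wear-adjusted — the source describes adjusting "time in activity
categories" only. Calendar days (00:00–24:00, device-local time) define the
day; thin first/last days are handled by the validity filter rather than
excluded outright, since the source does not say it dropped them.

## 2. Questionnaire scoring

**IPAQ-SF.** Each activity category (vigorous, moderate, walking) is
reported as days/week and min/day; the score is `days × minutes ÷ 7`
min/day, and sitting passes through as sedentary min/day (weekday sitting,
unweighted — no weighting rule is given). The official data-processing
protocol's cleaning rules are implemented but independently switchable
(`ipaq_rules`): reports under 10 min/day are recoded to zero, and
per-category time is truncated at 180 min/day. They default to on; which of
them the source study applied is not stated, which is one reason
reproduction tolerances on IPAQ quantities are generous. Missing components
propagate to a missing category score — never zero-filled — and deletion
happens downstream (pairwise for correlations, listwise for regression),
matching the varying per-cell sample sizes such studies report.

**TPAQ.** Five derived items: Q1 = weekly school-commute walking/cycling
minutes (days × one-way minutes, to-school plus homeward), Q2 = weekly
sports-club minutes, Q3 = days (0–7) with ≥ 30 min of at-least-moderate
activity, Q4 = indicator of ≥ 30 min on ≥ 5 days, Q5 = screen time coded
1–5. When the yes/no behind Q4 is missing it falls back to `Q3 >= 5`,
matching the item's wording. The MVPA index evaluates the fixed calibrated
coefficients

$$L = -2.25476 + 0.00018\,Q_1 + 0.00023\,Q_2 + 0.01543\,Q_3
      + 0.18694\,Q_4 - 0.05822\,Q_5,$$

then maps to min/day as `mean_wear × plogis(L)`. The index is therefore
bounded in (0, mean wear), strictly increasing in Q1–Q4 and decreasing in
Q5; the coefficients are constants here (recalibration is out of scope).

**DSI Inactivity.** The sum of five 0–4 ratings (0–20); any missing item
gives a missing score (listwise within the scale), consistent with the much
smaller analysable n such scales show.

## 3. The agreement battery

All minute-valued variables are transformed by `log(x + offset)` before
correlation and regression. Minutes distributions have a point mass at
zero, so an offset is required; the default `offset = 1` maps zero to zero
and preserves ranks. The offset the source study used is unknown — this is
the dominant tolerance source when comparing correlation/R² values to
printed ones, and the offset is exposed everywhere.

* `correlation_matrix`: pairwise-complete Pearson r with per-cell n and a
  two-sided p from `t = r√(n−2)/√(1−r²)`.
* `paired_comparison` / `stratified_bias`: classical paired t on **raw**
  minutes (printed biases are in min/day), overall and split at
  60 min/day of objective MVPA — the guideline threshold.
* `bland_altman`: bias = mean difference, limits of agreement
  bias ± 1.96 SD, and the proportional-bias correlation of difference with
  pair mean. The difference is `a − b` for the caller's ordering.
  Orientation matters: paired-bias tables here use self-report minus
  accelerometer (an under-report is negative), while the source study's
  agreement plots are only sign-consistent with their prose if their
  difference was accelerometer minus self-report — so reproducing their
  proportional-bias signs means calling `bland_altman` device-first. Both
  conventions are the same analysis; the package leaves orientation
  explicit instead of hard-coding one.
* `fit_mvpa_regression`: OLS with intercept on complete cases;
  rank-deficient designs are rejected with the collinear columns named.
  Nested models on identical rows have monotone R², which the tests check.
* p-values are two-sided throughout and uncorrected for multiplicity,
  matching the source analyses.

## 4. The synthetic cohort generator

The generator's defaults are the stated world of the reference cohort
(n = 191 boys, 7 days, 15-s epochs): per-class adjusted minutes with means
and SDs sedentary 545.2 ± 56.1, light 167.7 ± 39.6, moderate 37.4 ± 15.7,
vigorous 19.0 ± 14.7, MVPA 56.4 ± 25.0 min/day; wear 769.3 ± 108.9 min/day;
steps near 8000/day; a latent self-report↔objective correlation of 0.3
(the reported correlations cluster around 0.3); screen time 3.3 ± 0.8; and
an inactivity-scale distribution with ≈ 47% zeros.

Per subject, true MVPA is log-normal matched to the MVPA moments — the
right skew matches the reference quartiles' shape (27.9 / 52.3 / 89.0) —
and the standard-normal log z-score `z` is the subject's latent activity
propensity. Wear is normal; sedentary/light split the non-MVPA remainder
around the target ratio. Days get integer class minutes by
largest-remainder allocation of the subject's composition with log-normal
day jitter, so planted minutes sum exactly to the day's wear; 5% of days
are short-wear (120–450 min, hence invalid) to exercise the validity
rules. Embedded non-wear episodes (Poisson rate 0.7/day, 20–90 min) are
inserted at distinct interior cut points of the shuffled wear sequence, so
each is a maximal zero run; the wake block sits inside the day with
overnight zeros around it. Per-epoch counts are uniform within the class's
per-15-s range (sedentary 1–24 — floored at 1 so wear can never produce a
chance zero run — light 25–499, moderate 500–999, vigorous 1000–2400);
within-class shape is irrelevant to threshold-based classification, which
is why uniform suffices. Every planted quantity is recoverable exactly,
which turns the whole reduction stage into an oracle-checkable computation.

**Questionnaires.** Reported MVPA is built from
`z_r = ρ z + √(1−ρ²) z′`, giving exactly the planted log-scale correlation
ρ with true MVPA when reporting is unbiased. An activity-dependent
multiplicative bias (defaults 0.82 below / 0.72 at-or-above 60 min/day of
true MVPA) then produces the qualitative headline of such studies:
near-zero bias in the less active stratum, strong under-reporting in the
active stratum, overall reported mean near 43 min/day. These two factors
were derived analytically from the truncated log-normal means before any
testing, and are not tuned afterwards. Because the step bias itself depends
on true MVPA, the planted ρ is the population correlation only when the
bias is constant; the parameter-recovery tests therefore run with
`reporting_bias = c(inactive = 1, active = 1)`, while the bias tests run
the default world. Reported MVPA is decomposed into day/minute IPAQ answers
constructed to invert exactly under the scoring rules (days chosen so the
per-day minutes land inside [10, 180] whenever the planted value permits),
so the noiseless limit is testable. Walking, sitting, the TPAQ items and
the inactivity ratings come from correlated latents with marginals near
the reference descriptives; the inactivity score is a censored function of
`−0.45 z` plus noise, giving ≈ 45% zeros and a correlation with log MVPA
near −0.3.

**What the generator does not emulate** — and hence what a green test does
not establish: no within-day behavioural structure (activity bouts,
weekday/weekend or seasonal patterns), no biomechanical count waveforms, no
device artefacts beyond zero-run non-wear, and no guarantee that *every*
printed marginal of the reference cohort is jointly reproduced. Two printed
figures are in fact not jointly satisfiable: the TPAQ walking/cycling
quartiles (0.0 / 250.0 / 750.0) contradict their own mean ± SD
(43.1 ± 40.4), and the TPAQ index mean of 59.7 min/day is lower than the
printed coefficient formula yields at the printed item marginals (≈ 70);
the generator follows the item marginals and lets the index mean fall where
the formula puts it.

## 5. Numerical choices and degenerate inputs

* Tolerances: scoring identities are checked to 1e-9, the statistical
  engine against explicit-sum oracles to 1e-10; exact integer equality for
  planted reduction quantities.
* Zero-variance differences give an undefined paired t (reported as `NA`,
  not an error); constant Bland–Altman pairs give `sd_diff = 0` and an
  undefined proportional-bias correlation.
* Correlation cells with fewer than 3 complete pairs are missing.
* A subject with fewer than 3 valid days is `included = FALSE` with all
  summaries `NA` (undefined-as-missing, never zero).
* Seeds: the cohort seed drives subject/day draws; questionnaire draws use
  seed + 1; each subject's stream seed is `(seed mod 1e6)·1000 + i`, kept
  below 2³¹, so streams are reproducible independently of generation order.

## 6. Known limitations

* The deposited per-subject table of the reference study is not
  redistributable here, so the package verifies its numeric-reproduction
  path on clearly-labelled synthetic stand-ins; the column-mapping reader
  (`read_subject_table`) exists precisely so the deposited spreadsheet can
  be dropped in via `options(actipaq.s1_path = )`.
* Reduction covers uniaxial count streams only; raw-acceleration (g-unit)
  processing, bout detection and sleep algorithms are out of scope.
* MET-minute IPAQ scoring and the categorical IPAQ levels are deliberately
  not implemented (minutes per day are the unit of the whole analysis).
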