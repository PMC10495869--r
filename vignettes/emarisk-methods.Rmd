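---
title: "Methods: simulating, featurizing and evaluating EMA cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating, featurizing and evaluating EMA cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`emarisk` implements a complete pipeline for asking whether the *dynamics*
of momentary mood and contextual stressful events — rather than static
history variables — predict suicidal ideation one to eight months later.
This vignette is the package's account of its modelling choices: what the
simulator emulates and deliberately does not, how each tunable parameter is
set and why, the numerical conventions, and the limits of what the test
suite can establish about real data.

## 1. Study design being emulated

The design is a 25-day EMA protocol in young sexual and gender minority
adults: two scheduled prompts per day (morning and evening), six bipolar
mood adjective items scored 0–6 per prompt, a ten-category checklist of
minority-stress events since the previous prompt (marriage pressure,
fertility pressure, economy, housing, medical care, family discrimination,
working, learning, socializing, other), the single category with the most
impact, and a 0–6 worry rating conditional on any event. The 25 days span
three contiguous "waves" around the Lunar New Year (before / during /
after; default boundary days 8 and 17, configurable — no calendar mapping
is assumed). Follow-up assessments at 1, 3 and 8 months dichotomize the
PHQ-9 ninth item (any score ≥ 1 counts as ideation present). Seven
baseline predictors are collected once: baseline suicidal ideation,
lifetime non-suicidal self-injury frequency band (coded ordinally 0 = none,
1 = 1–10, 2 = 11–50, 3 = ≥ 51), lifetime suicide attempt, psychiatric
diagnosis and treatment histories, and family histories of suicide attempt
and of psychiatric diagnosis.

## 2. The synthetic cohort generator

No cohort of this design is publicly deposited, so the generator is a
first-class module: every downstream stage is exercised against data whose
signal structure is known exactly.

**Mood.** Each participant carries one latent AR(1) process over all 50
prompts, `m_t = φ m_{t−1} + ε_t`, with stationary initialization and
`φ = 0.6` (moderate day-to-day carryover, the range typically reported for
momentary affect). Participants differ in volatility: the innovation SD is
`1 × exp(N(0, 0.4))`, i.e. a log-normal individual-differences factor
spanning roughly a factor of two in either direction. This heterogeneity is
essential, not decorative: the "mood instability" construct that the
outcome model rewards is the SD of successive latent changes, and with a
common innovation SD that quantity would differ between participants only
through 50-step sampling noise — there would be nothing for any
mood-dynamics feature to predict. Observed items discretize the shared
latent through fixed loadings (1.0, 0.9, 0.8, 1.0, 0.7, 0.9), item noise
(SD 0.8), rounding, and clipping to 0–6, yielding correlated ordinal items
without asserting any particular factor structure.

**Events.** Each category is an independent Bernoulli draw per prompt.
Default base rates (4–12% per prompt per category) put a typical
participant at roughly one endorsed event per day. During wave 2 the
marriage, fertility and family-discrimination rates triple (the
family-gathering period concentrates exactly those pressures); all other
categories are wave-stationary. Among endorsed categories, the "most
stressful" selection is the one with the highest latent severity draw
(fixed per-category offsets plus noise; ties impossible almost surely,
broken by category order otherwise), and the worry rating is an increasing
function of that severity, rounded and clipped to 0–6. The worry scale and
the single-selection rule are package conventions; the instrument's own
scale for this item is not public.

**Outcomes.** Two standardized person-level latents drive ideation: mood
instability (SD of successive latent mood changes) and event burden (the
weighted count of endorsed events across all prompts, default weights 1 on
marriage, fertility, economy and socializing, 0 elsewhere — so exactly
four event-frequency features are "truly" predictive, a property the
recovery tests rely on). Labels at baseline and the three horizons are
Bernoulli draws from a logistic model. Defaults were fixed once, by
design-stage calibration, and not revisited:

* horizon intercepts (−2.6, −2.2, −1.65, −1.5), root-solved so marginal
  prevalences land near the published cohort's 18.4 / 24.8 / 29.4 / 31.1%;
* `beta_event = (2, 2, 2)` — persistent contextual-event effects. A
  200 000-draw oracle simulation gives a latent-model AUC ≈ 0.86 at β = 2,
  leaving room for feature-level attenuation to land realized
  cross-validated AUC near 0.8, the regime the real study reported;
* `beta_mood = (1.2, 0.6, 0.2)` — mood effects that decay with horizon;
* baseline ideation enters follow-up models with coefficient 0.8.

**Missingness** is missing-completely-at-random at the whole-survey level
(default 5.5%, matching the published 94.5% compliance); items are never
individually missing, mirroring the instrument's all-or-nothing delivery.
No MNAR mechanism is provided, and the generator makes no attempt to match
the real cohort's demographic margins.

Everything is drawn from a single seeded stream; identical configurations
give bit-identical cohorts.

## 3. Day aggregation and the missingness rule

The published rule — a missing survey removes that day's data — is
ambiguous between dropping the survey and dropping the day. The stricter
reading is the default (`require_both = TRUE`): a day is retained only
when both scheduled prompts are present; mood items are averaged over the
day's prompts; event flags are unioned; the day's most-stressful category
comes from the prompt with the higher worry (prompt order breaks ties);
the day's `most_stressful_level` is the maximum worry, 0 when no event was
endorsed (a numeric convention that avoids imputing missing worry).
Participants are retained however few valid days they have; no minimum-day
filter is applied by default because the source design states none.

## 4. The 60 features

Five summaries — mean, sample SD (n−1), OLS slope, maximum absolute
successive change, and probability of acute change — are computed for each
of eight day-level series (six mood items, daily event count, daily
most-stressful level): 40 features. Twenty more count, per category, the
retained days with the category endorsed and the days it was the
most-stressful selection. The column set and order are fixed at exactly 60
regardless of missingness.

Conventions that the source description leaves open, decided here:

* **Slope regressor** is the actual day index, so gaps from dropped days
  are preserved rather than compressed to ranks.
* **Successive differences** are taken between adjacent retained days,
  skipping across dropped days (an adjacent-calendar-days-only variant
  would discard most pairs at realistic missingness).
* **PAC threshold**: the acute-change literature operationalizes "acute"
  against the distribution of observed changes; the package uses the 90th
  percentile (type-7 interpolation) of pooled absolute successive
  differences per variable, computed on training folds only inside
  cross-validation to avoid leakage. A fixed-constant override exists.
* **Degenerate windows**: with fewer than two retained days, SD, slope,
  max-change and PAC are set to 0 (not NA) and the 60-column contract is
  kept; a participant with zero retained days gets an all-zero row and a
  warning. Keeping the schema fixed matters more for the tree models than
  the information lost in these rare rows.
* Features are computed on day-level series (prompt-level mode would
  double series length but the missingness rule is day-based); frequencies
  count days, not prompts.

## 5. Classification and evaluation

The classifier is a gradient-boosted tree ensemble (xgboost, binary
logistic objective), single-threaded and seeded for bit-reproducibility.
Defaults — 150 trees, learning rate 0.1, depth 3, `min_child_weight` 5,
80% row and column subsampling — are conservative settings for a few
hundred observations and 60–67 features. A random-search tuner (25
candidates over trees, learning rate, depth, minimum child weight, and
row/column subsampling; 3-fold inner CV; ties broken toward fewer trees,
then shallower) is provided but off by default: at n ≈ 100–400 the inner
folds are so small that tuning mostly chases noise, and fixed conservative
settings are both faster and more stable.

Evaluation is stratified k-fold cross-validation (round-robin within
class, so per-fold class counts deviate from proportionality by at most
one) repeated independently, 5×3 by default, with 10×3 and leave-one-out
variants. Per fold, the PAC thresholds and the classification threshold
(Youden's J on training-fold predictions; lowest maximizing cut; a fixed
0.5 mode exists) are derived on the training portion only. Reported
metrics are AUC (Mann–Whitney, ties at 1/2), sensitivity, specificity and
PPV (undefined-when-no-positives reported as missing), summarized as the
mean over fold values with a normal-approximation 95% CI — matching the
field's reporting style, with the caveat (recorded here rather than
"corrected") that fold-level values are not independent, so these CIs are
descriptive. LOOCV pools all held-out predictions before computing one set
of metrics, since per-case AUC is undefined; note that at very small n an
intercept-dominated model scores held-out cases at the deleted-case base
rate, which is *anti*-correlated with the true label — a known LOOCV
artifact worth remembering before reading its pooled AUC.

**Importance.** The canonical measure is the split-node count per feature,
min–max scaled to 0–100. Split counts from a single fit are unstable when
informative features are correlated: the ensemble gives one of them the
shared credit, and which one is realization-dependent (in development we
observed a feature whose marginal correlation ranked 6th of 60 land at
split-count rank ~35). `full_data_importance()` therefore supports
aggregating counts over seeded refits and over the three horizon models,
and `marginal_importance_hyperparams()` provides a random-subspace stump
ensemble — depth-1 trees over random 10% feature subsets — whose
aggregated counts approximate a marginal-strength tournament, the
recommended setting when the question is "which features carry signal"
rather than "what does this one model use".

## 6. The three experiments

All designs inside one experiment share identical fold assignments, making
comparisons paired by construction. Metric differences are tested with
two-sided Welch *t* tests on fold-level values (the unpaired test is the
default; fold values are shared, so these p-values are heuristic in the
same way the source analyses' were) and adjusted by Benjamini–Hochberg
within the experiment — one family per panel per horizon, 12 p-values for
a three-design comparison (3 pairs × 4 metrics). The day-overlay curve
refits on days 1..k for each k and reports the smallest k whose mean AUC
exceeds 0.70, the conventional "acceptable accuracy" bar (a named,
configurable constant). The wave analysis recomputes all 60 features
within each wave's days.

## 7. Problem sizes used in the checks

The automated checks run at sizes chosen to give stable Monte-Carlo
behaviour while staying desk-scale: oracle-equivalence sweeps use 1 000
random series and 200 random label/score sets; null calibration uses 20
cohorts of 1 000 participants each (expected CV AUC within [0.45, 0.55]);
signal-recovery and pattern checks use cohorts of 400 with 5×3
cross-validation, averaging the horizon-drift and wave contrasts over
three replicate cohorts because a single 15-fold AUC difference of ~0.05
sits at the edge of fold noise. The acceptance script simulates a
103-participant cohort (the published cohort's size) for schema and
compliance quantities and a 400-participant cohort for the three
experiment designs.

## 8. What passing tests do and do not show

The generator produces correlated ordinal items from one latent factor,
independent Bernoulli events, MCAR missingness, and logistic outcomes that
are exactly the model family the features were designed to capture.
Passing recovery tests therefore show the pipeline is *correct and
well-calibrated*, not that real EMA data behave this way: real mood items
are multidimensional with time-of-day structure; event categories co-occur
and cluster within persons; missingness is plausibly related to state;
outcome prevalence and effect sizes in any real cohort may differ
substantially. The published performance figures (e.g. mean CV AUC ≈ 0.80
at 1 month) come from an undeposited human cohort and are used only as
plausibility anchors for the simulator's calibration, never as test
targets.

Known limitations: no MNAR missingness; no prompt-level feature mode
exercised by the experiments (the flag exists at aggregation level via
`require_both = FALSE`); Wald intervals are used for prevalence because
that is the field's reporting convention, despite their poor coverage near
0; split-count importance inherits every caveat of Section 5 even in its
stabilized form; and the suicide-attempt outcome is out of scope entirely
(the source cohort was too small to model it, and the package follows
suit).
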