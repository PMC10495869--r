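# emarisk

Ecological momentary assessment (EMA) features and short- to long-term
prediction of suicidal ideation.

Intensive longitudinal studies deliver brief surveys to participants'
phones several times a day and ask whether the dynamics of mood and of
stressful minority-stress events predict who will report suicidal ideation
weeks to months later. `emarisk` packages that analysis end to end for
biostatisticians and computational psychiatry researchers:

* a **synthetic cohort generator** with a known, configurable signal
  structure (no real EMA cohort of this kind is publicly deposited, and the
  data are too sensitive to share), emulating a 25-day, twice-daily
  protocol spanning the three Lunar New Year waves, with survey-level
  missingness and wave-elevated family/marriage/fertility event rates;
* **readers and day-aggregation** for long-format EMA CSVs under the strict
  survey-level missingness rule (a day with a missing scheduled prompt is
  dropped whole — no imputation);
* a **featurizer** producing the 60 EMA predictors: mean, SD, OLS slope,
  maximum successive change and probability of acute change (PAC) for each
  of eight day-level series (six mood items, daily stressful-event count,
  daily most-stressful worry level), plus per-category counts of stressful
  and most-stressful event days;
* a **gradient-boosted tree evaluation harness** (xgboost backend) under
  repeated stratified cross-validation with AUC, sensitivity, specificity
  and PPV, Youden-threshold selection and split-count feature importance;
* the three **experiment designs**: baseline vs EMA vs combined predictor
  sets, incremental day-overlay AUC curves, and per-wave analyses, with
  Welch *t* tests on fold-level metrics and Benjamini–Hochberg adjustment.

## The model in brief

For participant *i* with day-level series \(x_{i1},\dots,x_{iT}\) on
retained days \(d_1 < \dots < d_T\), the dynamics features are

* mean \(\bar x_i\) and sample SD \(s_i\),
* slope \(\hat\beta_i\) from OLS of \(x_{it}\) on \(d_t\) (gaps preserved),
* maximum change \(\max_t |x_{i,t+1}-x_{it}|\),
* PAC \(= \Pr(|x_{i,t+1}-x_{it}| \ge \tau)\), with \(\tau\) the 90th
  percentile of pooled absolute successive differences on the training
  folds only.

A binary gradient-boosted classifier \(\hat p(y=1\mid \mathbf{x})\) is
evaluated by stratified 5-fold cross-validation repeated 3 times (also
10×3 and leave-one-out), and feature importance is the frequency with
which each feature is used as a split node, scaled 0–100.

In the simulator, the suicidal-ideation label at horizon
\(h \in \{1, 3, 8\}\) months follows

\(\operatorname{logit} \Pr(y_{ih}=1) = \alpha_h + \beta^{\text{mood}}_h z^{\text{instab}}_i + \beta^{\text{event}}_h z^{\text{burden}}_i + \gamma\, \text{SI}^{\text{base}}_i\)

with decaying mood coefficients (1.2, 0.6, 0.2) and persistent event
coefficients (2, 2, 2) by default, so the generator reproduces the
qualitative phenomenon the pipeline is meant to detect: mood effects fade
with horizon, contextual-event effects persist.

## Worked example

```r
library(emarisk)

co    <- simulate_cohort(sim_config(n_participants = 200, seed = 7))
ds    <- ema_dataset(co$surveys, participants = co$baselines$participant_id)
daily <- day_aggregate(ds)

round(100 * compliance_rate(ds), 1)
#> [1] 94.3

cmp <- compare_predictor_sets(daily, co$baselines, co$outcomes,
                              horizon = "1mo", scheme = cv_scheme(5, 3, seed = 8))
cmp
#> EMA experiment at horizon 1mo
#>   baseline           AUC 0.504  sens 0.455  spec 0.558  ppv 0.311
#>   ema                AUC 0.757  sens 0.448  spec 0.839  ppv 0.445
#>   baseline_plus_ema  AUC 0.797  sens 0.520  spec 0.880  ppv 0.543
#>   5 of 12 pairwise differences BH-significant at 0.05
```

The simulated 200-participant cohort completes 94.3% of its scheduled
surveys. The EMA feature set (mean cross-validated AUC 0.76) clearly
outperforms the seven baseline history predictors (AUC 0.50 — at this
cohort size the history predictors alone carry almost no out-of-fold
signal) at the 1-month horizon. `incremental_day_curve()` then reports how
many EMA days are needed before the mean cross-validated AUC exceeds 0.70,
and `wave_analysis()` evaluates each Lunar New Year wave separately:

```r
dc <- incremental_day_curve(daily, co$outcomes, "1mo",
                            scheme = cv_scheme(5, 3, seed = 8))
dc$crossing_k
#> [1] 11
```

`full_data_importance()` ranks the 60 features by split count; with
`marginal_importance_hyperparams()` it uses a random-subspace stump
ensemble so correlated informative features each receive marginal credit.

## Command line

A thin CLI over the same functions lives at `inst/cli/emarisk.R`:

```sh
Rscript inst/cli/emarisk.R simulate --out sim --n 103 --seed 1
Rscript inst/cli/emarisk.R compare  --ema sim/ema_surveys.csv \
    --baseline sim/participants.csv --out sim --cv 5x3 --horizon 1mo
```
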