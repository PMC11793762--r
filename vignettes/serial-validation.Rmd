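---
title: "Serial validation of static risk models: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serial validation of static risk models: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Clinical risk models for adverse maternal outcomes in preeclampsia (the
fullPIERS logistic score and its machine-learning successors) predict the
probability of a composite adverse outcome — maternal death or severe
end-organ complication — within 48 hours of an assessment. They were built
and validated for use at admission, yet guidelines encourage re-applying
the same static model day after day during expectant management.
`serialrisk` implements the machinery needed to study what happens when a
static model is used that way: daily re-prediction with the latest
available measurements, multi-group risk stratification, per-day
discrimination and clinical-utility metrics, and risk-group transition
accounting — together with a synthetic longitudinal cohort generator with a
known ground truth, so that every stage of the pipeline is testable at desk
scale without access to any clinical database.

All user-facing functions take and return tibbles (or small S3 wrappers
around them) and compose with the pipe; each result type has `autoplot()`
and, where useful, `tidy()`/`glance()` methods.

## Data model

A cohort is two tables. `measurements` is long format, one row per
patient-day, with days anchored at each patient's own day 0 (first
assessment with preeclampsia); `patients` carries `outcome_day`,
`delivery_day` and `end_of_followup_day`. Key invariants, enforced by
`validate_cohort()`:

* `(patient_id, day)` unique, `day >= 0`;
* no measurement row after `outcome_day` — once the composite outcome has
  occurred, later measurements are not part of the evaluation;
* event days lie within `[0, end_of_followup_day]`.

Missing measurements are `NA` in memory and empty cells on disk (literal
`"NA"`/`"NaN"` are accepted on read but never written), which makes CSV
round-trips bit-identical. Units are fixed by the schema (weeks, mmHg, %,
×10⁹/L, fL, µmol/L, U/L) and never converted silently: a unit mismatch is
the caller's error, not a rescale.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure of a large pooled
preeclampsia surveillance cohort (~8,843 women, ~12% composite outcome
incidence, median follow-up 5 days with IQR 3–11, daily outcome counts
decaying from over 200 to around 10 across a 14-day window, roughly 18% of
covariate cells missing). The mechanism, per patient:

1. **Latent severity** `s0 ~ N(0, 1)` evolving as a random walk
   `s[d+1] = s[d] + drift + N(0, innovation_sd)`. One latent dimension is
   the simplest structure that yields correlated multi-organ lab
   derangement and a rising hazard; the defaults are `drift = -0.12`
   (treated inpatients improve on average) and `innovation_sd = 0.2`
   (day-to-day change small relative to the between-patient spread).
   These two values control the late-window behaviour of the cohort: the
   negative drift compresses late hazards (reproducing the decaying daily
   event counts), and the modest innovation keeps selective depletion —
   the sickest patients leaving the risk set through outcome or delivery —
   the dominant force in late-day case mix, which is what produces the
   deterioration of discrimination over time that the serial-evaluation
   literature reports. With a much larger innovation the late risk sets
   re-diversify and late discrimination artificially rebounds.
2. **Covariates** drawn daily from marginals calibrated to published
   admission medians and IQRs. Continuous families use a correlation
   parameterization: on the (log-)scale,
   `x = m + sigma * (rho * s + sqrt(1 - rho^2) * z)` with
   `m = ln(median)` and `sigma = ln(q75/q25)/(2 × 0.6745)` for the
   log-normal family (identity-scale analogues for normal and truncated
   normal). Because `rho * s + sqrt(1 - rho^2) * z` is standard normal
   whatever the loading `rho`, the configured marginal is preserved
   exactly in distribution while the loading controls the covariate's
   correlation with severity. A single scale parameter cannot reproduce
   an *asymmetric* printed IQR (e.g. AST 30 [23–43.05]); the generator
   matches the median exactly and fits the IQR symmetrically on the
   model scale — a documented approximation. SpO2's printed IQR
   (97 [96.85–97]) is degenerate at the upper quartile; the default
   widens it to 97 [96.5–97.5] to satisfy `q25 < median < q75`.
   Gestational age is drawn once at baseline and advances
   deterministically by 1/7 week per day.
3. **Outcome**: each day, a Bernoulli draw with probability from the
   ground-truth logistic model (`default_truth_model()`) applied to that
   day's *true* covariates. The intercept is calibrated so the default
   cohort realizes ≈12% cumulative incidence. Measurements cease on the
   outcome day.
4. **Delivery**: a per-day logit hazard rising with gestational age
   (term induction) and severity. Observation continues a configurable
   `followup_after_delivery` days (default 1 — postnatal visits exist but
   no duration is published) and then censors; undelivered patients censor
   at the horizon. This yields the right-skewed follow-up distribution
   (median ≈ 5 days, long tail from preterm patients under expectant
   management).
5. **Missingness**, applied after the fact to the measurement table only
   (ground truth stays complete): MAR-class covariates are masked with
   probability `plogis(intercept + slope × (sbp − 152))` — sicker-looking
   patients get more complete workups is the *negative*-slope variant; the
   default slope is positive and small, so masking depends on an observed
   variable either way, which is what makes it MAR. MNAR-class covariates
   (platelets, mean platelet volume) follow a skip rule: after day 0 the
   lab is skipped with high probability when the last *observed* value was
   in the configured normal range (clinicians re-measure what looked
   abnormal). Gestational age and systolic BP are always observed so that
   the MAR mechanism conditions on observed data only; the real cohort has
   ~15% missing BP, a simplification we accept.

The generator returns both the masked cohort and the unmasked ground truth
(severity paths and per-day true event probabilities), enabling
parameter-recovery tests: the evaluation engine sees only what a clinician
would have seen, while the truth model knows what generated the events.
This separation creates exactly the information decay a static "snapshot"
model suffers in serial use.

What the generator does **not** emulate: the individual clinical
components of the composite outcome, site/country heterogeneity,
management policies tied to gestational age, and informative measurement
*timing* beyond the MNAR skip rule. Passing tests on synthetic data
therefore demonstrate that the pipeline's accounting and estimators are
correct and that the qualitative serial-performance phenomena are
reproducible under a known mechanism — not that any particular clinical
cohort behaves identically.

## Missing-data handling

Following standard practice for this kind of cohort, the package uses a
hybrid strategy:

* `locf_fill()` — last observation carried forward, per patient, for
  MNAR-class labs (the skip rule above is exactly the situation where
  LOCF is the natural estimate: the value was not measured because it was
  believed unchanged). Leading missingness is preserved; the operation is
  idempotent and never reaches forward in time.
* `multiple_impute()` — chained-equations multiple imputation (default
  `m = 20` completed datasets) for MAR-class covariates: each covariate is
  regressed on all others plus `day`, continuous covariates get Gaussian
  residual draws, the binary symptom covariate gets Bernoulli draws from
  fitted probabilities, over 5 chained sweeps — the smallest standard
  scheme that satisfies the MAR contract. Observed values are preserved
  exactly in every dataset, and the whole set is deterministic under
  `(m, seed)`.
* `pool_estimates()` — downstream metrics are computed per completed
  dataset and averaged, with the between-imputation SD reported alongside.
  Rubin's variance rules are deliberately *not* applied to AUCs (there is
  no accepted closed form for their within-imputation variance);
  percentile-bootstrap CIs are reported instead.

Which covariates are MNAR-class is configuration in the schema (platelets
and mean platelet volume by default), not something the package infers.

## Risk models and stratification

`logistic_model_spec()` expresses any fullPIERS-shaped score — intercept
plus linear, squared, and pairwise-product terms — and
`predict_risk()` evaluates `1/(1 + exp(-eta))`. A missing required
covariate is an explicit error; the serial engine drops such members with
logging rather than zero-filling. Published coefficient sets are meant to
be transcribed into a JSON/YAML config and loaded with
`load_model_spec()`; the package ships only the synthetic generator's
truth model as an example
(`inst/extdata/models/synthetic_truth_model.json`) because shipping a
published model's coefficients requires transcription from its original
publication. Any object obeying the scoring contract (a function from a
covariate tibble to probabilities) can stand in for the model — this is
how externally trained black-box predictors plug into the pipeline.

`stratification_scheme()` maps probabilities to the published five ordered
risk groups with cut-offs 0.6%, 3.1%, 18.8% and 45.6%. Boundary sides
follow the printed intervals: 0.6% and 3.1% belong to *low*, 18.8% and
45.6% to *high*. The intervals partition [0, 1], so every probability maps
to exactly one group; dichotomization is just the two-label scheme with
one cut-off. Probabilities are proportions everywhere inside the package;
percent appears only in I/O and labels.

## The serial evaluation engine

For each day `d` in 0…13 (the two-week window covers the vast majority of
adverse outcomes in this setting), `build_daily_risk_set()` includes every
patient with (i) no outcome before `d`, (ii) follow-up through `d`, and
(iii) at least one measurement at a day ≤ `d`; effective covariates are
per-covariate carry-forward of the latest observation. Three deliberate
conventions:

* a patient whose outcome occurs **on** day `d` stays in day `d`'s risk
  set — the day-`d` prediction deserves credit for flagging them;
  exclusion starts at `d + 1`;
* delivered-but-still-followed patients remain members until
  `end_of_followup_day` (postnatal events are part of the composite);
* the 48-hour label is day-granular: label 1 iff
  `outcome_day ∈ {d, d+1}`, i.e. the half-open window `[d, d+2)`.

`run_consecutive_prediction()` applies the model each day (per completed
dataset when given an imputation set) and `mean_trajectories()` splits
each day's members by *final* status — ever-adverse versus uncomplicated —
to show the separation between the groups' mean predicted risks over time.
Days where a group is empty are `NA`, never 0.

## Metrics

* **AUC-PRC** is the average-precision estimator (step-function integral),
  not trapezoidal PR interpolation, which is biased; tied scores receive
  their tie-block precision. Its natural baseline is the day's fraction of
  positives: a label-independent scorer attains the prevalence in
  expectation, so discriminative value is the gap above that baseline —
  the right lens when positives are rare and AUC-ROC flatters.
* **AUC-ROC** is pairwise concordance with ties counted ½.
* **Bootstrap CIs** are percentile intervals over patient-level resamples
  stratified by label, so each resample keeps the day's (often
  single-digit) positive count; `B = 2000` by default, deterministic under
  seed. The stratification is what keeps late-window CIs defined.
* **Group likelihood ratios**: for group `g`,
  `LR = P(g | outcome) / P(g | no outcome)`, reported as +LR above the
  moderate band and −LR below it. Edge semantics are kept, not
  continuity-corrected away: `Inf` when a group contains outcomes only,
  `NA` when it is empty, `0` when it contains non-outcomes only. CIs use
  the standard log-LR normal method with
  `SE = sqrt(1/tp − 1/(tp+fn) + 1/fp − 1/(fp+tn))` and are suppressed at
  the edges.
* **Decision curves**: net benefit `tp/n − fp/n · pt/(1 − pt)` for the
  model (flag = probability ≥ `pt`, closed at the threshold to match the
  scheme's closed sides), against treat-all and treat-none, on a 0–60%
  grid with the four stratification cut-offs marked. Treat-all and
  treat-none cross at the prevalence.

## Transitions

`assign_daily_states()` gives every patient a state every day: their risk
group, or `outcome` (absorbing from `outcome_day`; outcome takes
precedence over delivery), or `delivered` (absorbing, for patients who
never reach the outcome within the horizon), or an explicit `unscored`
state rather than silent removal. Delivered is absorbing *in this display
view only* — the serial risk sets deliberately keep delivered patients
under follow-up; the two modules differ by design. `build_flow_table()`
then counts day-pair transitions; conservation (occupancy sums to the
cohort size every day; flows out of a day sum to its occupancy) holds by
construction and is asserted in tests. `group_episode_summary()` reports,
per group, the ever-in-group count and how many reached their outcome (or
delivered) within 2 days of *first* classification into the group —
the episode statistics used to characterize rule-in behaviour.
`export_sankey()` writes a renderer-agnostic nodes/links JSON.

## Determinism and problem sizes

Every stochastic stage takes an explicit seed, and `run_pipeline()`
derives per-stage seeds from one root (simulate = seed, impute = seed + 1,
bootstrap = seed + 2), so two runs with the same config are byte-identical
— asserted on output checksums. The test suite exercises generator
calibration at the full cohort size (n = 8,843, averaged over 5 seeds) and
the serial-deterioration property at n = 6,000 over 20 seeds with m = 2
imputations, sizes at which Monte-Carlo noise in the late-window AUC-PRC
(driven by ~10–20 events per late day) is small relative to the effect
being demonstrated; unit and property tests use cohorts of tens to
hundreds of patients.

## Known limitations

* One latent severity factor; real multi-organ heterogeneity is richer.
* Symmetric (on model scale) IQR fits to asymmetric printed quartiles.
* The generator's event-count decay conflates depletion and
  treatment-improvement; no parametric target for the decay shape exists,
  so only its direction and rough magnitude are calibrated.
* Delivery is a hazard, not a competing-risks model; no recalibration or
  dynamic updating of models is implemented — the package evaluates static
  models, it does not fix them.
* Printed headline values from any particular clinical cohort are not
  reproducible here; the pipeline reproduces *properties* (baseline-ratio
  discrimination, deterioration over days, LR edge behaviour, conservation)
  under a known synthetic truth.
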