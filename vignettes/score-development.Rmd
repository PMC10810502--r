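---
title: "Developing and validating bedside severity scores with bqsofa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Developing and validating bedside severity scores with bqsofa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bqsofa)
```

## The problem

In paediatric emergency departments with few monitors and no rapid
laboratory support, clinicians need a way to pick out, at the bedside, the
children most likely to die in hospital. The qSOFA family of scores answers
this with a handful of binary clinical signs, each scored 0 (normal) or 1
(abnormal) and summed: the LqSOFA uses age-adjusted heart rate, age-adjusted
respiratory rate, capillary refill time (CRT) and consciousness level; the
BqSOFA — its adaptation for sub-Saharan African hospital populations —
replaces the respiratory-rate cutoffs with simpler cohort-derived ones,
drops heart rate, and adds moderate/severe pallor, keeping the 0–4 range.
Consciousness is assessed with the Blantyre Coma Scale (BCS, 0–5; below 5 is
abnormal), the paediatric scale in routine use in the region.

This package implements the scores *and* the machinery used to develop and
validate such scores: declarative score definitions, age-banded cutoff
tables, an explicit missing-data policy, discrimination and calibration
metrics, reclassification analysis, univariate screening, a stepwise
amendment engine, and a simulator that generates cohorts with known ground
truth so that every part of the pipeline is testable without patient-level
data (none of the motivating cohorts are public).

## The score model

A `score_definition` is a named list of components; each component is a
predicate over one patient record evaluating to exactly one of *normal*,
*abnormal* or *missing*, with an integer weight (1 throughout the qSOFA
family; larger weights support multi-point comparator scores). The four
predicate kinds, and their comparison conventions, are:

* **vital-above-cutoff** — abnormal when the vital is *strictly above* the
  threshold of the age band containing the child. Bands are half-open
  intervals in months, lower-inclusive, and must partition [2, 192) months
  (2 months to 16 years) exactly; an age outside coverage is an error, never
  a silent default. If either the vital or the age is missing the component
  is missing.
* **crt-prolonged** — abnormal when CRT is *strictly greater* than the
  threshold in seconds (default 3 s, the WHO ETAT shock convention). Both a
  measured `crt_seconds` and a pre-coded `crt_prolonged` yes/no flag are
  accepted because admission forms differ; seconds take precedence when both
  are present.
* **bcs-below** — abnormal when the BCS is *strictly below* the stated value
  (default 5).
* **flag-present** — abnormal when a categorical field is
  `yes`/`moderate-or-severe`; this also covers passthrough columns beyond
  the canonical record, which is how comparator-score components such as
  deep breathing enter.

All cutoff *values* live in editable YAML configuration files shipped under
`inst/extdata/`, not in code: the shipped heart-rate/respiratory-rate tables
are editable defaults (the LqSOFA tables approximate published
hospital-based 99th-percentile charts; the BqSOFA table uses three
memorable bands), and `derive_percentile_cutoffs()` re-derives tables from a
local cohort as the age-banded percentile of the observed values. The
quantile rule is linear interpolation between order statistics
(`stats::quantile` type 7, the common statistical-software default) — the
convention matters at small band sizes, so it is stated and configurable.

## Missing data

Real admission data are incomplete, and more incomplete for sicker
children. The policy, applied per score and in this order:

1. records with a missing outcome are excluded (`missing-outcome`);
2. records with two or more missing components (threshold configurable) are
   excluded (`too-many-missing`);
3. a single tolerated missing component scores 0 — *assumed normal*.

The assume-abnormal variant (`missing_policy(single_missing = "abnormal")`)
exists solely for sensitivity analysis: `missingness_sensitivity()` scores a
cohort under both conventions and reports both AUCs and their difference,
the standard check that the convention is not driving the result. Because
the exclusion rule depends on the component set, every amendment during
development re-applies the policy from scratch — two scores over the same
cohort generally include different children.

## Evaluation

* **AUC** — the Mann–Whitney functional: the probability a randomly chosen
  child who died outscores a randomly chosen survivor, with ties given half
  credit. Half-credit is not a nicety here: the scores take at most five
  values, so a large share of comparisons are ties. Confidence intervals use
  DeLong's distribution-free variance (tie-aware placements); Hanley–McNeil
  is available as an option.
* **Classification metrics** — sensitivity, specificity, PPV and NPV at a
  cutoff, each with a Clopper–Pearson exact interval by default
  (conservative, defensible at the small event counts of mortality cohorts;
  Wilson optional). A metric with a zero denominator is reported as
  undefined, never as 0. Both cutoff conventions are first-class — `ge`
  (score ≥ k positive) and `gt` (score > k) — because both appear in
  routine reporting; every result object carries the semantics used.
* **Calibration** — observed mortality at every attainable score level,
  empty levels reported explicitly.
* **Binary NRI** — for one cutoff per score, the net fraction of deaths
  reclassified upward plus the net fraction of survivors reclassified
  downward, in percent; algebraically identical to ΔSensitivity +
  ΔSpecificity, which the tests exploit as an independent oracle. The CI is
  the asymptotic normal one with the two components' multinomial variances
  summed.
* **Univariate screening** — each candidate sign is cross-tabulated against
  outcome with pairwise deletion; Pearson chi-square without continuity
  correction, switching to two-sided Fisher when any expected cell count is
  strictly below 5 (the conventional rule; the boundary case of expected
  counts exactly 5 stays with chi-square). Predictors with no testable
  table are flagged untestable rather than dropped.

## The development engine

Amendments come in three kinds — substitute a component's cutoff table,
remove a component, add a component — and `stepwise_develop()` tries an
ordered candidate list. The acceptance rule is an explicit, replaceable
predicate (default: accept when the AUC rises or the NRI at the primary
cutoff is positive), because narrative score development is only
reproducible once the rule is explicit. Two modes exist: `"chained"`
(default; an accepted amendment becomes the baseline for the next
candidate, so the trace forms a chain) and `"fixed-baseline"` (every
candidate compared against the same baseline, the natural mode when
screening alternative additions against one intermediate score). The
historical LqSOFA→BqSOFA path ships as a recorded candidate sequence
(`bqsofa_development_sequence()`): substitute the heart-rate and
respiratory-rate tables with 90th-percentile ones, remove heart rate, add
pallor. Replaying it is a structural identity — applying the sequence to
the shipped LqSOFA definition must reproduce the shipped BqSOFA definition
exactly — which keeps the three shipped configs mutually consistent.

## The simulator

`simulate_cohort()` generates cohorts with per-child ground truth in two
modes:

* **score-distribution** mode states the marginal mortality and the
  conditional distributions of the score given death and given survival.
  Its AUC is then available in closed form (`analytic_auc()`), which is the
  exact oracle used to test AUC recovery: at n = 20 000, the empirical AUC
  of the rescored emitted records must sit within Monte-Carlo error of the
  analytic value. Each drawn score is realised as a uniformly chosen subset
  of abnormal components.
* **latent-severity** mode draws a standard-normal severity per child;
  death and each sign follow logistic models in that severity. Intercepts
  are calibrated by numerical integration (`calibrate_intercept()`) so the
  *marginal* rates hit their targets exactly regardless of the slopes.
  This yields correlated signs and mortality that rises with the score
  level.

Numeric vitals are drawn uniformly on the correct side of the child's
age-band cutoff given the sign truth — only threshold crossings matter to
any score, and no vital-sign distributions are identified by descriptive
cohort tables. Ages are log-normal, moment-matched to a target median and
IQR and truncated to [2, 192) months; the family is a simplicity choice, as
no score depends on the age distribution beyond band membership.
Missingness is applied last, per field, MCAR by default; a positive
`missing_slope` tilts missingness toward sicker children, which reproduces
the qualitative finding that excluded children (≥2 missing components) have
higher mortality than included ones.

`make_table1_preset()` packages two configurations whose marginal sign
prevalences, mortality, age distribution and per-field missingness match
published descriptive tables for a development-style cohort (N = 493,
mortality 15.4%) and a validation-style cohort (N = 377, mortality 22.0%).
Two caveats define what passing tests do and do not show. First, marginal
tables do not identify the joint dependence of the signs; the presets'
dependence comes entirely from the one-factor severity model with slopes
chosen once (heart rate deliberately weakest, matching its weak and
inverted crude association with mortality in this population; 0.6–1.2 for
the prognostic signs). Second, as a consequence, score-level operating
characteristics (positivity fractions, sensitivities, AUCs) of simulated
cohorts are properties of the simulator, not estimates of any real
cohort's values; the tests assert marginal recovery, internal consistency
and oracle agreement, never real-cohort performance.

## Numerical choices and degenerate inputs

* Strict inequalities everywhere a threshold is crossed (above cutoff,
  CRT > 3 s, BCS < 5); equality is normal.
* Band membership is lower-inclusive/upper-exclusive, so an age equal to a
  band edge belongs to the upper band.
* Cohorts with no deaths or no survivors among included records raise a
  degenerate-cohort error in every discrimination metric rather than
  returning a vacuous number; 2×2 tables with an empty margin are an
  undefined-test error.
* AUC intervals are truncated to [0, 1]; a single event (or non-event)
  contributes no variance term.
* The NRI requires identical outcomes on the shared included records and
  is computed on the intersection.
* All simulator randomness flows from one integer seed; identical config
  and seed give identical cohorts.

## Problem sizes

The test suite exercises exact oracles on 1 000 random small cohorts
(≤ 30–40 records) for the AUC-enumeration and NRI-identity properties, 20
replicates of n = 20 000 for analytic-AUC recovery, and single n = 20 000
draws for preset marginal recovery — sizes at which three binomial standard
errors separate real defects from sampling noise while the whole suite
runs in well under a minute.

## Limitations

The package evaluates one assessment per admission (no time-series
scoring), binary in-hospital mortality (no time-to-event structure), and
BCS as the only consciousness scale (AVPU is a documented extension point).
The shipped cutoff values are editable defaults, not authoritative
transcriptions; any clinical use requires substituting locally validated
tables. The FEAST-PET configuration is a structural template whose
component list and weights must be completed from an authoritative source
before it scores anything meaningful.
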