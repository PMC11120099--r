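---
title: "Score construction and diagnostic-accuracy methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Score construction and diagnostic-accuracy methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vapscore)
```

## The clinical problem

Ventilator-associated pneumonia (VAP) is among the most frequent
hospital-acquired infections in pediatric intensive care, and no bedside
gold standard exists for its early diagnosis. The Clinical Pulmonary
Infection Score (CPIS) — six components of 0–2 points each: temperature,
blood leukocytes, oxygenation (PaO~2~/FiO~2~), tracheal secretions, chest
radiography, and tracheal-aspirate microbiology — is widely used but has
modest specificity, partly because portable chest radiography reads
poorly in ventilated patients. Two bedside measurements promise better
discrimination: lung ultrasound (LUS), which characterises consolidations
directly, and serum procalcitonin (PCT), a bacterial-infection biomarker.

`vapscore` implements the score family built on that idea, for one
suspected-VAP episode per row:

| score | composition | range |
|---|---|---|
| `cpis` | the six classic components | 0–12 |
| `lus_score` | four LUS findings alone | 0–9 |
| `cpis_lus` | CPIS with radiography replaced by the LUS findings | 0–19 |
| `cpis_pct` | full CPIS plus PCT points | 0–14 |
| `cpis_plus` | CPIS without radiography, plus PCT, plus LUS | 0–21 |

The LUS findings and their points are: consolidation type (subpleural 1,
lobar 2), size (<15 mm 0, 15–20 mm 1, >20 mm 2), laterality (bilateral 1,
unilateral 2) and air bronchogram (static 1, dynamic 3). The dynamic air
bronchogram — air-filled bronchi moving with respiration inside a
consolidation — is the single strongest predictor and accordingly
carries the largest weight.

## Banding conventions

Continuous measurements must map totally, so bands are half-open where
the published bands leave gaps. Temperature scores 2 at ≤36 °C or ≥39 °C
and 1 on [38.5, 39); the unprinted interval (36.0, 36.5) maps to 0, the
clinically normal side. Leukocytes are normal on [4000, 11000]/mm³, with
2 points requiring both an abnormal count and ≥500 band forms/mm³.
Oxygenation is two-valued: 2 points iff P/F ≤ 240 without ARDS (ARDS
makes a low ratio uninformative for pneumonia). PCT bands are
<0.5 / [0.5, 1) / ≥1 ng/mL for 0/1/2 points — the published score-table
convention; an earlier methods passage describing 1/2/3 points is not
used, since the final score table governs. Consolidation size of exactly
20 mm falls in the middle band.

**Missing data are contracts, not imputation targets.** A composite that
needs a missing input (no radiograph, no PCT, no LUS exam) is `NA`, and
`evaluate_panel()` excludes such patients per score with a reported
count — the mechanism that reproduces the evaluated-subset-versus-whole-
cohort distinction that arises when LUS is performed in only part of a
cohort.

Threshold rules are data (`threshold_rule()`), defaulting to CPIS > 6,
CPIS-LUS ≥ 12, CPIS-PLUS ≥ 12, LUS ≥ 7 and CPIS-PCT ≥ 7, with the
deliberate strict inequality for CPIS.

## Deriving points from log-odds ratios

Given per-level 2×2 tables against a reference level ("no consolidation"
/ "no bronchogram"), the package estimates odds ratios (Haldane–Anscombe
+0.5 on zero cells, flagged), Wald intervals on the log scale with
z = Φ^-1^(0.975), and association p-values (Fisher's exact test when any
expected cell is below 5, Pearson's χ² otherwise — the expected-count
rule is ours, since both tests are standard and no switch rule is
canonical).

`points_from_log_or()` turns odds ratios into integer points: the
scaling unit is max(log OR)/max~points~, each level receives its log OR
divided by the unit, rounded half away from zero and clipped to
[0, max~points~]; ORs ≤ 1 receive 0. Round-half-away is chosen because
it reproduces the published point pattern (static 1 / dynamic 3;
15–20 mm 1 / >20 mm 2; bilateral 1 / unilateral 2) from the published
odds ratios. One divergence is inherent: a level with OR exactly 1
(subpleural consolidation, 1 vs 7 in both groups) receives 0 points
under any log-OR-proportional rule, while the published table assigns
it 1 — a reminder that the published assignment also encoded clinical
judgment. No formula choice that is a function of the log OR alone can
award a positive weight to a null association, so we document the
difference rather than special-case it.

`pilot_like_cohort()` reconstructs a 108-episode cohort whose
*per-feature margins* equal the pilot cohort's printed counts exactly
(51/108 confirmed VAP, LUS in 84, every finding-level count). The
coupling across features is an arbitrary deterministic one — only the
margins are identifiable from printed tables — so the object supports
exact reanalysis of per-feature statistics (odds ratios, intervals,
derived points, prevalence) but not of joint quantities such as a
patient-level AUC. It is synthetic and named accordingly.

## Diagnostic-accuracy machinery

Sensitivity, specificity and predictive values carry Wilson score
intervals (chosen for small-sample coverage; the coverage property is
itself tested: ~95% at n = 49, p = 0.78). The AUC is the Mann–Whitney
concordance probability with half credit for ties, computed via
midranks. Its variance and the paired-comparison covariance follow the
placement-value (DeLong) construction: `Var(AUC) = S₁₀/n₁ + S₀₁/n₀`
with `S` the empirical (co)variances of per-positive and per-negative
placement values on the common patient subset. Perfect separation gives
zero estimated variance; the interval then degenerates to the point and
is flagged, and a zero-variance paired difference returns p = 1 by
convention. ROC construction uses the "positive iff score ≥ t"
convention throughout; the strict CPIS > 6 rule exists only at
classification time. Youden-optimal cut-offs are found by exhaustive
search over observed score values, ties broken toward the lowest
threshold.

The test suite checks each estimator against an independent route:
brute-force pair counting and trapezoidal ROC integration for the AUC,
`pROC` for DeLong intervals and paired tests, a 2000-replicate bootstrap
percentile interval at n = 200, a per-patient label-swap permutation z
at n₁ = n₀ = 5 (compared as a median over instances, because the
permutation distribution is coarse there), and exhaustive hypergeometric
enumeration for Fisher p-values at n ≤ 12.

## What the synthetic cohort emulates

`generate_cohort()` draws episodes hierarchically: confirmed-VAP label
(prevalence 51/108), then group-conditional features, then LUS existence
(84/108), consolidation type, and size/laterality/bronchogram
conditional on a consolidation being present. Everything identifiable
from the pilot's printed tables is taken verbatim: the type conditionals
(e.g. P(lobar | VAP, LUS) = 47/49), the consolidated-patient
conditionals for size, laterality and bronchogram, per-group
tracheal-secretion frequencies (12/24/15 of 51 and 32/23/2 of 57) and
fever frequencies (38/51, 36/57). PCT is lognormal per group, inverted
from the printed medians and IQRs (0.47 [0.17–1.32] vs
0.21 [0.10–0.79] ng/mL) via `lognormal_from_quartiles()` —
μ = log(median), σ = (log q₃ − log q₁)/(2 Φ^-1^(0.75)) — lognormal
because the printed quartiles are right-skewed and consistent with one.

Shapes the printed tables cannot identify are fixed defaults, exposed in
`default_generator_config()`: temperature is a febrile/afebrile normal
mixture (39.2 ± 0.7 / 37.1 ± 0.5 °C), leukocytes lognormal from the
whole-cohort quartiles (12 400 [8 500–16 200]/mm³, identical per group as
printed), P/F a low/high normal mixture (180 ± 35 / 300 ± 45), and the
microbiology and radiography mixes were set once so that the simulated
CPIS group means match the printed 6.63 (VAP) vs 5.09 (no-VAP) — the
defaults give ≈6.5 vs ≈5.0 and a whole-cohort CPIS AUC of ≈0.70,
matching the reported value. LUS features are conditionally independent
given group and consolidation status: only marginal tables are printed,
so no richer copula is identifiable; users modelling feature correlation
must override the conditionals.

What passing tests therefore show: the estimators are correct and the
pipeline recovers the parameters it generated, including the qualitative
headline that the ultrasound-augmented scores dominate CPIS (observed in
100 of 100 seeded cohorts of n = 500, and the simulated Youden-optimal
cut-offs coincide with the published thresholds). What they do not show:
calibration of any joint structure in real patients — feature
correlations within an exam, PCT–LUS dependence, or operator effects in
image acquisition are all outside the generator.

## Problem sizes and numerical choices

Large-sample checks use n = 10⁵ draws (law-of-large-numbers
calibration, 3-SE bands), n = 10⁴ cohorts for log-OR parameter recovery
(tolerance ±0.26 on the log scale, ≈2 standard errors of the dominant
zero-ish cell), 100 cohorts of n = 500 for the headline comparison, and
10⁴ binomial replicates for Wilson coverage. The acceptance script
evaluates accuracy on one n = 2000 cohort; all randomness flows from a
single integer seed. Counts in contingency tables are validated as
non-negative integers; degenerate inputs (empty outcome group, zero
margins, single-class ROC input, all-ORs-at-1 derivation) raise errors
rather than returning conventional values, except where a convention is
standard and flagged (zero-variance DeLong comparisons).

## Known limitations

* The derived score table reproduces the published points except for the
  OR = 1 subpleural level, as discussed above.
* The generator's continuous-covariate mixtures are calibration devices,
  not physiological models; only their induced band frequencies matter
  to the scores.
* No multivariable modelling, shrinkage, or internal bootstrap
  validation of the derived table is provided — the derivation is the
  univariable log-OR recipe by design.
* A printed per-unit PCT odds ratio (0.95 with a reversed interval) is
  not reproducible from any printed data and is excluded from the
  reanalysis surface.
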