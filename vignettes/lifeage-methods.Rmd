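---
title: "Life Age: model, calibration, and evaluation methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Life Age: model, calibration, and evaluation methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lifeage)
```

Life Age is a risk-communication metric, not a survival prediction: it
re-expresses a person's modifiable mortality risk and psychosocial
well-being as years added to or removed from their calendar age. This
vignette documents the model, the calibration choices behind the shipped
defaults, the numerical conventions, and what the synthetic-data-based
tests do and do not demonstrate.

## The effective-age conversion

Adult all-cause mortality is well described by a Gompertz hazard
$h(t) = a e^{bt}$. If a lifestyle factor multiplies the hazard by a
relative risk $RR$, the same hazard is reached by a reference person
$\ln(RR)/b$ years older, so

$$\text{years offset} = \frac{\ln RR}{b}.$$

This is `rr_to_years()`. It is log-additive — the offset of a product of
risks is the sum of offsets — which is what justifies summing per-factor
years. The default slope $b = 0.0866\,\text{yr}^{-1}$ corresponds to the
hazard doubling roughly every 8 years ($\ln 2 / 0.0866 \approx 8.0$), a
robust feature of adult mortality schedules in high-income populations.
$b$ only enters when the user supplies relative risks; the shipped
default table is expressed directly in years.

## The default lifestyle table is a calibration, not an estimate

No per-factor relative risks are shipped. The default year offsets

| factor | categories (years) |
|---|---|
| BMI | <23: −1 · 23–24.9: 0 · 25–29.9: +2 · 30–39.9: +4 · ≥40: +8 |
| smoking | never: −2 · ex: 0 · current: +8 |
| alcohol | none/low: −1 · moderate: 0 · binge: +4 |
| diet | optimal: −1 · average: 0 · poor: +4 |
| activity | high: −1 · moderate: 0 · low: +2 · sedentary: +4 |

are a calibration chosen to satisfy two anchor totals — the optimal
profile sums to exactly −6 years and the worst profile to +28 years —
while keeping each factor monotone from healthiest to least healthy
category and giving each factor a zero reference. Within those
constraints the individual cell values are judgement, ordered to match
the relative strength of the underlying evidence (current smoking and
severe obesity dominate). Offsets are relative to the per-factor
reference category, not to a population average; users with published
risks should prefer `la_config(rr = ..., gompertz_slope = ...)`, which
derives the table from them and round-trips to the same totals as a
precomputed years table built from the same risks (tested to 1e-9
years).

Band edges: BMI cut at 23/25/30/40 kg/m²; alcohol no/low below 14
units/week, binge overriding units whenever any typical-week binge
episode is reported; diet optimal at 14-item score ≥ 10 and poor at ≤ 6;
activity sedentary below 1 MET·h/week, low to 10, moderate to 20, high
at ≥ 20 (150 min of moderate activity at 4 MET is 10 MET·h, so
"moderate" starts at the aerobic guideline).

## Questionnaire scoring

* **Diet**: 14 yes/no criteria, one point each. Published banding labels
  low adherence < 7 and high ≥ 8, leaving 7 unassigned; we class 7 as
  low so that "high" always means ≥ 8.
* **Mood**: two 10-item subscales rated 1–5; the analysis variable is
  combined mood = positive − negative (range −40…+40). Missing
  subscales are an error; nothing is imputed.
* **Life satisfaction**: a 5-item, 1–7 scale (total 5–35) — the response
  format consistent with cohort summaries near mean 30, SD 6.
* **Perceived stress**: 10 items rated 0–4, items 4, 5, 7, 8
  reverse-coded, total 0–40.
* **Activity**: minutes are converted at 4.0 MET (moderate) and 8.0 MET
  (vigorous), configurable; directly reported MET·h pass through, and a
  conflicting pair (direct vs derived, > 0.5 MET·h apart) is an error
  rather than a silent preference. The guideline flag is an OR of
  150 moderate / 75 vigorous minutes; an equivalent-minutes blend
  (moderate + 2·vigorous ≥ 150) is available but off by default.

All scorers reject out-of-range or missing items instead of clipping:
questionnaire data errors should surface at entry, not be absorbed.

## Psychosocial years

Each of life satisfaction, combined mood, and stress maps through

$$\text{years} = \mathrm{clip}\left(-d \cdot \frac{x - \mu}{\sigma} \cdot s,\; -2,\; +2\right)$$

with direction $d = +1$ for satisfaction and mood, $-1$ for stress, and
slope $s$ = 1 year per SD by default (configurable per domain). Sleep is
U-shaped: $\min(2, |h - 7| \cdot 1)$, never negative — optimal sleep
earns no bonus. The ±2-year cap per domain keeps the whole psychosocial
block (range −6…+8 under defaults, since sleep cannot go below 0)
comparable in magnitude to the −6-year lifestyle floor.

The shipped norms (satisfaction 24 ± 6, combined mood 15 ± 10, stress
16 ± 7) are documented placeholders to be replaced with a reference
population when one is available. One consequence worth knowing: the
satisfaction instrument's ceiling (35) sits 1.83 SD above the default
norm, so the best *instrument-attainable* psychosocial total is −5.83
years rather than the clip-limit −6; the cap is reached on the unhealthy
side (score 5 is 3.2 SD below norm → +2). Whether the ±2-year range
should be read per domain or for the block as a whole is genuinely
ambiguous in the source material; we implement it per domain with
configurable slopes and leave the block range as a consequence.

## Evaluation machinery

* **Paired t test**: closed form on differences, two-sided. Degenerate
  inputs are defined, not errors: all-zero differences give $t = 0, p = 1$;
  zero variance with nonzero mean gives an infinite statistic and $p = 0$.
* **Wilcoxon signed-rank**: zero differences dropped (classic
  treatment), mid-ranks for tied magnitudes. With $m \le 12$ nonzero
  differences the two-sided p is exact: the null distribution of $W^+$
  over all $2^m$ sign assignments is built by convolution over the
  (doubled, hence integer) ranks and the two-sided tail is measured by
  distance from the center $m(m+1)/4$, which is exact under the
  distribution's symmetry even with ties. Above 12 a normal
  approximation is used with $\mathrm{Var}(W^+) = \sum r_i^2/4$ (with
  mid-ranks this equals the classical tie-corrected variance) and a 0.5
  continuity correction. The threshold of 12 keeps exact enumeration
  cheap while covering the completer counts a feasibility study of this
  size produces.
* **Variable–test assignment** is fixed, mirroring the study analysis
  plan: t tests for diet score, life satisfaction and combined mood;
  signed-rank for Life Age delta, BMI, weight, activity, stress, sleep.
  It is an assignment, not a data-driven normality decision.
* **Sample size** uses normal quantiles,
  $n = \lceil ((z_{1-\alpha/2} + z_{\text{power}})\,\sigma/\delta)^2 \rceil$,
  inflated by $1/(1-\text{dropout})$ — the version that reproduces the
  planning arithmetic of this design (24 completers, 30 enrolled at
  $\delta = 0.5$, $\sigma = 0.75$, 90% power, 20% dropout). Because the
  normal quantile ignores the estimated variance's extra noise, the
  *realized* power of the paired t test at 24 pairs is about 88%
  (the package's own Monte-Carlo simulation and the noncentral-t
  calculation agree); `plot_power_curve()` makes the gap visible. This
  is a property of the classical formula, faithfully reproduced.
* **Summaries** report mean (SD) for parametric variables and median
  with *both* the full range and the IQR, labelled explicitly (summary
  tables in this literature sometimes print min–max under an "IQR"
  heading; labelling both removes the ambiguity). Percentages are
  rounded half away from zero to integers, so 10/16 renders as 63%.
* Two-sided p-values throughout; significance at $p \le 0.05$; no
  multiplicity adjustment (matching the single-arm feasibility analysis
  this reproduces); complete-case analysis only, no imputation.

## The synthetic cohort generator

`generate_cohort()` draws baselines from truncated, grain-rounded normal
distributions calibrated to the feasibility cohort's published
marginals (diet 7.1 ± 1.8, satisfaction 30.6 ± 6.3, positive mood
35.7 ± 6.4, sleep ≈ 6.5 h, BMI ≈ 24.2, waist ≈ 81.3 cm, activity ≈ 13
MET·h; weight is derived as BMI × height² for internal coherence), then
adds per-variable normal change draws whose means default to the
observed mean changes (diet +1.4, satisfaction +3.6, sleep +0.5 h,
stress −1, BMI −1.4, activity +3.4). Change SDs are *free calibration
parameters* — no source publishes them — chosen so that effects of the
observed size are detectable but not certain at ~18 completers. Dropout
is missing-completely-at-random at 1/3 by default (the observed 27 → 18
completion pattern); the 20% figure is the planning assumption and is
the default only in `required_sample_size()`.

Reproducibility: one integer seed governs a cohort; per-variable
substream seeds are derived from it (shared streams for
categoricals/dropout/items drawn first), so adding a variable to the
spec does not disturb the draws of existing ones. Raw questionnaire
items can be back-filled consistently with the target scores
(`items = TRUE`), with reverse-coded stress items generated on the coded
scale and inverted.

What the generator does **not** emulate: correlations between variables
(a real cohort's BMI, activity and diet co-vary; here they are
independent given the margins), informative dropout, regression to the
mean, and measurement error structure. Tests passing on synthetic
cohorts therefore demonstrate that the *pipeline* is correct and
calibrated — type-I error near nominal, known effects recovered — not
that the score has clinical validity on real data.

## Problem sizes and numerical conventions

The shipped tests exercise: 10,000 simulated cohorts for power and
type-I calibration of both tests at n = 18; 1,000 generated cohorts for
parameter recovery (grand-mean SE ≈ 0.011 on the diet change); 300
zero-effect cohorts through the full evaluation pipeline (±0.015 band
around the nominal 5%); 200 random instances for exact-vs-enumeration
signed-rank equivalence; and 10,000 profiles for exact decomposition and
bit-reproducibility. These sizes give Monte-Carlo error comfortably
below each assertion's band and run in about a minute.

Other conventions: scoring is deterministic (identical inputs and
configuration give bit-identical output, asserted in the tests); the
additive decomposition `delta = lifestyle_years + psychosocial_years`
is checked on every scored row; chronological age outside 30–60 warns
but scores (the target range is a study property, not a mathematical
one); waist circumference and sex are carried but unscored; configs and
norms embed a version tag and an FNV-1a content fingerprint in every
result for provenance; percentages use round-half-away-from-zero
(base R's `round()` rounds half to even, which would print 10/16 as
62%).

## Known limitations

The default offset table and psychosocial norms are calibrations, and
honest use on real participants requires replacing them with sourced
relative risks and reference-population norms. There is no sex- or
age-specific stratification of offsets, no interaction between factors,
and no absolute-risk or life-expectancy output — by design, Life Age is
a communication device whose decomposition must stay legible.
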