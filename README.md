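# lifeage

**lifeage** computes "Life Age": a mortality-anchored effective-age score
for communicating lifestyle risk to healthy adults, plus the statistical
machinery to evaluate a single-arm pre/post lifestyle intervention on it.
It is aimed at researchers running (or planning) small behavioural
feasibility studies who want a transparent, fully configurable scoring
engine and a reproducible analysis pipeline — with a synthetic-cohort
generator so everything can be exercised without participant data.

## The model

Life Age is chronological age plus two signed year components:

```
life_age = age + lifestyle_years + psychosocial_years
delta    = life_age - age
```

**Lifestyle years.** Adult all-cause mortality follows a Gompertz hazard
h(t) = a·exp(b·t), so multiplying the hazard by a relative risk RR is
equivalent to shifting age by

```
years = ln(RR) / b
```

(`rr_to_years()`; default b = 0.0866/yr, a hazard doubling time of ~8
years). Each of five modifiable factors — BMI band, smoking status,
alcohol band, Mediterranean-diet adherence band (14-item score), and
physical-activity band (MET·h/week) — contributes a year offset relative
to a zero reference category, and the offsets add with no interactions.
The shipped default table is calibrated so the optimal profile
(BMI < 23, never-smoker, no/low alcohol, optimal diet, high activity)
totals **−6 years** and the worst profile (BMI ≥ 40, current smoker,
binge drinker, poor diet, sedentary) totals **+28 years**. Published
relative risks can be supplied instead (`la_config(rr = ..., gompertz_slope = ...)`).

**Psychosocial years.** Life satisfaction, combined mood
(positive − negative affect), and perceived stress are mapped by
standardized distance from a population norm,
`clip(−direction · (score − mean)/sd · years_per_sd, −2, +2)`, so each
domain contributes at most ±2 years; sleep is mapped by absolute
deviation from a 7 h/night optimum (U-shaped risk), `min(2, |h − 7|)`.

**Evaluation.** Paired t tests (diet score, life satisfaction, combined
mood) and Wilcoxon signed-rank tests (Life Age delta, BMI, weight,
activity, stress, sleep) on complete cases, with exact signed-rank
p-values by full sign-assignment enumeration when ≤ 12 nonzero
differences remain; normal-quantile paired sample size with dropout
inflation; Monte-Carlo power simulation.

## Worked example

```r
library(lifeage)

p <- list(id = "p1", age = 45, bmi = 27.5, smoking = "ex",
          alcohol_units = 18, binge = FALSE, diet_score = 6, met_hours = 6,
          positive_mood = 32, negative_mood = 21, life_satisfaction = 19,
          stress = 24, sleep_hours = 6)
compute_life_age(p)
#> Life Age for participant 'p1'
#>   chronological age : 45.0 y
#>   lifestyle years   : +8.0 y
#>   psychosocial years: +3.4 y
#>   Life Age          : 56.4 y  (delta +11.4 y)
#>   config default-1.0 (8cd7917d), norms default-1.0
```

This participant's Life Age is 11.4 years older than their calendar age:
+8 from lifestyle (overweight BMI band +2, poor diet +4, low activity
+2) and +3.4 from psychosocial well-being (satisfaction 0.83 SD below
norm → +0.83 y, mood +0.4 y, stress +1.14 y, one hour short of optimal
sleep → +1 y); `tidy(compute_life_age(p))` returns that breakdown as a
tibble and `autoplot()` draws it.

A whole study, end to end, on synthetic data:

```r
coh <- generate_cohort(27, seed = 42)   # paired cohort, 1/3 MCAR dropout
ev  <- evaluate_pre_post(coh)
ev
#> Single-arm pre/post evaluation: 27 enrolled, 15 completed (56%)
#> Paired tests at alpha = 0.05:
#>           variable          method  n estimate statistic p.value significant
#>         diet_score        paired_t 15     1.40      3.86 0.00173        TRUE
#>              delta wilcoxon_approx 15    -2.14      7.00 0.00287        TRUE
#>        sleep_hours  wilcoxon_exact 15     0.50     55.00 0.00195        TRUE
#>  ...
tidy(ev)      # one row per tested variable
glance(ev)    # enrolment, completion, significant-test counts
autoplot(ev)  # estimate dot plot
```

Here the generator's default change effects (diet +1.4 units,
satisfaction +3.6, sleep +0.5 h, ...) produced significant improvements
in diet score, sleep and the Life Age delta among the 15 completers,
while BMI and weight moved in the right direction without reaching
significance — the pattern of a small single-arm study.

Design planning:

```r
required_sample_size(delta = 0.5, sd = 0.75, alpha = 0.05,
                     power = 0.90, dropout = 0.20)
#> Paired design: delta 0.5, SD 0.75, alpha 0.05 (two-sided), power 0.9
#>   completers needed: 24
#>   enrol (dropout 20%): 30
simulate_power(n = 24, delta = 0.5, sd = 0.75, reps = 10000, seed = 1)
```

A thin command-line wrapper (`inst/cli/lifeage.R`) exposes
`score`, `evaluate`, `simulate` and `power` subcommands over CSV/YAML
files.

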