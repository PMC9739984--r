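---
title: "Estimating dietary environmental footprints from frequency and recall data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating dietary environmental footprints from frequency and recall data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietfootprint)
```

## The estimation problem

Food-frequency ("propensity") questionnaires record *how often* each of a
fixed list of food groups was eaten over the last year — a count from 1 to
10 per day, week, month, or year — but not *how much*. A 24-hour dietary
recall records amounts, foods and preparations, but only for a single day.
`dietfootprint` combines the two instruments with a life-cycle-assessment
(LCA) coefficient table to estimate, per respondent, the carbon footprint
(CF, g CO~2~eq/day), water footprint (WF, L/day) and ecological footprint
(EF, m²/day) of habitual diet, and standardizes each to 1000 kcal of
estimated energy intake so that respondents with different total intakes
are comparable.

The chain has four steps:

1. **Daily frequency.** A report of $c$ times per period becomes
   $f = c / d$ occurrences per day, with fixed divisors
   $d \in \{1, 7, 30, 365\}$ for day/week/month/year.
2. **Estimated food consumption.** For group $i$,
   $\mathrm{EFC}_i = f_i \times \mathrm{percapita}_i / 1000$ in kg/day,
   where the per-capita amount per consumption occasion (grams) comes from
   the *pooled* 24HR: the mean of observed mass amounts weighted by the
   number of times each food was consumed. Volumes are converted to masses
   by explicit dilution rules (1 g/mL is a reasonable default for thin
   liquids; powders need their own entries, and a missing rule is an
   error, never a silent 1:1 guess).
3. **Footprint totals.** Each group's coefficient (per kg) is the
   consumption-weighted mean over the raw/prepared foods observed in the
   24HR, and the individual total is
   $F = \sum_i \mathrm{EFC}_i \times \mathrm{impact}_i$.
4. **Energy standardization.** Estimated energy is
   $E = \sum_i \mathrm{EFC}_i \times 10 \times \mathrm{kcal100}_i$, where
   $\mathrm{kcal100}_i$ is the group's unweighted mean caloric density per
   100 g from the composition table — the factor 10 converts kilograms
   into 100-g portions and is required for $E$ to be in kcal/day. The
   standardized value is $F \times 1000 / E$.

Two readings of the per-capita sentence in the field's questionnaire
methodology are defensible — a times-weighted mean or a median of amounts —
so both are implemented (`estimator` argument of `group_per_capita()`),
with the weighted mean as default since weighting by the number of times a
food was consumed is the more explicit convention. Likewise, per-capita
amounts can be computed from the pooled cohort recall (default, matching
the design in which each respondent contributes one recall day) or per
individual with pooled fallback (`per_capita_mode = "individual"`).

## Downstream analyses

**Tertiles.** Standardized footprints are split at the empirical 1/3 and
2/3 quantiles (linear interpolation) into low/medium/high strata. Because
quantile cuts do not by themselves balance tied data, membership is
assigned by stable rank (ties broken by input order), guaranteeing group
sizes differ by at most one; remainders go to the lower tertiles. Tertile
cuts default to the *adjusted* (per-1000-kcal) values, since stratum-level
summaries are reported on that scale; `tertile_basis = "raw"` is available.

**Contribution decomposition.** Within any stratum, group $g$'s
contribution is $100 \times \sum_{\text{members}} a_g / \sum
\text{totals}$, where $a_g$ are the per-group addends. Percentages close
to 100 within each stratum by construction, and are invariant to a uniform
rescaling of all coefficients.

**Rank-based comparisons.** Footprint distributions are right-skewed, so
group differences are tested with the Mann–Whitney U test (two categories)
or Kruskal–Wallis (three or more), two-sided throughout. The U statistic
is reported as $\min(U_x, U_y)$; p-values are exact (full enumeration) for
$n_x + n_y \le 12$ without ties, otherwise the normal approximation with
tie and continuity corrections. Normality screening uses the one-sample
Kolmogorov–Smirnov statistic against a normal with estimated mean/SD; the
result carries a note that the standard asymptotic p-value is conservative
in this estimated-parameter (Lilliefors) situation. Category tables get a
compact letter display: groups share a letter iff their pairwise
Mann–Whitney p is at or above the level. No multiple-testing adjustment is
applied by default (an optional Bonferroni flag exists), mirroring common
practice in descriptive epidemiological tables.

**Correspondence analysis.** Tertile × category tables are decomposed from
first principles: SVD of the standardized residual matrix
$S = D_r^{-1/2}(P - rc^\top)D_c^{-1/2}$, principal coordinates for both
point clouds (both are plotted in one map, so both are scaled by the
singular values), principal inertias $\lambda_k = d_k^2$ with
$\sum_k \lambda_k = \chi^2 / n$. Missing ("don't know / didn't answer")
categories are dropped with a logged count, never imputed. The association
verdict uses the standard rule, $p < \alpha$ strictly; a literal
"observed chi-square below the critical value" condition that circulates
in some software manuals is the reverse of the standard rejection region,
so it is computed and reported in the rationale but never enforced. The
graphical ellipse device often drawn around tertiles has no standard
numeric definition; the package instead reports each category's nearest
tertile by chi-square map distance (`nearest_tertile()`).

## What the synthetic cohort emulates

Survey microdata of this kind are typically unavailable for privacy
reasons, so `generate_cohort()` produces every input table from one seed:

- **Covariates** for 411 respondents drawn from the reference cohort's
  category marginals (42.1% male, 53.5% adults, 35.3% white, income
  quintiles near 20% each), with per-item "don't know / didn't answer"
  rates of roughly 0.7–2.9% matching the per-item footnotes of the study
  table.
- **41 food groups** partitioned into eight classes. Coefficients are
  log-normal within class around synthetic medians chosen so that the
  ruminant-meat class is an order of magnitude more carbon- and
  water-intensive per kg than plant classes (30 000 vs 700–1500 g CO~2~eq/kg),
  reproducing the qualitative dominance of animal-source foods without
  embedding any published coefficient.
- **Consumption.** Each respondent × group has a latent daily frequency:
  class baseline × covariate effect multipliers × log-normal noise
  (sdlog 0.6), encoded to the questionnaire's (count, period) format by
  choosing the finest period whose rounded count lies in 1–10. Recall
  amounts are log-normal (sdlog 0.35) around class medians; beverages are
  reported in mL with a 1 g/mL dilution table. The spreads were chosen
  once as realistic dietary heterogeneity: they put the simulated
  adjusted-footprint interquartile range at roughly half the median, the
  dispersion regime typical of energy-adjusted footprint surveys.
- **Effects.** The default specification encodes the study-pattern
  gradients (male, adult and higher-income respondents eat more of the
  meat classes, with the income multiplier rising from 1 to 1.5 across
  quintiles). `null_effect_spec()` switches every multiplier to 1 for
  calibration runs; `income_effect_spec(1.5)` isolates a single income
  gradient for recovery experiments; `ground_truth_report()` states the
  orderings a non-null cohort should display.

What the generator does **not** emulate: real Brazilian diet composition,
seasonal or day-of-week recall structure, correlated covariates (income
and schooling are drawn independently), survey design weights, or
measurement error in the questionnaire itself. Passing tests therefore
demonstrate that the estimation chain is arithmetically correct, calibrated
under the null, and able to recover planted monotone effects of realistic
size — not that any particular real-world footprint value is right, which
depends entirely on the user-supplied coefficient and composition tables.

## Numerical and design choices

- Period divisors are fixed at 365/30/7/1; no calendar-aware variants.
- A group observed in the recall but consumed by nobody contributes
  nothing; a group reported on the questionnaire with no pooled recall
  profile is an error at the function level and an explicit, counted drop
  (`on_missing_profile = "drop"`) at the pipeline level.
- Respondents with non-positive estimated energy keep raw totals but no
  standardized value; they are counted in the exclusion log and omitted
  from tertiles and tests.
- Degenerate tertile input (all values equal) falls back to stable-order
  assignment with a warning rather than failing.
- Duplicate (food, preparation) coefficient rows are an error: coefficient
  tables are curated inputs, and silent overwrites hide curation mistakes.
- Contingency tables with all-zero rows/columns are pruned (with a
  warning) before decomposition; empty intersections are errors.
- The pipeline writes no timestamps, so identical inputs give
  byte-identical outputs.

Simulation-based checks in the test suite run at deliberately modest
problem sizes — property sweeps on cohorts of 24–60 respondents with
10–12 groups, calibration at the full n = 411 over 1000 (null) and 100
(recovery) replicates — sizes at which the binomial noise on a rejection
rate is a fraction of the acceptance band being checked.

## Known limitations

- Energy estimated from group-mean caloric densities inherits the FFQ's
  upward bias; standardized values are comparable within a cohort but not
  calibrated against doubly-labelled-water intakes.
- The compact-letter construction uses unadjusted pairwise tests by
  default; with many categories the familywise error grows accordingly.
- The KS screen's asymptotic p-value is conservative with estimated
  parameters; it is a screen, not a test of record.
- Correspondence analysis is descriptive; its chi-square test assumes
  independent observations and is reported as such, without survey-design
  correction.
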