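# dietfootprint

Estimation of the environmental footprints of individual diets —
carbon (CF, g CO₂eq/day), water (WF, L/day) and ecological (EF, m²/day) —
from the two instruments epidemiological diet surveys actually field: a
food-frequency ("propensity") questionnaire that records how often each
of a fixed list of food groups was eaten (a count of 1–10 per day, week,
month or year), and a 24-hour dietary recall that records amounts, foods
and preparations for one day. It is written for nutrition and
environmental epidemiologists who have such survey tables plus a
life-cycle-assessment (LCA) coefficient table, and want per-respondent
footprints, energy-standardized comparisons and association analyses
without re-deriving the arithmetic each time.

## The method

For each respondent and food group *i*:

```
f_i    = count_i / d_i                      d ∈ {1, 7, 30, 365}   (occurrences/day)
EFC_i  = f_i × percapita_i / 1000                                 (kg/day)
F      = Σ_i EFC_i × impact_i                                     (footprint/day)
E      = Σ_i EFC_i × 10 × kcal100_i                               (kcal/day)
EEF    = F × 1000 / E                                             (footprint/1000 kcal)
```

where `percapita_i` (g per consumption occasion) and the weighted group
coefficient `impact_i` (per kg) come from the cohort's pooled 24-hour
recall, and `kcal100_i` is the group's mean caloric density per 100 g from
a food-composition table. Standardized footprints are split into
low/medium/high tertiles; per-group percentage contributions are
decomposed per stratum; differences across socioeconomic and
food-purchase categories are tested with Mann–Whitney / Kruskal–Wallis
rank tests (with a compact letter display); and tertile × category tables
are examined by correspondence analysis (SVD of standardized residuals,
principal coordinates, total inertia = χ²/n) with an explicit association
verdict. A synthetic-cohort generator produces all four input tables with
configurable covariate→consumption effects, so the entire pipeline is
testable without access to survey microdata.

## Worked example

```r
library(dietfootprint)

cohort <- generate_cohort(generator_config(seed = 7))   # 411 respondents, 41 groups
analysis <- analyze_cohort(cohort)

s <- analysis$summary
round(c(cf_day  = s$cf$total$median,  cf_1000 = s$cf$per_1000kcal$median,
        wf_day  = s$wf$total$median,  wf_1000 = s$wf$per_1000kcal$median,
        ef_day  = s$ef$total$median,  ef_1000 = s$ef$per_1000kcal$median,
        kcal    = s$energy_kcal$median), 1)
#>  cf_day cf_1000  wf_day wf_1000  ef_day ef_1000    kcal
#>  8530.4  3272.5  5653.3  2197.1    50.8    20.2  2508.2
```

The median simulated diet emits ~8.5 kg CO₂eq/day (3273 g CO₂eq per
1000 kcal), embeds ~5653 L of water and ~51 m² of bioproductive area per
day, on ~2508 kcal/day of estimated intake. Contributions show the
animal-source dominance the generator builds in — the two meat classes
account for 85% of the carbon footprint in the high-CF tertile versus 59%
in the low one:

```r
meat <- cohort$groups$group_id[cohort$groups$class %in%
                               c("ruminant_meat", "other_meat")]
ct <- analysis$contributions
sum(ct$percent[ct$stratum == "high" & ct$footprint_kind == "CF" &
               ct$group_id %in% meat])
#> [1] 85.4
```

The default generator plants higher meat intake for male, adult and
higher-income respondents, and the analysis recovers the income gradient
(Kruskal–Wallis across quintiles on CF per 1000 kcal):

```r
cmp <- analysis$comparison
cmp[cmp$variable == "income_quintile",
    c("category", "n", "median_CF", "letters_CF", "p_CF")]
#>   category     n median_CF letters_CF    p_CF
#> 1 Q1          92     2866. a          0.00827
#> 2 Q2          72     2982. a,b        0.00827
#> 3 Q3          70     3549. b,c        0.00827
#> 4 Q4          75     3308. b,c        0.00827
#> 5 Q5          92     3667. c          0.00827
```

File-based runs go through `run_config()` + `run_pipeline()` (or the thin
CLI: `exec/enf simulate --seed 1 --n 411 --out inputs/` then
`exec/enf run --config cfg.yaml`), writing per-respondent footprints,
addends, tertiles, contribution tables, the stratified comparison table,
correspondence-analysis coordinates and verdicts, a JSON summary and an
exclusion log — byte-identical across re-runs on the same inputs.

## Package layout

- `R/foodb.R` — coefficient/composition/registry loading and validation
- `R/intake.R` — questionnaire and recall ingestion, dilution rules,
  pooled per-capita amounts and weighted group coefficients
- `R/footprint.R` — the estimation chain (frequencies, EFC, totals,
  energy, 1000-kcal standardization)
- `R/strata.R` — tertiles, stratum medians, contribution decomposition
- `R/stats_tests.R` — rank tests, KS screen, compact letters, the
  stratified comparison table
- `R/ca.R` — correspondence analysis and association verdicts
- `R/synthetic.R` — the cohort generator and its effect specifications
- `R/pipeline.R` — end-to-end orchestration and file I/O
- `vignettes/dietary-footprints.Rmd` — the methods vignette (model,
  assumptions, generator realism, numerical choices, limitations)
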