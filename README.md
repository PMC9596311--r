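# heartage

Cardiovascular risk is easier to communicate as a **predicted heart age
(PHA)**: the chronological age of a person with the same 10-year
cardiovascular disease (CVD) risk but all modifiable risk factors at ideal
levels. This package implements a full population-level PHA analysis for
STEPS-style national risk-factor surveys — the kind of pooled,
design-weighted microdata analysis epidemiologists run to ask *how much
older are people's hearts than their birth certificates, and would the
people with "old hearts" even qualify for preventive treatment under
risk-based guidelines?*

It is aimed at epidemiologists and biostatisticians working with
survey microdata (the real WHO STEPS files are access-controlled, so a
synthetic generator with known ground truth stands in for them end to end).

## What it computes

The sex-specific Framingham general-CVD risk (D'Agostino et al.,
*Circulation* 2008), office-based (non-laboratory) and lipid-based
(laboratory) variants:

    risk = 1 − S0(10)^exp(LP − mean LP),
    LP = β·ln(age) + β·ln(SBP) [treated/untreated] + β·ln(BMI or lipids)
         + β·smoker + β·diabetes

and its closed-form inversion to heart age against the ideal reference
(SBP 125 mmHg untreated, BMI 22.5 kg/m², non-smoker, non-diabetic):

    PHA = exp((LP_subject − C_ideal) / β_ln_age)

plus, around that core:

* STEPS-style cleaning: inclusion rules (30–74 y, non-pregnant, no CVD
  history), plausibility ranges, complete-case filtering, with a
  reason-coded drop ledger and per-country flow tables;
* censoring of PHA to `"<30"`/`">80"` and classification of the PHA − age
  gap (low / equal / high / very high, excess = ≥ 1 year);
* WHO HEARTS antihypertensive and lipid-lowering eligibility rules;
* survey-weighted prevalence with stratified between-PSU Taylor
  linearization, risk-quintile stratification, region/income ANOVA;
* mixed-effects logistic models (country nested in region) for correlates
  of excess PHA and of treatment eligibility;
* a multi-country synthetic survey generator with injected implausible
  values, missingness, and a complete truth ledger.

## Worked example

```r
library(heartage)

p <- data.frame(sex = c("female", "male"), age = c(61, 40),
                sbp = c(140, 160), on_bp_treatment = c(TRUE, FALSE),
                bmi = c(28, 31), smoker = c(TRUE, TRUE),
                diabetes = c(FALSE, TRUE))
score_heart_age(p)[, c("sex", "age", "risk_10y", "pha_continuous",
                       "pha_coded", "gap_class", "excess")]
#>      sex age risk_10y pha_continuous pha_coded gap_class excess
#> 1 female  61    0.261          101.8       >80 very_high   TRUE
#> 2   male  40    0.266           74.9        75 very_high   TRUE
```

The treated, smoking 61-year-old woman has a 26.1% 10-year risk — the risk
of an ideal-factor woman older than 80, so her PHA is censored to `">80"`
and her gap class is *very high* (≥ 5 years above chronological age). The
40-year-old man with SBP 160, BMI 31, smoking and diabetes has the risk of
a 75-year-old with ideal factors: a 35-year excess. Both meet WHO HEARTS
treatment thresholds:

```r
treatment_eligibility(c(0.261, 0.266), sbp = c(140, 160), dbp = c(85, 95),
                      age = c(61, 40), diabetes = c(FALSE, TRUE))
#>   elig_aht elig_aht_rule elig_llt elig_llt_rule
#> 1     TRUE  risk20_bp130     TRUE        risk20
#> 2     TRUE  risk20_bp130     TRUE        risk20
```

## The analysis workflow

`analysis/01_simulate.R` … `06_sensitivity_lab.R` run the full study on the
synthetic multi-country population (16 presets, six WHO regions, 2,000
records each) and write tidy tables under `results/`: cleaning flow, scored
records, category prevalence by country and sex, eligibility among
excess-PHA people at gap thresholds 1/5/10/20 years, risk-quintile tables,
a plot-ready age-band flow table, ANOVA summaries, odds-ratio tables, and
the laboratory-vs-non-laboratory paired sensitivity comparison:

```sh
for s in analysis/0*.R; do Rscript "$s"; done
```

A typical run keeps ~92% of raw records, censors ~2% of PHAs to `">80"`,
finds excess PHA in roughly three quarters of the cleaned population, and —
as in real survey populations — a majority of people with excess PHA meet
neither treatment-eligibility rule.

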