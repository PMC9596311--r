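---
title: "Predicted heart age from survey risk factors: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicted heart age from survey risk factors: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heartage)
```

## The model

The package implements the Framingham general cardiovascular disease (CVD)
risk profile (D'Agostino et al., *Circulation* 2008): a sex-specific Cox
model whose 10-year risk is

$$\text{risk} = 1 - S_0(10)^{\exp(LP - \bar{LP})}, \qquad
LP = \sum_j \beta_j x_j,$$

with natural-log transforms of age, systolic blood pressure (a separate
coefficient when the person is on antihypertensive treatment), and either
BMI (the office-based, *non-laboratory* variant) or total and HDL
cholesterol (the *laboratory* variant), plus 0/1 indicators for current
smoking and diabetes. $S_0(10)$ is the sex-specific 10-year baseline
survival and $\bar{LP}$ the cohort mean linear predictor. The constants live
in `inst/extdata/framingham_coefficients.yaml`, transcribed from the score
publication and locked by a checksum test; we validated the transcription
against that publication's printed worked example (10.5% for the reference
woman) before freezing the file. Risk is carried as a fraction throughout;
percent formatting happens only in reporting code.

**Predicted heart age (PHA)** is the age of a person with the same risk but
all modifiable factors at the ideal reference: SBP 125 mmHg untreated, BMI
22.5 kg/m², non-smoker, non-diabetic. Since only the age term remains free
on the ideal side, the inversion is closed-form:

$$a^* = \exp\!\left(\frac{LP_{\text{subject}} - C_{\text{ideal}}}
{\beta_{\ln \text{age}}}\right),$$

where $C_{\text{ideal}}$ sums the non-age ideal-reference terms. Tests check
this against a bisection root-finder on the forward model to $10^{-6}$
years, and the self-inversion identity (an ideal-profile subject's heart age
equals their chronological age) to $10^{-6}$ years over the whole 30–74 age
range. For the laboratory variant the ideal lipid levels are total
cholesterol 180 and HDL 45 mg/dl, the score publication's "normal" profile;
this is a package choice, as the primary analysis is the non-laboratory
variant.

**Censoring and the gap.** Continuous PHA is rounded to whole years (halves
away from zero) and then censored: below 30 it is reported as `"<30"`,
above 80 as `">80"`. Censoring after rounding means 29.6 becomes 30, not
`"<30"`; the alternative is a one-line change in `censor_code()`. The gap
versus chronological age is categorized as *low* (< 0), *equal* (0), *high*
(1–4 years) or *very high* (≥ 5 years); *excess* is high or very high.
Sentinels are classified by bounding, not imputation: `">80"` implies a gap
of at least $81 -$ age, hence always *very high* for eligible ages; `"<30"`
implies at most $29 -$ age, hence always *low*. The same bounds feed the
graded excess thresholds (≥5, ≥10, ≥20 years). The gap is never reported as
a continuous outcome.

## Cleaning and variable derivation

Records are kept only for non-pregnant adults aged 30–74 without
self-reported CVD history, with all measured values inside the plausibility
ranges (SBP 70–270, DBP 30–150 mmHg, height 1.00–2.50 m, weight 12–300 kg,
BMI 10–80 kg/m², waist 30–200 cm, FPG 45–540, total cholesterol 67–773
mg/dl; shipped as data in `plausibility_ranges.yaml`), and complete on every
analysis variable. Each dropped record carries the *first* failing rule in a
fixed order (age window, pregnancy, CVD history, the eight plausibility
rules, complete-case), so flow tables conserve counts. Three design
decisions worth knowing:

* BP plausibility is evaluated on the analysis value — the mean of the 2nd
  and 3rd measurements (the 1st is discarded) — not per measurement; DBP
  mirrors the SBP averaging rule.
* BMI plausibility (10–80) applies to derived BMI *before* the calculator
  clamp (15–50, applied with a flag at scoring time); the two ranges serve
  different purposes.
* Missingness in covariates used only by the regressions (education,
  marital, work status) does not exclude a record from heart-age
  estimation — the least destructive reading of complete-case analysis;
  the regression code applies its own complete-case filter.

Diabetes is FPG ≥ 126 mg/dl or self-reported diagnosis; high cholesterol is
total cholesterol ≥ 200 mg/dl; abdominal obesity is waist ≥ 102 cm (men) /
≥ 88 cm (women). Education, marital and work codes collapse to 4/3/5
harmonized categories whose first levels (none, never married, unemployed)
are the regression reference levels.

## Treatment eligibility

WHO HEARTS rules, evaluated on exact risk fractions (not rounded percent):
antihypertensive treatment when risk ∈ [10%, 20%) with SBP ≥ 140 or DBP ≥
90; risk ≥ 20% with SBP ≥ 130 or DBP ≥ 80; or SBP ≥ 160 or DBP ≥ 100
regardless of risk. Lipid-lowering treatment when risk ≥ 20% or at age ≥ 40
with diabetes. "10%–19%" is implemented as [0.10, 0.20) so the two risk
bands partition [0.10, ∞). The rule engine is tested exactly against
brute-force clause evaluation on an exhaustive boundary grid.

## Survey estimation

Prevalences are weighted proportions with stratified between-PSU Taylor
linearization: scores $z_i = w_i (y_i - \hat p)/W$ are summed to PSU totals
and the variance is $\sum_h \frac{n_h}{n_h-1}\sum_c (z_{hc} - \bar z_h)^2$.
Strata with a lone PSU contribute squared deviations from the grand mean of
PSU totals. CIs are normal-approximation on the proportion scale, truncated
to [0,1] — close to standard survey-software defaults. On equal-weight,
one-record-per-PSU designs the SE reproduces the binomial SRS formula up to
the $n/(n-1)$ factor. Risk quintiles are computed per country from the
weighted risk distribution (type-1 weighted quantiles); boundary ties fall
to the lower quintile, so fully tied risks land in Q1. Region and income
contrasts of country-level prevalence use classic one-way ANOVA, excluding
groups with fewer than two countries. The chronological-age-by-heart-age
flow table is deliberately unweighted, since it describes divergence rather
than national prevalence.

## Correlate models

Mixed-effects logistic regressions with random intercepts for region and
for country-within-region, fixed effects education + abdominal obesity +
high cholesterol + marital + work + smoking + diabetes (diabetes omitted
for lipid-therapy eligibility, where it is part of the outcome definition),
fitted by `lme4::glmer`. Eligibility models are restricted to records with
excess PHA. Survey weights are not used in these models. Wald z tests and
exponentiated coefficients give the OR tables. Estimation uses the Laplace
approximation by default; `nAGQ = 0` (the faster penalized-least-squares
step) is used for large replicate studies and the pipeline driver, and the
200-replicate null calibration shows ~95% CI coverage for all terms under
that setting. Random terms whose grouping factor has fewer than two levels
are dropped with variance reported as zero; with none left the fit collapses
to ordinary logistic regression, which realizes — and is tested against —
the single-cluster collapse property at $10^{-3}$ on the log-odds scale.
Fits either converge or carry an explicit non-convergence status; runaway
estimates (|log-odds| > 15 or SE > 100) are flagged per coefficient as
separation.

## The synthetic-data generator

Real inputs to this kind of analysis are application-gated national
surveys, so the package ships a generator whose defaults define the study
conditions. Sixteen country presets spanning the six WHO regions carry
survey-reported weighted means and prevalences (mean age, proportion male,
mean SBP, mean BMI, smoking, total diabetes); dispersions are not reported
by the surveys, so they are fixed package defaults chosen once as
field-plausible values (age SD 11 y truncated to 30–74, SBP SD 18 mmHg, BMI
SD 4.8 kg/m², lognormal FPG with log-SD 0.18, lognormal total and HDL
cholesterol with log-SD 0.19/0.25, waist SD 11 cm). A single latent
"metabolic" factor (loading 0.45, negated for HDL) plus a PSU-level effect
(ICC 0.03) induces positive cross-correlations among adiposity, glycemia,
lipids and blood pressure and realistic design effects; waist additionally
tracks BMI with correlation 0.6. FPG location is calibrated so the
glucose criterion carries 60% of the target total diabetes prevalence and
self-reported diagnosis tops up the rest, making the analytic total equal
the target exactly. Three BP readings are emitted as true pressure plus
independent noise (SD 4 mmHg), the first biased +2.5 mmHg, so discarding
the first reading matters. Designs use 5 strata × 8 PSUs and lognormal
weights (log-SD 0.4; zero gives exactly equal weights). Implausible values
are injected at stated per-variable rates from documented out-of-range
bands — BP corruption overwrites readings 2 and 3 jointly, and BMI
corruption uses in-range height/weight pairs with an out-of-range ratio, so
every corruption deterministically trips exactly its own cleaning rule —
and a truth ledger records every corruption, every analytic prevalence and
the weight construction. Countries are generated from hash-derived
substreams of the master seed, so a country's records are identical however
many countries are batched.

What the generator does **not** emulate: sex-specific risk-factor levels
(apart from waist and height), age trends in blood pressure or BMI,
treatment effects on measured BP, correlations between socio-demographic
covariates and risk factors, and real STEPS inter-variable correlation
matrices. Passing tests therefore demonstrate that the *machinery* —
cleaning, scoring, inversion, design-aware estimation, model fitting — is
correct under known ground truth, not that any particular country's printed
estimates are reproduced; the real microdata are access-controlled, and
sex contrasts in generator output should not be read as emulating the real
male–female gap.

## Numerical choices and problem sizes

Inversion tolerances: closed form vs bisection $10^{-6}$ years; round-trip
risk $10^{-9}$. Rounding of PHA is half-away-from-zero (base R's `round`
is banker's rounding, which would map 56.5 to 56). Degenerate paired
comparisons (all differences equal) report an undefined t as `NA` with a
flag rather than an error. The test and driver problem sizes are the
package's own choices: 1,000 random profiles per sex for inversion
properties, 50,000-record surveys (5 replicates) for generator recovery,
200 replicates of 40 countries × 500 records for the GLMM null calibration,
and 2,000 records per country for the 16-preset analysis workflow.

## Known limitations

The equations are not recalibrated for non-Framingham populations (the
non-laboratory variant is known to overestimate risk relative to the
laboratory variant — visible in the shipped sensitivity stage); no
heart-age algorithm exists for the 2019 WHO risk charts, so they are out of
scope, as are other guideline systems and antiplatelet therapy. Reported
risk is not capped (some published calculators cap at 30%); thresholded
logic is unaffected.
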