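# cfcsurv

Coronary flow capacity mapping and survival modelling in R.

`cfcsurv` is for cardiovascular imaging researchers and biostatisticians
working with quantitative myocardial perfusion PET. It takes per-pixel
rest/stress perfusion polar maps of the left ventricle (LV), classifies each
pixel into one of seven ordered coronary flow capacity (CFC) severity
classes, summarises the size-severity of disease as fractions of the LV,
links those fractions to all-cause mortality through a multivariable Cox
model with time-dependent revascularization, and asks the counterfactual
question revascularization decisions hinge on: *how much survival benefit
could fixing the severely flow-limited myocardium plausibly buy this
patient?*

## The model

**Classification.** Each of the 1344 polar-map pixels carries coronary flow
reserve CFR = stress/rest and stress perfusion *s* (mL/min/g). A pixel is
scored on both scales against the published breakpoints

| class | CFR | stress (mL/min/g) |
|---|---|---|
| EXCELLENT | > 2.9 | > 2.17 |
| ADEQUATE | (2.38, 2.9] | (1.82, 2.17] |
| MILD | (1.6, 2.38] | (1.09, 1.82] |
| MODERATE | (1.27, 1.6] | (0.83, 1.09] |
| SEVERE | [1.0, 1.27] | ≤ 0.83 |

and receives the more severe of the two single-scale ranks. Two overrides
take precedence: myocardial **scar** (rest ≤ 0.3 *and* stress ≤ 0.3) and
myocardial **steal** (CFR < 1). Class fractions of LV form the grouped Cox
covariates: `cfc_normal` (EXCELLENT + ADEQUATE, reference), `cfc_mild`,
`cfc_severe` (MODERATE + SEVERE + STEAL) and `scar`.

**Survival.** With covariates x(t) including the time-dependent
revascularization indicator and its interaction with severe-CFC
involvement, the hazard is λ(t | x) = λ₀(t) exp(xᵀβ) and per-patient
survival probability is S(t | x) = exp(−Λ₀(t) e^{xᵀβ}) with the Breslow
baseline Λ₀ (Efron ties).

**Virtual revascularization.** The *Optimal Virtual* probability replaces
the severe fraction with normal CFC; the *Realistic Virtual* probability
redistributes it between normal and mild in proportion to their prevalence
outside the severe region. Both are predicted under the revascularized
pathway; their gap to the observed post-revascularization estimate
(discordance) quantifies residual or incompletely treated disease.

A seeded synthetic-data generator (`sim_config()`, `generate_cohort()`,
`generate_paired_cohort()`) emulates the whole data structure — contiguous
artery-territory defects across all seven classes, microvascular and
diffuse patterns, and piecewise-exponential survival with confounded
treatment assignment — so every stage is testable with known ground truth.

## Worked example

```r
library(cfcsurv)

cfg    <- sim_config(seed = 7, n_patients = 2000)
cohort <- generate_cohort(cfg)
kept   <- apply_inclusion_filter(cohort$records)  # >90-day follow-up
fit    <- fit_cox(expand_time_dependent(kept))
tidy(fit)
#> # A tibble: 7 × 7
#>   term            estimate std_error statistic  p_value conf_low conf_high
#> 1 cfc_mild          0.357    0.318        1.12 2.62e- 1 -0.267      0.980
#> 2 cfc_severe        1.92     0.314        6.13 8.85e-10  1.31       2.54
#> 3 scar              1.56     0.553        2.82 4.78e- 3  0.477      2.65
#> 4 age               0.0374   0.00398      9.39 6.06e-21  0.0296     0.0452
#> 5 sex_male          0.175    0.0897       1.95 5.13e- 2 -0.00101    0.351
#> 6 revasc            0.355    0.149        2.39 1.70e- 2  0.0635     0.646
#> 7 revasc_x_severe  -0.724    0.209       -3.46 5.45e- 4 -1.13      -0.313
```

The fitted coefficients recover the generator's truth (β_severe = 2,
β_scar = 1.5, β_age = 0.04, harmful revascularization main effect with a
protective severe-stratum interaction). Predicted 10-year mortality by
stratum and pathway:

```r
cohort_mortality_contrast(fit, kept, horizon = 10)
#>   stratum    pathway          n mean_mortality relative_reduction
#> 1 non_severe no_revasc     1343          0.343             -0.300
#> 2 non_severe revasc_at_t0  1343          0.445             -0.300
#> 3 severe     no_revasc      632          0.466              0.234
#> 4 severe     revasc_at_t0   632          0.357              0.234
```

Revascularization reduces predicted mortality only where severe CFC is
present — in the non-severe stratum it is harmful, as encoded in the
generating hazard. Counterfactual survival for three severe patients:

```r
virtual_survival(fit, kept[kept$cfc_severe > 0, ][1:3, ], horizon = 10)
#>   patient_id observed_prob optimal_virtual_prob realistic_virtual_prob
#> 1 P00001             0.373                0.637                  0.624
#> 2 P00006             0.527                0.729                  0.721
#> 3 P00008             0.691                0.782                  0.780
```

For P00001, ideal complete revascularization would raise the model's
10-year survival probability from 0.37 to at most 0.64; the realistic
estimate (0.62) accounts for the surrounding diffusely diseased tissue the
procedure cannot normalise.

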