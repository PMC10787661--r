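---
title: "Coronary flow capacity, survival, and virtual revascularization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coronary flow capacity, survival, and virtual revascularization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfcsurv)
```

## The problem

Quantitative rest/stress perfusion PET measures myocardial blood flow in
mL/min/g for every pixel of a left-ventricular polar map. Coronary flow
capacity (CFC) compresses the two per-pixel measurements — coronary flow
reserve (CFR, the stress/rest ratio) and absolute stress perfusion — into
seven ordered severity classes, and the fraction of the LV occupied by each
class ("size-severity") is what carries prognostic information. `cfcsurv`
implements the full chain: pixel classification, size-severity
summarisation, a Cox survival model on the grouped fractions, and
counterfactual ("virtual") survival after hypothetical revascularization.

## Pixel classification

A pixel is ranked separately on CFR (breakpoints 2.9, 2.38, 1.6, 1.27,
exclusive lower bounds, inclusive upper bounds) and on stress perfusion
(2.17, 1.82, 1.09, 0.83 mL/min/g), and receives the more severe of the two
ranks. The printed class definitions are conjunctions of a CFR range and a
stress range, which leaves discordant combinations (for example preserved
CFR with low absolute stress flow) undefined; the worst-rank rule covers
the whole plane, is monotone in each input, and errs on the side of
severity, which matches how joint flow criteria are used clinically. Two
overrides precede the ranked classes:

* **Scar** — rest ≤ 0.3 *and* stress ≤ 0.3 mL/min/g. A fixed defect is
  defined by absolute flows alone, so it is tested before anything else
  (the near-unity CFR of a scar would otherwise rank it as viable).
* **Steal** — CFR < 1, stress flow below rest flow, defined solely by CFR.

CFR uses a floored divisor, `stress / max(rest, 0.1)`, because near-zero
rest values are dominated by noise and would otherwise produce unbounded
ratios; flooring happens after the scar test, which uses raw rest. Floored
pixels are flagged and surfaced by the pipeline stage.

Boundary semantics are verified two independent ways: bisection along each
input axis must recover every printed breakpoint to 1e-6, and the
classifier must agree with a separately coded interval-table oracle on a
dense grid of (CFR, stress) combinations — both are in the test suite.

## Grouping and layout choices

The survival covariates group the classes as `cfc_normal` = EXCELLENT +
ADEQUATE (the reference), `cfc_mild` = MILD, `cfc_severe` = MODERATE +
SEVERE + STEAL, and `scar`. Whether steal belongs in the severe group is
genuinely open — it is the extreme of flow limitation but a distinct
mechanism — so `summarize_map(steal_in_severe = FALSE)` splits it into its
own `cfc_steal` column while keeping the groups a partition of the LV.

The default layout is 21 rings × 64 sectors = 1344 pixels. Only the pixel
count is canonical; the ring/sector factorisation and the contiguous
LAD/LCx/RCA sector arcs (40/30/30%) are package defaults, overridable via
`polar_layout()`.

## The survival model

Records with ≤ 90 days of follow-up are excluded. Each patient contributes
counting-process intervals split at the revascularization time, with the
`revasc` covariate switching 0 → 1 and its interaction with the
severe-involvement indicator (`cfc_severe > 0`, the threshold is a
parameter). Covariates enter as fractions of LV in [0, 1] for coefficient
scale stability; human-readable reports print percent. Fitting delegates
to `survival::coxph` with the Efron tie approximation (ties arise only
through duplicated data here, but Efron is the safer default); the Breslow
baseline cumulative hazard at covariate zero is stored as a step function.
Ten-year survival is S(10 | x) = exp(−Λ₀(10) e^{xᵀβ}), with last value
carried forward (and flagged) beyond the final event time.

An independent brute-force implementation of the Efron partial likelihood
and score — explicit loops over event times and risk sets,
`cox_partial_loglik()` — is part of the package surface. The test suite
requires it to agree with `coxph` to 1e-8 at arbitrary coefficient values
on small cohorts, so the fitting route and the verification route cannot
share a defect.

A deliberate subtlety: duplicating a cohort leaves Cox estimates unchanged
only under the Breslow tie approximation, because duplication creates
cross-copy event ties that Efron downweights differently. `fit_cox()`
therefore exposes `ties`, and the invariance test runs under Breslow.

## Virtual revascularization

Both virtual transforms zero the severe fraction and conserve total mass:

* **Optimal**: all severe mass moves to normal — ideal complete
  revascularization.
* **Realistic**: severe mass splits between normal and mild in proportion
  n : m, their prevalence outside the severe region. The clause "keep mild
  constant" cannot hold simultaneously with a proportionate split; the
  proportional rule is the default because it follows the stated ratio
  most literally, and a `mild_constant` mode (all mass to normal, mild
  frozen) is selectable. When n + m = 0 the degenerate rule sends all
  severe mass to normal and flags the row.

Virtual predictions use the revascularized pathway so they are comparable
with observed post-revascularization estimates. The severe indicator in
the revascularization interaction is fixed at its **baseline** value for
the observed, optimal and realistic predictions alike: effect modification
describes the pre-treatment state, and if the indicator instead followed
the modified covariates, a protective interaction would hand the observed
(severe-present) prediction a benefit the severe-cleared virtual
predictions lose, inverting the expected ordering for small severe
fractions. With the indicator held fixed, optimal ≥ realistic ≥ observed
is a theorem whenever the fitted β_severe ≥ β_mild ≥ 0, and the
discordance between virtual and observed-post estimates isolates exactly
the difference between the maps. Both transforms are idempotent, and the
pixel-level variant (relabel severe-group pixels, then summarise) produces
identical grouped covariates to the covariate-level transform.

## Comparison statistics

Severity histograms order the seven classes by rank (scar most severe) and
the two-sample KS statistic is the maximum absolute gap between cumulative
curves. P-values use the asymptotic two-sample KS series with effective
sample size n·m/(n+m) on pixel counts and should be read as nominal:
polar-map pixels are spatially correlated, so the effective information is
lower. Paired survival changes are classified better/worse/unchanged with
an |Δ| < 0.005 unchanged band (probabilities are reported to ~2 decimals,
so smaller differences are not meaningful); strata follow the standard
reporting split: severe present, non-severe, and normal CFC over ≥ 90% of
LV. Bland–Altman agreement and the serial coefficient of variance (SD of
paired differences / √2, over the pooled mean) complete the paired
toolkit.

## The synthetic generator

The generator emulates the *structure* of a referral CAD cohort, not any
specific dataset:

* **Maps.** Background pixels draw (CFR, stress) uniformly inside the
  EXCELLENT/ADEQUATE boxes; each defect is a contiguous breadth-first
  region grown inside an artery territory (spilling into neighbours when
  larger than the territory), with values drawn strictly inside the target
  class's decision box and a one-pixel rim from the next-milder class.
  Setting rest = stress/CFR guarantees the intended label under the
  worst-rank rule without modelling tracer kinetics. Subendo/subepi layers
  carry a preserved (≈1.0) or reduced (≈0.8) transmural ratio for the
  microvascular vs diffuse-CAD patterns, against a healthy reference band
  of 1.0 ± 2·0.075.
* **Archetype mixture** (defaults): 38% no defect, 24% mild, 15% moderate,
  13% severe, 4% steal, 6% scar, defect extents uniform on [0.05, 0.45] of
  LV, severe-group patients carrying an extra diffuse mild component up to
  0.2. This reproduces the qualitative shape of a tertiary referral mix —
  most studies abnormal, a minority severe.
* **Survival.** Piecewise-exponential hazard h₀·exp(lp) switching at the
  revascularization time, h₀ = 0.03/yr, β = (mild 0.8, severe 2.0, scar
  1.5, age 0.04/yr centred at 65, male 0.3, revasc +0.25, severe×revasc
  −0.9). The net severe-stratum revascularization hazard ratio
  exp(−0.65) ≈ 0.52 mirrors the roughly 40% mortality reduction reported
  for severe flow limitation, while the harmful main effect encodes
  procedural risk without physiologic benefit in near-normal hearts.
  Revascularization is assigned with probability `plogis(−2.2 + 6·severe)`
  — confounding by indication — at a uniform time in [0.1, 2] years, and
  occurs only if the patient is still under observation. Censoring is
  administrative at 12 years plus uniform drop-out on [0.5, 30] years.
  Because age enters the generating hazard centred while the model fits it
  linearly, the offset is absorbed by the baseline and all coefficients
  remain comparable.
* **Paired cohorts.** Post-revascularization maps derive from pre maps by
  archetype: complete (all severe-group pixels redrawn normal), partial
  (half), failed (unchanged), harmed (a fifth of normal pixels degraded) —
  emulating the heterogeneous response spectrum.

What the generator does **not** emulate: PET noise spectra, attenuation
artifacts, motion, spatially smooth perfusion gradients, or correlations
between age and disease extent. Passing tests therefore demonstrate the
pipeline's internal correctness and statistical calibration under a known
truth, not clinical performance on real images.

## Problem sizes and numerical choices

The test suite uses cohorts of 600–5000 patients and 200 parameter-recovery
replicates at n = 2000 — sizes at which Cox coefficient bias is expected
below 10% of truth with 95% CI coverage near nominal, while the full suite
runs in about a minute. The recovery replicates draw covariate fractions
directly from the archetype distribution rather than rendering a polar map
per patient; the map path is exercised separately and round-trips exactly,
so rendering 2.7 million pixels per replicate would add cost without
information. Bisection tolerances are 1e-6 (boundaries are exact to
machine precision; 1e-6 matches the reporting precision), conservation
checks use 1e-12, and oracle agreement 1e-8 (Cox) / 1e-12 (KS). Degenerate
inputs — zero events, constant covariates, revascularization at or after
the end of follow-up, empty maps, zero pooled means — are rejected or
flagged rather than silently handled.

## Known limitations

* The classifier assumes the published breakpoints; no ROC re-derivation.
* The Cox model treats the CFC fractions as linear effects; no splines or
  time-varying coefficients.
* Virtual probabilities are model extrapolations conditional on the fitted
  coefficients; they inherit any confounding the model does not absorb.
* KS p-values treat pixels as independent draws, which overstates
  information; use the D statistic for effect size.
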