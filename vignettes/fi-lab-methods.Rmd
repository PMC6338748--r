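---
title: "Methods: the FI-LAB frailty index, its synthetic cohort, and the mortality models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the FI-LAB frailty index, its synthetic cohort, and the mortality models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(filab)
```

## The deficit-accumulation model

A frailty index treats health as an accumulation of *deficits*: binary
indicators of something being wrong. The FI-LAB restricts the deficit set
to routine blood laboratory variables, so it can be computed from a single
fasting blood sample without questionnaires or functional testing. Here
the panel has 22 variables: white cells, neutrophil percentage, platelets,
red cells, haemoglobin, haematocrit, MCV, MCH, MCHC, glucose, total
cholesterol, triglycerides, LDL-C, HDL-C, total and direct bilirubin, ALT,
albumin, globulin, urea, creatinine and uric acid.

Each variable is coded 1 when the value falls outside its normal range and
0 when inside; the index is the ratio of deficits to variables actually
measured, so it lies in [0, 1]. Three coding conventions matter and are
fixed here:

* **Interval endpoints are normal.** A haemoglobin of exactly 131 g/L for
  a man (range 131–172) is *not* a deficit. Two-sided ranges are treated
  as closed intervals.
* **One-sided cut-offs follow their printed inequality strictly.** Total
  cholesterol is normal when "< 5.18" mmol/L, so 5.18 itself is a deficit;
  HDL-C is normal when "≥ 1.04", so 1.04 itself is normal. Each panel
  entry carries its own `bound_style`, so either convention can be
  configured per variable.
* **The completeness rule.** The published construction requires most of
  the panel to be present. The wording is ambiguous about whether 70%
  refers to the panel or to something else; we fix the interpretation as:
  a subject's index is valid only when ≥ 70% of the panel variables are
  non-missing, and the denominator is the count of non-missing variables.
  This keeps the index a ratio of considered items and matches the
  original 20+-variable construction lineage.

The default panel ships the printed reference table verbatim, including a
female MCV lower bound of 32.6 fL that is almost certainly a misprint of
82.6 fL (32.6 fL is not a survivable MCV). Fidelity wins by default; the
corrected panel is available as `load_reference_panel("table3_mcv82")`,
and no pipeline behaviour other than MCV coding depends on the choice.
Two further oddities are shipped as printed: the neutrophil entry is a
percentage (50–70%) although described elsewhere as a count, and the
direct-bilirubin cut-off "< 3.4" µmol/L is unusually low. Units are
metadata only; no conversion is attempted.

Subjects at or above the **cut-point 0.21** are classified frail. The
cut-point is inclusive (printed as "≥") and configurable; 0.20–0.25 is the
conventional comparability band with phenotype-based frailty.

## The synthetic cohort

No individual-level data accompany the study this pipeline reproduces, so
the package carries a generator whose defaults *are* the study
conditions: n = 736 subjects aged 90–108 (truncated normal, mean 93.6,
SD 3.4 years), 67.5% female, index mean 0.21 and SD 0.10, frail hazard
ratio 1.32, and 53.5% overall mortality over a 4-year follow-up with
administrative censoring.

**Correlated deficits.** Per-variable abnormality frequencies are not
published, only the index moments, so deficits are exchangeable: subject
*i* draws a latent propensity `q_i ~ Beta(a, b)` with mean `p` and
intraclass correlation `rho = 1/(a + b + 1)`, then 22 independent
Bernoulli(`q_i`) indicators. The index (the row mean) then has variance

```
Var(FI) = p (1 - p) [ rho + (1 - rho) / N ]    (N = 22)
```

and `rho` is solved from the targeted SD: `icc_from_moments(0.21, 0.10,
22)` gives ≈ 0.0155. With completely-at-random missingness the observed
denominator `n_obs` varies, inflating the variance to
`p(1-p)[rho + (1-rho) E(1/n_obs)]`; `icc_from_moments()` accepts the
missingness rate and solves the corrected identity, so the realised index
still hits the target SD. The default missingness is 2% per value — small,
because the source cohort excluded subjects without blood samples, so
near-complete panels are the realistic condition.

**Lab realisation.** The binary deficit matrix is converted to concrete
lab values: normal codes draw uniformly inside the subject's sex-specific
normal range, deficits draw outside it (side chosen at random for
two-sided ranges, within a bounded offset of 25% of the range width so
values stay physiologic). Re-coding the emitted values reproduces the
deficit matrix exactly — draws are continuous and R's uniform sampler
never returns an interval endpoint — which the tests assert as an exact
round trip for both panels.

**Survival.** Event times are exponential within group under proportional
hazards — the simplest model that satisfies exactly the assumption the Cox
analysis fits — with administrative censoring at 4 years. The non-frail
rate λ solves

```
(1 - prev) exp(-λt) + prev exp(-hr λ t) = 1 - mortality
```

by bracketed root-finding (residual < 1e-10). The generator calibrates λ
against the *generated cohort's own* frail prevalence, so the expected
death fraction equals the target exactly. Two consequences are worth
stating plainly: the Beta-Binomial model implies a frail prevalence of
about 49% at the 0.21 cut-point, slightly below the reported 50.5% — a
two-parameter calibration cannot also pin the prevalence — and the
data-dependent order statistics (median, maximum, 99th percentile) are not
calibration targets at all.

**Covariates** (education in three levels, smoking, alcohol, exercise,
eight chronic-disease flags) are generated independently of frailty at
their reported prevalences. Independence is deliberate: the published
adjusted hazard ratios are nearly identical to the unadjusted one,
implying weak confounding, and independent covariates give the adjusted
models a sharp null to verify — the frailty HR must not move beyond
Monte-Carlo noise across the four nested models.

What the generator does **not** emulate: the real correlation structure
among labs (haemoglobin–haematocrit coupling and the like — deficits are
exchangeable), informative missingness, survival bias of nonagenarian
sampling, and covariate–frailty confounding (unless effects are configured
explicitly). Passing tests therefore show the *pipeline* is correct and
the *calibration identities* hold, not that real nonagenarian data would
reproduce any particular hazard ratio.

## Survival models

The Cox models use `survival::coxph` with **Breslow tie handling** by
default, matching the default of the legacy statistics package used in
the original analysis lineage; Efron is available by flag. Confidence
intervals are Wald on the log-hazard scale, no robust variance. The four
model specifications are nested: unadjusted; + age, sex, education; +
smoking, alcohol, exercise; + the eight chronic-disease flags. Covariates
that are constant in a given cohort are dropped from that fit rather than
crashing it.

The per-variable hazard screen fits one univariate Cox model per panel
variable with that variable's deficit code as the only regressor.
Variables with fewer than **5 events in either arm** are flagged unstable
and their estimates withheld — a published ALT row with HR 0.05 and a CI
spanning two orders of magnitude is what such cells look like when
reported anyway; we surface instability rather than print it.

Cumulative hazards use the Nelson–Aalen estimator via
`survival::survfit`, verified in tests against hand-computed increments
(events / at-risk at each event time) and invariant to record duplication.
The tests also compare `coxph` coefficients against an independent
coarse-then-fine grid search of the Breslow partial likelihood written
directly from the risk-set definition, with agreement to 1e-4.

## Comparison statistics

Group tables mirror the usual cohort-paper layout: mean ± SD with an
unpaired pooled-variance t-test for continuous variables, percentage with
a Pearson chi-square for binary ones, flags at 0.05/0.01, and no
multiplicity correction (matching per-row testing convention). Three
numerical choices are fixed because they reproduce printed statistics
from reconstructable inputs:

* **Chi-square without continuity correction** is the default; the
  uncorrected statistic reproduces the published 22.6 (sex by frailty) and
  4.27 (respiratory disease by vital status) from counts reconstructed
  off printed percentages and margins; the Yates-corrected one does not.
* **Wilson score interval** is the default proportion CI; it reproduces
  both printed prevalence bounds (46.9% and 54.1% for 372/736) after
  one-decimal rounding, while the Wald interval rounds the upper bound to
  54.2%. Both are available.
* **Count reconstruction** from printed percentages rounds to the nearest
  integer and verifies against printed margins, warning on mismatch.

The t-test from summary statistics uses the pooled form with
`df = n_a + n_b - 2` (Welch optional) and equals the raw-data t-test when
the summaries come from raw data — a tested identity. Note that published
t statistics for this design are not always recomputable from printed
rounded summaries (rounding of means/SDs upstream); recomputed values are
the tested ones.

## Numerical and design notes

* Quantiles use linear interpolation between order statistics (type 7);
  the convention is oracle-tested against a direct sort-based
  computation. SD uses the n−1 denominator.
* All generator randomness flows from a single integer seed; seeded
  helpers save and restore the caller's RNG state, and a fixed seed gives
  byte-identical pipeline artifacts (tested).
* Degenerate inputs fail loudly: all-missing subjects yield an invalid
  index (never division by zero), constant exposures and event-free
  cohorts are rejected before fitting, zero table margins are a
  chi-square error, and an empty valid-subject set is a summary error.
* Subjects lost to follow-up are excluded upstream by the cohort contract
  (the source design excluded its 5.5%); an analysis-time policy of
  censoring them at follow-up end can be emulated by setting their
  `time` to the follow-up length with `event = 0` before scoring.
* Problem sizes: the package's validation experiments use 200 replicates
  of n = 736 for calibration/recovery (chosen so Monte-Carlo standard
  errors are an order of magnitude below the quantities checked) and a
  single n = 50,000 simulation for the mortality calibration check.

## Limitations

The index is only as meaningful as its reference ranges; this package
takes them as configuration, performs no unit conversion and no
reference-range estimation. The exchangeable deficit model reproduces the
first two moments of the index but not its higher-order shape or tail
behaviour. The survival model is exponential-within-group by construction;
real cohorts need not satisfy proportional hazards, and no proportionality
diagnostics beyond visual cumulative-hazard inspection are provided.
Competing risks and time-varying covariates are out of scope.
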