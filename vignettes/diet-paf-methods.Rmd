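---
title: "Estimating diet-attributable cancer burden with dietpaf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating diet-attributable cancer burden with dietpaf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietpaf)
```

## The problem

Registry-based burden studies ask what share of incident cancer cases in a
population would not have occurred had everyone adhered to dietary
guidelines. dietpaf implements that comparative-risk-assessment pipeline for
categorical dietary exposures with continuous dose–response relative risks,
and ships, as worked fixtures, a Texas 2015 analysis of four colorectal
cancer risk factors: red meat and processed meat consumption (detrimental),
and insufficient fiber and calcium intake (protective intakes modelled as
deficits).

## The model

**From published RR to a per-unit slope.** Epidemiological meta-analyses
report relative risks per consumption increment `x` (e.g. RR = 1.28 per
100 g/day of red meat). On a log-linear dose–response scale the per-unit
slope is

    Rg = ln(RR) / x           (detrimental factor)
    Rg = ln(1 / RR) / x       (protective intake, risk per unit of deficit)

so `Rg` is risk per g/day (meats, fiber) or per mg/day (calcium). The
inverse map `RR = exp(±Rg·x)` is exact, which the tests check to 1e-12
relative error. Estimates whose confidence interval spans the null are
carried as point estimates with a metadata flag; no uncertainty is
propagated (the pipeline deliberately computes no confidence intervals,
as there is no agreed method for PAF intervals).

**Exposure categories.** Individual 24-hour-recall-style records are
summarised per stratum (survey age band × sex × race/ethnicity) into
ordered categories with survey-weight prevalences `p_x`, bounds, and
weighted median consumption. Each category's modelled dose is its distance
from the guideline reference level, clamped at zero:

    G_x = max(0, median_x − reference)    (detrimental)
    G_x = max(0, reference − median_x)    (protective)

Clamping makes compliant categories contribute nothing and, equivalently,
drops them from the sum — over-adherence (say, 35 g/day of fiber against a
28 g/day guideline) confers no modelled benefit beyond compliance.

**PAF.** With excess relative risk `ERR_x = exp(Rg·G_x) − 1`, the
population attributable fraction in a stratum is the Levin-type expression

    PAF = Σ p_x·ERR_x / (1 + Σ p_x·ERR_x).

**Latency and burden.** PAFs computed on survey age bands are paired with
registry counts ten years older (configurable offset): the band pairing
prefers an exact lower-edge match after shifting, the youngest incidence
band falls back to the youngest survey band, and an open-ended oldest
incidence band re-uses the oldest survey band (carry-forward; survey meat
data stop at 69). Excess cases are `PAF × count` per incidence band;
age-weighted stratum PAFs are total excess over total cases, so the
identity `excess = PAF × cases` survives aggregation. Factor-specific
excess cases are combined **additively** into an all-factors figure, as
burden studies of this design do; the complement-multiplicative
alternative `1 − Π(1 − PAF_f)` is available behind
`combine_factors(mode = "complement")` for sensitivity analysis, with the
caveat that it assumes independently acting exposures and is not how the
bundled tables were produced. Additive combination can exceed 1 for large
PAFs; the package warns rather than truncating. Finally, colorectal excess
is re-expressed against the all-cancer denominator (all invasive cancers
excluding basal- and squamous-cell skin carcinomas) to give the share of
total burden.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| red meat reference | 60 | g/day | guideline limit; intake ≤ 60 is compliant |
| processed meat reference | 0 | g/day | any consumption is non-compliant |
| fiber reference | 28 | g/day | guideline minimum |
| calcium reference | 1000 | mg/day | guideline minimum |
| latency offset | 10 | years | assumed exposure-to-diagnosis lag |
| category scheme | quantile, K = 5 | — | compliant class + quartiles of the non-compliant range |
| RR policy | sex-specific | — | men/women rows use their own RR; persons rows use the persons RR with pooled prevalence |
| combination | additive | — | excess cases sum over factors |

Consumption exactly at a reference level counts as compliant on both
comparator types. Pooled strata ("persons", all races) are built by pooling
records, never by averaging sub-stratum summaries — which is why race-
subgroup excess totals need not sum to the pooled total, a property of the
method rather than a rounding artefact.

## Category schemes

The source analyses of this design bin prevalence into 4–5 consumption
levels whose boundaries are rarely published. `scheme_quantile(k)` (default
`k = 5`) therefore makes category 1 the compliant class and splits the
non-compliant range into `k − 1` weighted quantile classes, so the
reference level is always a category boundary and the adherence prevalence
equals the non-compliant category mass. `scheme_fixed(breaks)` reproduces
any published fixed binning (half-open `[lower, upper)`, with a boundary at
a maximum-type reference kept on the compliant side). `scheme_distinct()`
is the full refinement — one category per distinct value — under which the
categorical PAF coincides with the enumerated individual-level
attributable fraction `(E[RR] − 1) / E[RR]`; algebraically `S = E[RR] − 1`
in that limit, and the test suite verifies agreement far below 0.1
percentage points on seeded populations of 10,000.

## The synthetic-data generator

`scenario_config()` defines a study in which every stage is checkable
offline. Consumption per factor and stratum is zero-inflated log-normal: a
point mass `π0` of never-consumers (essential for processed meat, whose
reference is zero) and a right-skewed positive part `LogNormal(meanlog,
sdlog)`, the shape of single-day recall intakes. Defaults (π0 = 0.15 and
median 60 g/day for red meat; π0 = 0.15, median 35 g/day for processed
meat; medians 16 g/day fiber and 850 mg/day calcium, no zero mass) were
chosen once so that the implied non-adherence fractions fall in the range
of the bundled prevalence table (roughly 50 / 85 / 90 / 60 % for red meat,
processed meat, fiber, calcium); the implied tail probabilities are
available in closed form via `true_nonadherence()` and are recovered from
simulated records within three binomial standard errors at n = 10,000.

Incidence counts are generated with a known ground truth: each person's
relative risk is `exp(Σ_f Rg_f · G_{f,i})`, expected colorectal cases per
cell are a baseline scaled by the population mean RR, rounded
deterministically by largest remainder (a Bernoulli person-level mode
exists for stochastic tests), and an all-cancer site group adds a
diet-independent count. Pooled marginals are sums of concrete cells, so
marginal validation passes by construction. The generator emulates the
*structure* of survey-plus-registry inputs — not usual-intake measurement
error, within-person recall variance, survey design effects, or correlated
multi-factor diets (factors are drawn independently). Passing tests
therefore demonstrate estimator correctness under the stated mixture
model, not unbiasedness on real recall data.

## Numerical choices

- **Weighted median**: smallest value whose cumulative weight fraction
  reaches 1/2; when a value lands exactly on 1/2 (even unit-weight
  samples) the midpoint with the next value is taken, so unit weights
  reproduce `stats::median()`. Deterministic under permutation.
- **Quantile edges** use the lower rule (no interpolation), keeping bin
  edges at observed values and binning reproducible.
- **Rounding** happens only at report time: PAF percentages to one decimal
  half-up, excess cases summed at full precision then rounded to the
  nearest integer — matching the "totals may not sum manually" convention
  of published tables. `round_half_up()` is exported because R's `round()`
  rounds half to even.
- **Degenerate inputs**: empty strata raise errors (never silent zeros);
  zero-count cells yield zero excess with the PAF still reported; missing
  count cells are errors, not implicit zeros.
- **Determinism**: all randomness flows from the scenario seed; pipeline
  outputs contain no timestamps, so reruns on identical inputs are
  byte-identical.

## Problem sizes in the test suite

Estimator-validation checks (oracle equivalence, prevalence recovery) use
one pooled stratum of 10,000 simulated persons; end-to-end pipeline checks
use 40 persons per stratum cell across six survey bands, two sexes and two
race groups — sizes at which every property asserted is already stable.

## Known limitations

- PAFs carry no uncertainty intervals; sampling error in prevalence and RR
  estimates is not propagated.
- Additive multi-factor combination ignores overlap between exposures and
  can exceed the denominator in extreme configurations (warned, not
  truncated).
- The exposure module consumes individual-level records; survey replicate
  weights and usual-intake correction are out of scope (weights enter only
  as per-record numbers).
- Exact reproduction of the bundled Table-3-style PAFs from raw inputs is
  not possible because the original category boundaries, category medians,
  age-specific prevalences and stratified colorectal counts were not
  published; the shipped fixtures carry the printed values, and the
  package's acceptance checks verify the arithmetic identities those
  values satisfy plus the estimator properties on synthetic data.
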