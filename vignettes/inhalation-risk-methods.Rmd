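---
title: "Probabilistic inhalation risk assessment: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic inhalation risk assessment: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inhalrisk)
```

## The problem

Workers in carpet-factory finishing shops inhale volatile organics released
from styrene–butadiene glue, chiefly 1,3-butadiene (BD, an IARC group 1
carcinogen) and styrene (ST, group 2A). Occupational risk assessment asks two
questions: what is the incremental lifetime probability of cancer implied by
the measured breathing-zone concentrations, and is the non-cancer hazard
acceptable? `inhalrisk` answers both with the standard USEPA inhalation
methodology, propagates the uncertainty in the exposure factors by Monte
Carlo, and attributes the output variance back to its inputs.

## The dose and risk model

Two dose metrics are computed from a common factor set
$(C, IR, ED, EF, BW, ET)$:

$$\mathrm{CDI} = \frac{C \cdot IR \cdot ED \cdot EF}{BW \cdot AT_{days}},
\qquad
\mathrm{EC} = \frac{C \cdot ET \cdot ED \cdot EF}{AT_{hours}},$$

with $C$ the shift concentration (mg/m³), $IR$ the inhalation rate (m³/day),
$ED$ the exposure duration (years), $EF$ the exposure frequency (days/year),
$BW$ body weight (kg) and $ET$ exposure time (hours/day). Risk indices are

$$\mathrm{CR} = \mathrm{CDI} \times SF, \qquad
\mathrm{HQ} = \mathrm{EC} / \mathrm{RfC},$$

with $SF$ the inhalation cancer slope factor ((mg/kg/day)⁻¹) and RfC the
reference concentration (mg/m³). CR values above 10⁻⁶ and HQ values at or
above 1 are treated as unacceptable; the boundary conventions are CR ≤ 10⁻⁶
acceptable, HQ < 1 acceptable.

Three modelling choices deserve explanation, because the source material for
the bundled preset is internally ambiguous:

* **Two averaging times.** The intake dose (CDI) averages over days while
  the concentration metric (EC) averages over hours. The preset fixes
  `AT_days = 9000` and `AT_hours = 9000 × 24 = 216000`. This dual convention
  is the unique one under which the deterministic core reproduces both the
  preset's cancer-risk and hazard-quotient levels, and both fields are
  explicit arguments of `exposure_factors()` rather than a hidden constant.
* **Slope factor for BD.** Published values for the BD inhalation slope
  factor differ by an order of magnitude (0.6 vs 6 (mg/kg/day)⁻¹). The
  preset uses 0.6, the value consistent with the bundled study conditions;
  it is an ordinary field of `tox_profile()` and can be overridden.
* **CDI for both analytes.** Cancer risk is computed as CDI × SF for BD and
  ST alike (rather than an inhalation-unit-risk route), because a slope
  factor is available for both compounds and this keeps the two assessments
  methodologically uniform.

## Uncertainty propagation

`mc_propagate()` draws every stochastic factor from a declared
`dist_spec()`, fills the rest from a fixed factor set, and evaluates the
four equations elementwise — the Monte Carlo engine reuses the same scalar
functions as the deterministic core, so an all-`point` specification
collapses to the deterministic answer exactly (this is asserted in the test
suite). Sampling is plain Monte Carlo with 10,000 iterations by default;
at that size stratification (Latin hypercube) buys nothing for a
five-factor product model.

The replication preset (`replication_specs()`) encodes the bundled study
conditions:

| factor | family | parameters | truncation |
|---|---|---|---|
| EF | normal | 301.06 ± 12.87 days/yr | (0, 366) |
| ED | normal | 29.66 ± 1.60 yr | (0, ∞) |
| BW | normal | 74.45 ± 13.68 kg | (0, ∞) |
| ET | normal | 10.81 ± 1.89 h/day | (0, 24) |
| C  | point at the measured mean, or lognormal | mean 0.039 (BD) / 12.108 (ST) mg/m³, GSD 2.5 | — |

Normal families fit questionnaire-style mean ± SD summaries; the truncation
bounds are physical ranges, not tuning knobs (all bounds sit more than five
standard deviations from the mean, so they are guards against impossible
draws, not distributional reshaping). Truncation is enforced by rejection
resampling with a budget of 1000 passes — unbiased, and effectively free at
these mild truncations; a truncation region retaining essentially no mass
exhausts the budget and raises an error rather than looping forever.

The lognormal family is deliberately parameterised by the *arithmetic* mean
and the geometric standard deviation: occupational-hygiene studies report
arithmetic shift means, and the moment-matched log-scale parameters
($\sigma = \ln g$, $\mu = \ln m - \sigma^2/2$) preserve that mean under
simulation. GSD defaults to 2.5 — a middle value of the 2–3 range typical
for within-workplace shift concentration data, and strong enough skew to
span several orders of magnitude in the risk output, as wide occupational
risk ranges require. Because the underlying study publishes only mean
concentrations, any GSD is an assumption; it is a first-class argument
everywhere it appears.

Reproducibility contract: a fixed master seed yields bit-identical draws and
summaries. Each analyte's stream is seeded with a sub-seed derived
deterministically from the master seed and the analyte name
(`derive_subseed()`), so adding, removing or reordering analytes never
perturbs another analyte's results.

Note one systematic effect the deterministic core misses: with $BW$ in the
denominator, $E[1/BW] > 1/E[BW]$ (Jensen's inequality), so the Monte Carlo
mean CR sits a few percent above the CR at the mean body weight. This is
not an error — it is the reason probabilistic means differ from plug-in
point estimates — and it is asserted as a property in the test suite.

## Sensitivity analysis

`contribution_to_variance()` implements the signed contribution-to-variance
convention of commercial Monte Carlo risk tools: the Spearman rank
correlation $r_i$ of each input with the output, normalised as
$\mathrm{sign}(r_i) \cdot 100 \cdot r_i^2 / \sum_j r_j^2$. Absolute
contributions sum to 100%. Constant inputs receive exactly 0 and are
excluded from the normalisation; ties in the ranking break alphabetically
for determinism. Because the statistic is rank-based it is invariant under
any strictly increasing transformation of the output. A
standardised-rank-regression variant (`method = "srrc"`) is provided for
comparison; the two coincide for independent inputs.

The exact percentage attributed to the concentration depends entirely on
the assumed concentration spread (the GSD), which the underlying study does
not publish. The package therefore treats sensitivity output as
*structural* — which factor ranks first, which signs are negative — rather
than as numerically reproducible targets. Under the lognormal-C preset the
concentration ranks first for CR and HQ of both analytes and body weight's
CR contribution is negative, matching the qualitative field expectation.

## The synthetic cohort

`generate_cohort()` simulates the study design end to end: 75 workers with
questionnaire factors drawn from the preset distributions, three
consecutive sorbent-tube samples per worker and analyte with uniform
durations on [70, 120] minutes at 0.2 L/min, desorption recoveries of 0.87
(BD) and 0.89 (ST), and 22 field blanks. Sorbent masses are constructed by
inverting the reduction formula (mass = C·recovery·flow·duration + blank),
so `concentration_from_record()` recovers the generating concentration
exactly when measurement noise is off — separating inversion correctness
from noise behaviour, which is available as an optional multiplicative
lognormal mass-noise knob. Blank masses are fixed at 0.5% of the analyte's
typical front mass, consistent with field blanks below 1% of sample values.

What the generator does *not* emulate: between-factory differences (the
emulated study pools two factories), seasonal variation (a single winter
campaign), within-worker day-to-day autocorrelation, and analytical
(GC–MS) error structure. Passing parameter-recovery tests therefore show
that the pipeline is an unbiased inverse of its own generative model — not
that the model captures every feature of real sampling campaigns.

## Sample processing choices

Blank subtraction floors the net mass at zero (a blank exceeding the sample
mass is noise, not negative air). Within-shift averaging is
duration-weighted by default — consecutive samples of 70–120 minutes should
contribute in proportion to the air volume they represent — with the plain
arithmetic mean behind `weighted = FALSE`. The breakthrough criterion
defaults to rear mass exceeding 10% of front mass, the conventional
rear-section check, and is configurable since studies rarely publish their
exact cutoff.

## Occupational-limit adjustment

For shifts longer than 8 h/day or 40 h/week, `brief_scala_daily()` and
`brief_scala_weekly()` implement the Brief & Scala reduction
$(8/h) \cdot (24-h)/16$ and $(40/h) \cdot (168-h)/128$, applied to a limit
via `adjust_oel()`. The daily form is the default because the bundled
cohort reports exposure time in hours/day (mean 10.81 h/day, giving a
factor of 0.61). Gas conversions use a configurable molar volume, default
24.45 L/mol (25 °C, 1 atm); regulatory tables that assume other reference
conditions can be matched by changing the `gas_spec()` field.

## Problem sizes and numerical checks

The test suite runs Monte Carlo at 2,000–20,000 iterations and
law-of-large-number checks at 10⁵ draws, sizes at which the asserted
3-standard-error bands have essentially full power while the whole suite
completes in well under two minutes. Statistical assertions use 3-SE (or
binomial-proportion) bands derived from the distribution at hand, never
hand-picked tolerances. Known limitations: no input correlations (copulas)
or two-dimensional variability/uncertainty separation; extreme order
statistics (min/max of 10,000 draws) are reported but are inherently
unstable summaries and are not asserted against.
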