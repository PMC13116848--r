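---
title: "Methods: 90-day stroke episodes, ECPS and funnel-based provider comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 90-day stroke episodes, ECPS and funnel-based provider comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stroke90)
```

`stroke90` turns raw administrative claims into a comparative analysis of
ischemic-stroke care: 90-day episode costs from the payer perspective,
crude and age-standardized 90-day mortality, the effective cost per
survivor (ECPS), and funnel plots with exact control limits for comparing
providers. This vignette is the package's account of the methodology: the
operational definitions, the statistical models, the tunable parameters,
and the design decisions taken where the underlying methodology leaves
room.

## Cohort operationalization

The unit of analysis is the *patient episode*. Its rules, applied by
`select_index_events()`:

* **Index event.** A patient's earliest hospitalization with main
  diagnosis ICD-10 I63 (any subcode, prefix match) inside the study
  window. The admission day is day 1 of the episode and anchors all
  windows. Same-day ties between two I63 claims are broken by the lower
  claim id — a deterministic, arbitrary rule; the tied claim is then
  counted as a second same-day hospitalization rather than discarded,
  because claims are indivisible payer units and deduplication would
  silently delete reimbursed money.
* **Age.** Patients younger than 18 at the index admission are excluded.
  Age is computed as `floor((index_date - birth_date) / 365.25)` years; the
  365.25-day convention can differ from calendar-exact age around a
  birthday, but the same convention is used consistently in the generator
  and the builder.
* **Follow-up.** Episodes need the full 90 days of observation:
  index admissions with `index_date + 90 > study_end` are excluded
  (reason `LATE_INDEX`).
* **Attribution.** Every episode belongs to the provider that reported
  the index hospitalization, regardless of where later care happened.
  Providers with fewer than `min_volume` (default 30) index patients are
  removed entirely. The filter runs once, on pre-filter counts — it is not
  iterated, so removing a small provider can not knock another provider
  below the threshold retroactively.
* **Intervention.** `thrombectomy` if the index claim carries the
  thrombectomy flag, else `thrombolysis` if it carries the thrombolysis
  flag, else `other` (no reperfusion therapy). The hierarchy makes
  bridging therapy (both flags) count as thrombectomy, so the three
  labels partition any cohort.

All exclusions are logged with machine-readable reasons (`UNDER18`,
`LATE_INDEX`, `LOW_VOLUME`, `BAD_RECORD`), and the pipeline manifest
reconciles cohort size = index events − low-volume exclusions.

## Episode costing and mortality

`build_episodes()` aggregates three payer-cost components over the
half-open window `[index_date, index_date + 90)`:

* `cost_primary`: the index claim's cost;
* `cost_other_hosp`: all other hospitalization claims whose *admission*
  falls in the window, regardless of diagnosis. The full claim cost is
  counted even when discharge falls after day 90 — claims are not
  prorated;
* `cost_outpatient`: outpatient claims with service date in the window.

`cost_total` is their exact sum, an identity asserted in the tests rather
than a rounding-tolerant comparison. The half-open convention is used for
*every* window decision in the package: a hospitalization admitted on day
89 counts, one admitted on day 90 does not; a death at offset 90 is a
survivor, a death on the index day (offset 0) is a death. Choosing one
convention everywhere beats matching any single ambiguous phrasing.

## Indirect age standardization

Mortality differs strongly by age, and providers differ in case mix, so
provider comparison uses indirect standardization against the whole
analyzed cohort as the reference population (`fit_reference()`):

* The default estimator tabulates the 90-day death rate `r_a` within
  half-open age bands, default `[18,45), [45,55), [55,65), [65,75),
  [75,85), [85,Inf)`. The bands are configurable because the referenced
  quality-indicator methodology prescribes the approach, not the strata;
  the default is a declared assumption, not a reconstruction of any
  specific deployment. Empty bands fall back to the overall rate.
* Each patient's expected death probability is the rate of their band;
  a group's expected deaths are `E = sum(p_i)`, and its standardized rate
  is `(O / E) × r̄` with `O` observed deaths and `r̄` the reference crude
  rate. If a group's age mix equals the reference mix, the standardized
  rate equals the crude rate exactly.
* Rates above 1 are possible for tiny groups with large `O/E`; they are
  deliberately not truncated (the funnel treats them as ratios), only
  warned about. Groups with `E = 0` have no defined rate: a single-group
  call errors, a grouped call warns and reports `NA` so the remaining
  providers stay usable.
* A logistic alternative (`method = "logistic"`, death ~ age) is offered
  for users who prefer a smooth risk curve, matching common
  quality-indicator practice; stratum rates remain the default for
  transparency.

Only age is adjusted for. Administrative claims carry no stroke severity
or functional status, and adjusting for treatment would adjust away the
very differences under study — standardized rates here are descriptive,
not causal.

## ECPS — effective cost per survivor

For a group of N patients with total 90-day costs `C_1..C_N` of whom `D`
died within 90 days,

ECPS = (Σ C_i) / (N − D).

It equals the mean cost when nobody dies, grows strictly with `D`, and is
undefined when nobody survives (the package raises an explicit
"no survivors" error rather than returning infinity). `D` is the *crude*
death count — that is what the definition says — even though published
tables typically print standardized mortality next to ECPS; reconstructing
ECPS from a printed standardized rate therefore carries a sub-percent
discrepancy, which is exactly the tolerance the reproduction test uses.
ECPS is a ratio indicator with non-trivial sampling behaviour; the package
reports it as a descriptive, supporting indicator and deliberately
provides no confidence interval for it.

## Funnel plots

`proportion_limits()`, `ratio_limits()` and `mean_limits()` compute
Spiegelhalter-style control limits around a common target against a
precision parameter, at two-sided levels 0.05 and 0.002 (the conventional
95% and 99.8% bands):

* **Proportions** (crude mortality vs unit size): exact binomial limits
  with continuity interpolation. For tail target `p`, with `F` the
  Binomial(n, θ₀) CDF, `r` the smallest integer with `F(r) ≥ p`, and
  `λ = (F(r) − p) / (F(r) − F(r−1))`, the limit is `(r − λ)/n`. The
  interpolation makes achieved coverage approximately nominal
  (95.2% / 99.80% at n = 200, θ₀ = 0.15) instead of conservative.
  A consequence of interpolating on the count scale is that the two
  limits at θ₀ = 0.5 satisfy `lower + upper = (n−1)/n` — symmetric up to
  the 1/n discreteness offset, not exactly about 0.5. The alternative
  (mirroring the upper limit) restores exact symmetry but pushes inner-band
  coverage to ≈96.3%; nominal coverage was judged the more important
  property and the package follows the published interpolation.
* **Standardized ratios** (O/E vs expected deaths E): the same
  interpolation applied to the Poisson(E) CDF, divided by E, around
  target 1. Limits are computed against `E` as the precision parameter,
  per the cited methodology; plotting against patient count instead is a
  rendering choice left to the caller.
* **Means** (mean 90-day cost vs unit size): normal-theory limits
  `μ₀ ± z₁₋α/₂ · σ₀/√n`, with `μ₀` the cohort grand mean and `σ₀` the
  pooled within-provider SD (`pooled_sd()`). Cost distributions are
  heavily right-skewed, so a log-scale variant is provided
  (`log_scale = TRUE`: limits computed on log costs and exponentiated);
  raw-scale limits are the default since provider *means* at typical
  volumes are already fairly normal.

Limits are clamped to the indicator's support (proportions to [0, 1],
ratios to ≥ 0). Band width is non-increasing in precision wherever the
lower limit is off the zero boundary; below that, the band is effectively
one-sided and the width inherits the upper limit's discreteness wiggles —
the property tests assert monotonicity exactly on the unclamped region.
No overdispersion inflation is applied by default — the basic in-control
scenarios. For settings with genuine between-provider heterogeneity,
`dispersion_phi()` estimates a multiplicative overdispersion factor from
winsorized z-scores (winsorized so true outliers do not inflate it), and
passing `phi > 1` to the limit constructors widens the bands by
`sqrt(phi)`; for the discrete families this switches to the
normal approximation with inflated standard error, as exact
binomial/Poisson quantiles have no overdispersed analogue.
`flag_units()` recomputes limits exactly at each
unit's own precision (the grid is purely cosmetic), classifies points as
`inside` / `outside_95` / `outside_998` with a direction, and counts
points exactly on a limit as inside (conservative flagging).

## The synthetic-claims generator

Real payer claims of this kind are not shareable, so `generate_world()`
produces synthetic tables with the statistical structure the analysis
assumes, and its defaults *are* the study conditions:

* cohort size 23,568; age ~ Normal(70.6, 12.4) truncated at 18; 47%
  female;
* a provider network of 13 comprehensive stroke centres, 32 primary
  stroke centres, 40 stroke-ready hospitals and 8 other providers, with
  expected volumes proportional to the published provider-type shares
  (35/46/17/1.9%);
* intervention mix conditional on provider type, reproducing both the
  overall 5.5/17/77% thrombectomy/thrombolysis/other split and the
  concentration of reperfusion therapy in stroke centres (88% of
  thrombectomies at comprehensive centres);
* log-normal costs per intervention and component, with location/scale
  solved from the published median/mean pairs (a log-normal's mean/median
  ratio is `exp(σ²/2)`, so both are matched exactly); secondary
  hospitalizations occur with probability 0.35, consistent with a zero
  median for that component; 40% of thrombectomy claims also carry the
  thrombolysis flag to exercise the bridging-therapy hierarchy;
* 90-day death from a logistic model in age (+0.7 log-odds per decade, a
  typical administrative-data gradient) with per-intervention offsets;
  the intercept and offsets are solved numerically so the *age-integrated*
  marginal rates are 29.3/14.9/14.4% — calibrating at the mean age instead
  would understate the marginal rate because the risk curve is convex in
  this range;
* deliberate boundary traffic: deaths and claims placed both inside and
  outside the 90-day window, plus injected edge cases (under-18
  admissions, repeated I63 admissions, admissions with fewer than 90
  follow-up days, low-volume providers) in configurable counts.

`calibration_report()` recomputes the realized structure (using exact
continuous ages from the birth dates; whole-year episode ages would bias
the mean down by about half a year) and compares realized mortality with
the model's implied rate.

What the generator does *not* emulate: diagnosis coding noise, insurer
identity, tariff/reimbursement logic, transfers within a single stay
(drip-and-ship pathways), regional geography, or any correlation between
cost and survival beyond what intervention and age induce. Passing tests
on synthetic data therefore demonstrate that the *pipeline arithmetic and
statistical machinery* are correct under the assumed structure — they say
nothing about coding quality or case-mix effects in any real claims feed.

## Numerical and interface choices

* Quantiles/IQRs use linear interpolation between order statistics
  (R type 7), stated and tested because published tables rarely say which
  quantile rule they used.
* Display formatting rounds costs to whole EUR and percentages to one
  decimal; shares below 0.1% print as "<0.1%"; internal values keep full
  precision.
* All tabular I/O is CSV with ISO-8601 dates; costs are generated in EUR
  and a single `currency_factor` rescales koruna-denominated (or other)
  inputs — no historical exchange-rate handling.
* A single-patient group reports SD 0 rather than NA so summary tables
  stay numeric.
* Every stochastic step flows from one integer seed; identical
  configuration and seed reproduce the tables exactly.

## Problem sizes in the test suite

The suite exercises the generator at 20,000 patients for the
population-structure checks (binomial/normal sampling error at that size
makes the ±0.2-year and ±1-point tolerances meaningful), 2000 simulated
providers for funnel coverage, 500 providers × 200 patients for the
standardization unbiasedness check, and exhaustive CDF enumeration up to
n = E = 50 for the exact-limit oracle; smaller worlds (150–2500 patients,
with a proportionally scaled-down provider network so volumes stay above
the minimum-volume threshold) cover the remaining behaviour. These sizes
are the package's choice of a good precision/runtime trade-off.

## Known limitations

* Only age enters risk adjustment; severity, comorbidity and sex do not.
* ECPS has no interval estimate.
* The volume filter and episode windows implement one documented
  convention each; alternative readings (iterative filtering, closed
  windows) are not options.
* The generator draws age independently of provider type, so synthetic
  case-mix differences between provider types come entirely from the
  intervention mix.
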