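---
title: "Methods: a cohort Markov cost-utility model for prostate radiotherapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a cohort Markov cost-utility model for prostate radiotherapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radcua)
```

## The decision problem

Six radiation treatment modalities are in routine or trial use for
intermediate-risk prostate cancer in Canadian centres: conventionally
fractionated IMRT (78 Gy / 39 fractions), hypofractionated IMRT (60 Gy /
20 fractions), HDR brachytherapy combined with IMRT, HDR brachytherapy
monotherapy (two fractions in one implant), LDR brachytherapy monotherapy
(one implant), and SBRT (five fractions). Long-term survival and
biochemical control are essentially equivalent across them, so the choice
is driven by toxicity profiles and by cost — which differ substantially,
mainly through fractionation. radcua implements the standard
health-economic machinery for that comparison from a provincial health
system perspective: expected 20-year discounted cost and quality-adjusted
life years (QALYs) per modality, and a sequential incremental cost-utility
ratio (ICUR) analysis.

## The cohort model

A cohort of men aged 60 enters the model immediately after the index
treatment and is propagated in 6-month cycles over a 20-year horizon
(40 cycles) through seven health states: healthy (long-term management),
acute GU toxicity, acute GI toxicity, late GU toxicity, late GI toxicity,
recurrence, and dead.

* **Acute toxicity** is defined as occurring within six months of
  treatment, so the acute states are reachable only during the first cycle
  and last exactly one cycle, after which survivors return to healthy.
* **Late toxicity** (beyond six months) is entered from healthy at a
  per-cycle probability and is chronic by default
  (`model_config(late_resolution_prob = 0)`); a per-cycle resolution
  probability can be configured.
* **Recurrence** aggregates biochemical and clinical relapse into one
  state entered from healthy (and, by default, from the late states) at a
  per-cycle probability; entry triggers a one-time salvage-treatment cost,
  identical across index modalities, followed by a per-cycle management
  cost. The state persists until death. The model does not distinguish
  biochemical from local/regional/distant recurrence: the published state
  diagram's exact arrows are not specified in the text we work from, and a
  single aggregated state is the least-assumption reading; this is a known
  structural simplification.
* **Mortality** is age-indexed background mortality from a life table,
  converted to the cycle length by `1 - (1 - q)^{0.5}` (constant hazard
  within the year), multiplied by a per-modality relative-risk factor
  (default 1, since survival is assumed non-differential across
  modalities) and, in the recurrence row, by a shared
  `recurrence_mortality_rr` multiplier (default 1; the calibrated
  specification uses 2 to reflect the mortality of relapsed disease).

Competing risks within a row are combined as independent event indicators
with exhaustive-outcome allocation: death takes precedence over all
events, and simultaneous non-fatal events are assigned by a fixed severity
priority (recurrence, then GU, then GI toxicity). This convention makes
every row exactly testable against a `2^n` enumeration oracle and
guarantees row-stochasticity without renormalisation. Rows are checked to
sum to 1 within 1e-12 and occupancy to be conserved within 1e-9.

## Outcome accumulation

State utilities sit on a relative dis-utility scale: healthy after
treatment is worth 1, death 0, and every other state `1 - disutility`
(clamped to [0, 1]), with dis-utilities identical across modalities so
that utility differences are driven entirely by event risks. Dis-utility
defaults are ranked acute < late < recurrence, reflecting severity.

Per cycle `k`, QALYs accrue as
`0.5 * sum_s u(s) * (occ_{k-1}(s) + occ_k(s))/2 * d(k)` with
`d(k) = 1.015^{-(k-0.5)/2}`: trapezoid averaging of the boundary
occupancies combined with mid-cycle discounting is the half-cycle
correction used throughout (the alternative convention — end-of-cycle
occupancy with a half-cycle shift — differs only in the fourth decimal at
this cycle length; one had to be fixed and documented, and
`model_config(half_cycle_correction = FALSE)` switches both off
together). State costs accrue identically from 6-month state management
costs; the salvage cost applies to the recurrence entry flow at its cycle;
the index treatment cost is applied at time zero and is therefore not
discounted (whether the source analysis discounted it is not stated; at
`t = 0` the two conventions coincide). The annual discount rate of 1.5%
applies to both costs and QALYs.

## Index-treatment costing

The index cost of a course decomposes as supplies per patient, a
per-fraction machine operating cost
`(oper + amort + maint) * 1.2 / annual_fractions` (the 1.2 is overhead)
multiplied by the regimen's fraction count, an hourly duration-priced
component for brachytherapy theatre time, course-level staffing, and the
physician fee for service. "Per number of fractions" is read as division
by the machine's annual fraction throughput, so that a 39-fraction course
costs 39 times the per-fraction machine cost — the annualised-machine
reading that makes longer schedules costlier, as the published totals
show for cfIMRT. Brachytherapy can mix the fraction-based and
duration-based components freely per modality (set `procedure_hours = 0`
to disable the latter); the source costing method for procedure duration
gives no numbers, so the mixture is configuration. All amounts are 2018
Canadian dollars; no inflation adjustment is applied.

## Parameter uncertainty and the PSA

Each uncertain parameter is a `(family, mean, se)` triple: beta for
probabilities and dis-utilities, gamma for costs (the convention of the
Canadian guidelines; the source does not state families), `fixed` to pin
a value. Families are fitted by the method of moments
(`fit_distribution()`), with infeasible beta moments rejected rather than
truncated. The PSA draws shared parameters (event/management costs,
salvage cost, dis-utilities) once per iteration and reuses them across all
six arms — common random numbers, so that within an iteration
between-modality differences come only from event risks and index costs —
then records one (cost, QALY) pair per arm per iteration. Draw order is
fixed, so a seed fully determines the result. Means with empirical
2.5/97.5 percentile intervals summarise the draws; the source's "95%
uncertainty variance from the mean" phrasing is nonstandard and is
implemented as percentile intervals.

## Sequential ICUR analysis, CEAC, CE plane

`icur_frontier()` implements the four-step sequential procedure: rank by
cost; exclude strategies at least as costly as and less effective than
another (strict dominance); compute ICURs between successive survivors and
exclude any whose ICUR does not improve on the next more effective
option's (extended dominance — such a strategy is never optimal at any
willingness-to-pay); recompute ICURs among survivors. Exact cost ties are
broken by higher QALYs, then name. The implementation is validated against
a net-monetary-benefit argmax oracle on a dense WTP grid: excluded
strategies never uniquely maximise `wtp * qaly - cost` anywhere, and every
frontier strategy wins on a nonempty interval. The CEAC is the standard
per-iteration NMB-argmax win fraction over a WTP grid (default $0-200,000
in $500 steps), with exact ties split equally; the source gives no formula
for its acceptability curve, and this is the field's standard
operationalisation.

## Synthetic inputs and calibration

The appendix tables of the source analysis (per-modality toxicity and
recurrence inputs, costing magnitudes) are not published, so the package
generates its own inputs two ways.

**`default_spec(seed)`** emulates the structure of those tables: distinct
per-modality probability means drawn from clinically plausible ranges
(acute toxicity 5-45%, per-cycle late toxicity 0.2-1%, per-cycle
recurrence 0.4-2%), index costs built from the micro-costing calculator
with illustrative machine magnitudes (a ~$1.9M/year IMRT linac delivering
8,000 fractions, afterloader and seed costs for brachytherapy), and
post-treatment costs given deliberately wide gamma uncertainty
(CV = 0.5 ≥ 0.3) because management costs vary widely across health
systems. These defaults were chosen once as a realistic scenario and are
not tuned to any output.

**`calibrated_reference_spec()`** inverts the published outputs instead:
it solves for a zero-variance input set whose deterministic run reproduces
each modality's published mean total cost (within 1%) and QALYs (within
0.02). The QALY targets are hit by 1-D root finding on the per-cycle
recurrence probability (QALYs are monotone decreasing in it) after fixing
a common mortality relative risk so the least-toxic arm with zero
recurrence sits 0.10 QALYs above the highest target; the cost targets are
then hit exactly by assigning `index_cost = target - downstream cost`,
which is exact because the index cost affects cost only — a triangular
system solved in one pass. Calibration residuals are stored on the object
and re-checkable with `calibration_residuals()`; on the shipped targets
they are at machine precision. `add_default_uncertainty()` re-attaches
variances (beta CV 0.2 on probabilities, gamma CV 0.4 on management
costs, CV 0.1 on the micro-costed index costs) for probabilistic analysis
around the calibrated means.

The synthetic life table is Gompertz, `q(age) = min(1, a e^{b age})` with
defaults `a = 3e-5`, `b = 0.085` — about 0.5% annual mortality at 60 and
2.7% at 80, a realistic adult male shape in two parameters.

What passing the calibrated-fixture checks shows is that the *pipeline*
(engine, discounting, dominance logic) reproduces the published totals and
classification when fed inputs consistent with them; it cannot show that
the unpublished inputs themselves are recovered — many input sets map to
the same outputs, and the recurrence-driven calibration is one such set.
Conclusions about real toxicity profiles are outside what these synthetic
inputs support.

## Problem sizes and numerical choices

The shipped analysis scripts and tests run the PSA at 2,000 iterations
(the published analysis used 20,000): per-modality Monte Carlo standard
errors on the means are already below ~$30 and ~0.002 QALYs there, an
order of magnitude under the differences being compared; `n_iter` is a
parameter throughout. Engine checks run against an individual-level
microsimulation oracle at 2×10^5 patients (agreement within 3 binomial
standard errors per state) and a closed-form geometric-series oracle for
the discounted always-healthy case (1e-10). Root finding uses
`stats::uniroot` to 1e-12 on the probability scale. Degenerate inputs are
handled explicitly: zero-variance specs collapse the PSA to the
deterministic result exactly; probability-1 death flushes the cohort in
one cycle; infeasible sampled probabilities trigger a logged resample.

## Known limitations

Individual-level heterogeneity (age distribution at entry), tunnel states
for time since recurrence, a cause-specific/all-cause mortality split,
direct acute→late toxicity pathways, one-way sensitivity analyses and
value-of-information measures are all out of scope. The relative
dis-utility scale means QALY totals are comparable across these six
modalities but not against other disease areas. The published analysis
lists four modalities as dominated in its table while its text calls
three dominated; applying the stated algorithm to the published numbers
yields four (HDR-b, hfIMRT, HDR-IMRT, cfIMRT), and that is what the
package reports.

## A worked run

```{r example, eval = FALSE}
spec <- calibrated_reference_spec()
det <- deterministic_run(spec)
icur_frontier(data.frame(name = det$name, cost = det$cost, qaly = det$qaly))

psa <- run_psa(add_default_uncertainty(spec), n_iter = 2000, seed = 1)
summarize_psa(psa)
ceac(psa, wtp_grid = c(5000, 50000))
```

See `analysis/01_make_inputs.R` through `analysis/04_cea.R` in the source
repository for the full staged workflow with written outputs.
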