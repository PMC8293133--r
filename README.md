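# radcua

Cost–utility analysis of six radiation treatment modalities for
intermediate-risk prostate cancer, built around a cohort Markov
state-transition model.

Radiation options for intermediate-risk prostate cancer — conventionally
fractionated IMRT (39 fractions), hypofractionated IMRT (20), HDR
brachytherapy + IMRT, HDR brachytherapy monotherapy (2 fractions, one
implant), LDR brachytherapy (one implant) and SBRT (5 fractions) — deliver
near-equivalent survival, so the comparison that matters to a provincial
payer is cost versus quality of life. radcua is for health-economics and
radiation-oncology researchers who want that comparison as tested,
reusable code rather than a spreadsheet.

## The model

A cohort of men aged 60 enters at treatment completion and moves through
seven states — healthy, acute GU/GI toxicity (first 6-month cycle only),
late GU/GI toxicity, recurrence (with a one-time salvage cost on entry),
dead — in 6-month cycles over a 20-year horizon. For modality *m* with
state occupancies *x_k*, transition matrices *P_k* (background mortality
from a life table, converted to the cycle and scaled by a relative risk),
discounted at rate *r* = 1.5%/year with half-cycle correction:

    x_k = x_{k-1} P_k
    QALY_m = Σ_k 0.5 · u'(x_{k-1}+x_k)/2 · (1+r)^{-(k-½)/2}
    Cost_m = c_index + Σ_k [c'(x_{k-1}+x_k)/2 + c_salv · flow_k(rec)] · (1+r)^{-(k-½)/2}

with utilities *u* = 1 − dis-utility (healthy 1, dead 0). Strategies are
then compared by the sequential incremental cost–utility ratio (ICUR)
procedure — rank by cost, drop strictly dominated strategies, drop
extended-dominated ones (ICUR not below the next more effective option's),
recompute ICUR = ΔCost/ΔQALY along the frontier — plus probabilistic
sensitivity analysis (beta/gamma parameter distributions, common random
numbers for shared parameters), cost-effectiveness acceptability curves
(per-iteration net-monetary-benefit argmax) and the incremental
cost-effectiveness plane. An index-treatment micro-costing calculator
builds per-course costs from supplies, per-fraction machine cost
`(oper + amort + maint) × 1.2 / annual_fractions`, procedure hours,
staffing and physician fees (2018 CAD).

Because the underlying study's appendix inputs are unpublished, the
package ships a seeded plausible input generator (`default_spec()`) and a
zero-variance specification calibrated so the deterministic run reproduces
the published per-modality cost/QALY averages
(`calibrated_reference_spec()`; see the methods vignette for the
calibration and its limits).

## Worked example

```r
library(radcua)
spec <- calibrated_reference_spec()
det  <- deterministic_run(spec)
icur_frontier(data.frame(name = det$name, cost = det$cost, qaly = det$qaly))
#>   name     cost  qaly  status    dominated_by ... icur
#> 1 LDR-b     8940 11.00 reference <NA>             NA
#> 2 HDR-b     9187 10.63 dominated LDR-b            NA
#> 3 SBRT     10048 11.38 frontier  <NA>             2915.79
#> 4 hfIMRT   14332 10.86 dominated LDR-b            NA
#> 5 HDR-IMRT 16939  9.95 dominated LDR-b            NA
#> 6 cfIMRT   19903 10.59 dominated LDR-b            NA
```

LDR-b is the least costly strategy (the reference); four modalities are
dominated (cheaper, more effective alternatives exist); SBRT is the only
frontier alternative, buying 0.38 extra QALYs for $1,108 — an ICUR of
about $2,916 per QALY from the rounded inputs (≈$2,985 from unrounded
means), far below a $50,000/QALY threshold. Propagating parameter
uncertainty:

```r
psa <- run_psa(add_default_uncertainty(spec), n_iter = 2000, seed = 1)
cc  <- ceac(psa)
unlist(cc[cc$wtp == 50000, -1])
#>   cfIMRT   hfIMRT HDR-IMRT    HDR-b    LDR-b     SBRT
#>    0.000    0.000    0.000    0.000    0.0005   0.9995
```

At $50,000/QALY, SBRT is the most likely cost-effective modality in
essentially every iteration; LDR-b leads only at thresholds below a few
thousand dollars per QALY.

The staged analysis lives in `analysis/01_make_inputs.R` …
`analysis/04_cea.R`; each stage writes CSV outputs and a JSON provenance
record under `results/`.

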