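---
title: "Model methods: partitioned-survival cost-effectiveness analysis of first-line chemo-immunotherapy in ES-SCLC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The decision problem

`escea` models the cost-effectiveness, from a United States payer
perspective, of three first-line treatment strategies for
extensive-stage small-cell lung cancer (ES-SCLC):

* **AEP** — atezolizumab (1,200 mg flat every 21 days) plus etoposide
  and carboplatin;
* **DEP** — durvalumab (1,500 mg flat every 21 days) plus etoposide and
  carboplatin;
* **EP** — etoposide and carboplatin chemotherapy alone.

A cohort enters progression-free (PFS), may progress (PS), and dies;
outcomes are discounted quality-adjusted life-years (QALYs) and costs,
compared by incremental cost-effectiveness ratios (ICERs) against a
willingness-to-pay of $100,000/QALY.

## Survival model

State occupancy is computed by the partitioned-survival (area-under-curve)
method from marginal PFS and OS curves evaluated at 21-day cycle
boundaries over a 10-year horizon (174 cycles):

* `pfs(t) = S_PFS(t)`, `dead(t) = 1 − S_OS(t)`,
  `ps(t) = S_OS(t) − S_PFS(t)` clamped at zero if the curves cross.

With only two marginal curves, the per-state exit probabilities of the
equivalent three-state transition model are under-identified; the
partitioned form is the standard reproducible choice.
`interval_event_prob()` remains available for building an explicit
transition-matrix variant.

The AEP arm uses log-logistic fits, `S(t) = 1 / (1 + θ t^κ)`, with
(θ, κ) = (0.003072, 2.297440) for OS and (0.008895, 2.852489) for PFS.
The pooled EP arm uses Weibull fits in scale-rate form,
`S(t) = exp(−λ t^γ)`, with (λ, γ) = (0.016073, 1.593409) for OS and
(0.042826, 1.712046) for PFS.  All times are **months**: these
parameters reproduce the source trials' published medians (≈12.4 and
≈5.2 months for AEP OS/PFS, ≈10.6 months for pooled EP OS), which is
asserted in the test suite and fixes both the time unit and the
parameterisation unambiguously.  The DEP arm applies proportional
hazards to the AEP curves, `S_DEP(t) = S_AEP(t)^HR`, with indirect
hazard ratios 1.04 (OS) and 1.01 (PFS).

**Extrapolation.** Both curves are parametric over the trials' ~2-year
follow-up.  Beyond a 24-month cutoff the PFS curves always continue
parametrically; the OS curves continue parametrically by default, or
switch to an external background-hazard table
(`extrapolation_policy(mode = "external_hazard_table")`), applied
piecewise-exponentially on top of `S(24)` so the composite curve is
continuous.  The published analysis replaced the OS tail with
registry-derived (SEER) hazards that appear only in its supplement; no
such table ships with this package, so the default is parametric
continuation and a user-supplied CSV (`time_months,monthly_hazard`)
can reinstate a registry override.  When a table is supplied it
replaces (not caps) the parametric hazard beyond the cutoff, and the
same table is used for the DEP tail — background mortality is
arm-independent, so HR adjustment is applied to the curve at evaluation
time and commutes with extrapolation in the default mode.

This is the model's largest known fidelity gap: a registry tail with a
survivor plateau raises EP QALYs and trims the heavy log-logistic AEP
tail relative to parametric continuation, which is why the package's
absolute EP totals and the AEP-vs-EP ICER sit below the published
values while all increments retain their sign and ordering.

## Costing

Per cycle, weighted by state occupancy at the cycle end and discounted
at 3% per year (`(1.03)^(−t/365.25 days)`):

* **First-line drugs** while progression-free and the line is active:
  etoposide 100 mg/m² × 3 days (BSA 1.8 m²), carboplatin by the Calvert
  formula `AUC 5 × (CrCl 70 + 25)` mg, both for 4 induction cycles;
  the ICI (flat dose) for its configured duration.  Per-mg 2020 CMS
  prices; linear pricing without vial rounding.
* **ICI duration**: the trials stopped ICIs for progression but also
  for toxicity and other reasons, so the base case uses a *median
  treatment cycles* stand-in, defaulting to 7 cycles per arm
  (`treatment.ici_cycles`).  The published medians are not printed
  anywhere recoverable, so this knob is an explicit calibration point.
  The scenario mode switches to until-progression, accruing ICI costs
  with PFS occupancy over the whole horizon.
* **Administration**: 4 infusion hours per chemo-immunotherapy cycle, 3
  per chemotherapy-only cycle (first hour $142.55, additional $30.68),
  1 hour per ICI maintenance cycle.
* **Adverse events**: one-time incidence-weighted aggregates in cycle 1
  ($4,959.82 AEP / $4,743.05 DEP / $6,100.94 EP).
* **Subsequent therapy**: topotecan 1.5 mg/m² days 1–5 (5 × 1-hour
  infusions), capped at 4 cycles, for the configured proportion of
  progressing patients (51.7% / 42.0% / 51.6%), plus a one-time
  second-line AE cost of $14,487.33 per starter.  Progression events
  per cycle are estimated as the PFS-occupancy drop net of deaths
  allocated to the living states in proportion to their start-of-cycle
  occupancy — the split is not identified from marginal curves, and
  attributing every PFS exit to progression would charge second-line
  therapy to patients who died progression-free.  Patients on
  topotecan are the rolling sum of recent starters, bounded by PS
  occupancy.
* **Follow-up** while alive: monthly physician visit ($148.33) and
  three-monthly imaging ($122.71), pro-rated per cycle
  (monthly × 21/30.4375).
* **Supportive care** ($637/month) for progressed person-time not on
  topotecan, and a one-time death cost ($9,433) per incremental death.

QALYs accrue as `u_PFS·pfs + u_PS·ps` per cycle-year (utilities
0.673/0.473), minus the arm's adverse-event disutility (0.090 AEP /
0.094 DEP / 0.112 EP).  The default policy subtracts the decrement from
the PFS utility during the planned first-line treatment cycles;
`one_time_cycle` and `one_time_absolute` variants are selectable.  The
disutility window is pinned to the *planned* (median) duration even in
the until-progression scenario, so that scenario changes costs only —
adverse events concentrate in cycle 1 and should not scale with
treatment duration.

No half-cycle correction is applied by default (the reference analysis
does not mention one); occupancy is evaluated at cycle end, and a
`half_cycle_correction` flag exposes the alternative.  Cycle-end
evaluation was also the convention that reproduced the published
until-progression scenario cost almost exactly, supporting the choice.

## Comparative analysis

`icer()` classifies every sign pattern (dominant / dominated /
indifferent / ICER, including the cost-saving-QALY-losing quadrant);
`frontier()` removes strictly and extendedly dominated strategies and
reports sequential ICERs; `net_monetary_benefit()` underlies the PSA
summaries.  ICERs are always computed from unrounded totals — the
published table's increment-rounding drift (e.g. 62,073/0.162 ≈
383,167 vs the printed 382,469) is reproduced only at presentation.

## Sensitivity analysis

* **One-way DSA**: each parameter in the configuration's sensitivity
  table is set to its low/high bound (95% CIs for utilities,
  disutilities and proportions; ±25% bands for prices and unit costs,
  as printed), the full model re-runs, and entries are sorted by ICER
  spread.  Dominance at a bound is encoded as `NA` with a status
  column rather than a numeric sentinel.
* **Threshold search**: bisection on a price multiplier `m ∈ [0, 1]`
  until `|ICER − WTP| < $500/QALY`; reported as a reduction fraction,
  with an explicit "unattainable" result when even a free drug does
  not reach the threshold.
* **PSA**: 10,000 draws; gamma (moment-matched mean/SE), beta
  (moment-matched, with an explicit infeasibility error), lognormal
  (baseline as median, `sdlog` from the CI on the log scale); the
  `[low, high]` range is read as a 95% interval, `se = (high−low)/3.92`.
  Survival distribution parameters are *not* varied (no published
  ranges); only the two DEP hazard ratios carry survival-side
  uncertainty, and parameters are drawn independently.  Draws are
  reproducible byte-for-byte for a fixed seed; EP and AEP traces are
  cached across draws because no sampled parameter enters their curves.
  Under these prescribed distributions the pairwise probability that a
  chemo-immunotherapy arm is cost-effective versus EP at $100,000/QALY
  is essentially zero: the ICER would need a ~77% ICI price cut, more
  than five standard errors below the sampled gamma mean.  The
  published small positive probabilities imply wider variance
  conventions that are not recoverable from the published table.
* **Scenario**: ICIs until progression, as above.

## Synthetic-data generator

`simulate_trial()` draws event times by inverse transform from any
supported curve (closed-form quantile functions), with uniform accrual,
administrative censoring at a calendar cutoff, and optional exponential
dropout.  `km_estimator()` computes the product-limit curve (events
before censorings at ties) with a numbers-at-risk table, yielding
exactly the digitized-KM shape that `reconstruct_ipd()` consumes, so
reconstruction/fitting can be validated end-to-end without external
data.  The generator emulates administrative censoring only — it does
not model dependent censoring, cure fractions, delayed separation of
arms, or digitization noise in the coordinates, so passing roundtrips
bound algorithmic error, not digitization error on real published
curves.

`reconstruct_ipd()` follows the interval-solving approach used for
published KM curves: within each risk-table interval the censoring
count is iterated until the implied number at risk matches the printed
one, censorings are spread uniformly over the interval (the standard
assumption, since their true times are unobservable), events sit at
the digitized step times, and survivors past the last coordinate are
censored there.  A reported total event count triggers a final
rebalancing pass converting trailing events/censorings.

`fit_parametric()` maximises the censoring-aware log-likelihood
`Σ_events log f(t) + Σ_censored log S(t)` by BFGS on log-parameters
from several moment-style starts (shape grid 0.7/1/1.5/2.5, scale from
the observed median); exponential uses its closed form.  The test
suite cross-checks estimates against `survival::survreg` and
`flexsurv::flexsurvreg`.  `select_best()` ranks by AIC with BIC, then
parameter count, then family name as tie-breaks.

## Numerical choices and edge cases

* Bisection tolerances: `1e-10` on the survival scale for medians,
  $500/QALY for price thresholds (60 iterations max).
* `interval_event_prob` returns 1 when `S(t0) = 0` (absorbing) and 0 on
  empty intervals; probabilities are clamped to `[0, 1]`.
* Degenerate inputs: all-censored data refuse to fit; fewer than two
  events refuse to fit; single-strategy tables produce no incremental
  block; equal sequential ICERs (collinear strategies) are retained on
  the frontier; CEAC ties split probability equally.
* Monthly quantities convert per-cycle by 21/30.4375 (30.4375 =
  365.25/12).

## Problem sizes used by the tests

The validation suite uses 50 reconstruction roundtrips at n ∈
{100, 200, 400}, parameter-recovery runs at n = 2,000 with ~20%
administrative censoring, consistency checks at n = 500 vs 5,000, a
100,000-individual microsimulation cross-check of the cohort trace,
and the full 10,000-draw PSA.  These sizes keep every stochastic check
comfortably inside its tolerance while the whole suite runs in a few
minutes on one CPU.

## Known limitations

* No registry hazard table ships with the package (see above); absolute
  EP totals are accordingly conservative (higher) versus the published
  model, while orderings, dominance and threshold results are stable.
* The median ICI cycle counts and the topotecan duration are config
  defaults standing in for unpublished values; both are flagged
  calibration knobs in `default_config()`.
* Durvalumab maintenance is modelled on the 21-day model cycle like
  atezolizumab; a 4-weekly maintenance interval would lower the
  DEP−AEP cost increment.  Users can approximate it by scaling the DEP
  cycle count.
* No vial-wastage, cisplatin arm, time-varying hazard ratios, cure or
  spline survival models, or correlated PSA sampling.
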