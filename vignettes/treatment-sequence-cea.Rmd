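---
title: "Methods: semi-Markov microsimulation of prostate-cancer treatment sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: semi-Markov microsimulation of prostate-cancer treatment sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqcea)
```

## The disease model and its assumptions

`seqcea` models advanced prostate cancer as a discrete-time semi-Markov
process over the states nmCSPC, mCSPC (low and high risk), nmCRPC, two
mCRPC treatment lines, progressed mCRPC and death, in 1-month cycles.
Transition probabilities depend on the time spent in the current state
(`t`, months, reset to 1 on every state entry) but not on total disease
time:

* progression: `alpha * (1 + beta)^(t - 1)`;
* death before progression: `gamma` (constant);
* death after progression — i.e. in progressed mCRPC: `delta` (constant),
  taken from the final treatment line's parameters.

The functional form deliberately sits between a free nonparametric hazard
(which would overfit digitized curves and permit non-credible abrupt
shifts) and constant probabilities (too restrictive): one geometric trend
parameter `beta` captures rising or falling progression risk.

Simulated patients are identical — no age or comorbidity covariates — and
there is no separate background-mortality hazard: the trial OS curves the
parameters are calibrated to already embed it.  There is no recovery state.

## Calibrating parameters from survival curves

Trial evidence arrives as PFS and OS Kaplan–Meier curves per
treatment–state pair.  Pre- and post-progression deaths are not separately
observable in an OS curve, so `(alpha, beta, gamma, delta)` are only
partially identified; the package resolves this by projecting the
cohort-level curves implied by a candidate parameter set,

```
u(0) = 1, v(0) = 0
u(t) = u(t-1) * (1 - P(t) - gamma)        PFS(t) = u(t)
v(t) = v(t-1) * (1 - delta) + u(t-1) P(t)  OS(t) = u(t) + v(t)
```

and minimizing the mean-squared error against the empirical curves over an
exhaustive parameter grid (`grid_search_fit()`, with a C++ kernel).
Numerical choices, each of which was genuinely open:

* **Fitting grid.**  Every integer month from 1 to the empirical follow-up,
  by step-function (last-observation-carried-forward) evaluation of the
  digitized curves, because the model runs in monthly cycles.  PFS and OS
  are pooled with equal weights and fitted jointly (the alternative —
  fitting PFS first, then OS — discards the OS curve's information about
  `gamma`).
* **Default ranges** `alpha` in [0, 0.25], `beta` in [−0.10, 0.10], `gamma`
  in [0, 0.10], `delta` in [0, 0.25], step 0.005: monthly probabilities
  above these bounds are clinically implausible for these states.  One
  refinement pass re-centres a grid of one-tenth the step on the incumbent,
  spanning one old step either side.
* **Tie-breaking** (deterministic output): smallest `|beta|`, then smallest
  `alpha`, `gamma`, `delta` — prefer the most constant hazard.
* **Clamping.**  Points where `alpha (1+beta)^(t-1) + gamma` would exceed 1
  late in follow-up are evaluated with the progression probability clamped
  at `1 - gamma` and flagged (`clamped`), rather than rejected; only points
  infeasible at `t = 1` are skipped.
* **Unidentified `delta`.**  When the fitted `alpha` is 0 nobody
  progresses, `delta` has no effect on OS, and the tie-break parks it at
  the grid minimum; `delta_identified = FALSE` flags this.
* A consequence of the recursion's timing is that newly progressed
  patients survive their entry month even when `delta = 1`; the stochastic
  engine, the deterministic projection and the trial generator all share
  this convention, and the tests assert it.

`parametric_benchmark_fit()` provides the Weibull/lognormal
maximum-likelihood comparators (via `flexsurv`) used to sanity-check the
grid fit's MSE.

## Reconstructing patient data from digitized curves

`guyot_reconstruct()` implements the Guyot interval-allocation scheme:
within each numbers-at-risk interval, censoring times are spread uniformly
and per-step event counts chosen so the product-limit estimate of the
output reproduces the input curve, iterating the interval's censor count
until the reconstructed number at risk matches the published one at the
next boundary.  Without a risk table the initial sample size must be
supplied and censoring is assumed administrative at last follow-up only —
the least-assumption default — with the output flagged.  Round-trip
accuracy (reconstruct, re-estimate, compare) is held to 0.005 absolute at
all curve times, and reconstructed risk tables match the input exactly.

## The microsimulation engine

`simulate_cohort()` (C++ core) simulates patients sequentially from one
seeded RNG stream, so a fixed seed reproduces the cohort bit for bit.
Conventions, in draw order within a month:

* the patient occupies one state per month and accrues that month's
  life-years, utility and cost first; events resolve at month end (no
  half-cycle correction — plain monthly cycles);
* one uniform draw resolves the competing events, partitioned
  `[0, P_prog)`, `[P_prog, P_prog + gamma)`, remainder = stay;
* progression from nmCSPC draws one uniform for the nmCRPC branch
  (probability `p_nm_to_nmcrpc`, default 0 — only the nmCSPC→mCSPC split is
  quantified in the sources, so the branch is exposed as configuration
  rather than invented) and one for the 0.651 / 0.349 low/high-risk mCSPC
  split;
* each suspension episode start draws one beta variate for its length.

Discounting is smooth monthly: month `m` is weighted
`(1 + r)^(-m/12)` with `r = 0.015`/year by default (3% and 3.5% in the US
and UK scenarios).

**Costs.**  Every non-suspended month carries the ADT backbone (CAD
322/month) plus the regimen's other components; chemotherapy drug cost and
IV management (CAD 455) apply only during its fixed cycles, non-IV
management (CAD 92) otherwise; suspended nmCSPC months incur only non-IV
management; progressed mCRPC carries management cost only.  Patients who
die in progressed mCRPC additionally receive CAD 1449/month over their last
`min(12, months progressed)` months, discounted at those months — patients
alive at the horizon receive none.  Chemotherapy cycle defaults are one
model month per cycle — monthly granularity cannot represent 3-weekly
protocol cycles, a documented approximation — with docetaxel 6 cycles in
mCSPC and 10 in mCRPC, cabazitaxel 10, all configurable.

**Utilities.**  Monthly QALY increment = (state annual utility − annual
disutility of the components taken that month)/12.  Treatment disutility
pauses during suspension (no drug, no adverse events — the sources do not
state this either way, so it is a flagged decision) and the chemotherapy
component's disutility stops with its cycles, mirroring the cost logic.

**Intermittency** applies only in nmCSPC (9-month active phases, suspension
lengths `max(1, round(scale * Beta(a, b)))` months).  Progression and death
hazards are applied identically in active and suspended months: the trial
curves the parameters are fitted to already integrate over the protocol's
on/off schedule, so suspension affects cost and disutility only.  The
shipped suspension parameters (a = 2, b = 2, scale = 24) are synthetic
placeholders, flagged as such, to be overridden by fitted values.

`project_sequence()` is the deterministic matrix analogue — the joint
(state, months-in-state) occupancy recursion under identical conventions —
and serves as the law-of-large-numbers oracle for the engine: tests require
the simulated mean life-years and mean months of occupancy per state to sit
within three standard errors of the projection.  (Cell-wise month-by-month
occupancy comparisons are not used as pass criteria: deviations are
serially correlated and far-tail cells hold expected counts of a few
patients, where a Gaussian three-sigma band is meaningless.)

## Sequences and admissibility

Regimen availability per state follows the trial evidence base
(`default_catalogue()`).  Admissibility rules: no ARPI in any treatment
line after a line containing an ARPI (cross-resistance — this is the one
rechallenge excluded); cabazitaxel only immediately after docetaxel; a
second mCRPC line only after first-line docetaxel; docetaxel itself may
recur in mCRPC after mCSPC combination use.  nmCSPC-starting sequences
assign one shared regimen to mCSPC and nmCRPC (a patient visits one of
them, so this slot is a single treatment line), and any late ARPI use sits
in that shared slot, making the mCRPC lines of nmCSPC starts
chemotherapy-only.  Under these rules enumeration yields 20 low-risk and 26
high-risk mCSPC sequences and 12 nmCSPC sequences; the published list has
11 for nmCSPC, but its exact rule set lives in unpublished appendix
material, so expected counts are a soft check (`expected` argument reports
a diff) rather than an invariant.  The no-ARPI references are
`(adt, adt, doce)` and `(adt, doce)`.

## Cost-effectiveness layer

`NHB = Benefit − Cost/CET` is the headline statistic (not ICER — with many
comparators NHB has the clearer interpretation); `rank_sequences()` reports
totals and increments over the reference with deterministic tie handling
(lower cost, then label).  Acceptability curves resample stored per-patient
outcomes (2000 iterations × 100 patients by default) rather than
re-simulating: distributionally equivalent for means, orders of magnitude
cheaper, and reproducible from a seed.  The CET grid defaults to CAD
1K–300K in 1K steps.  `tornado_threshold()` returns the lowest grid CET at
which a group wins more than 99% of iterations.  Scenario handling
(`apply_scenario()`) covers 10/20-year horizons, ARPI prices equalized to
abiraterone's CAD 919, and US VA / US private / UK public payers (discount
3% / 3% / 3.5%, CET conversion at 1.3698 CAD/USD and 1.7504 CAD/GBP); the
shipped US/UK price tables are labelled synthetic placeholders and are
meant to be overridden with actual payer tables.

## What the synthetic generator does and does not emulate

`generate_trial()` draws patient-level progression and death months under
known truth parameters, applies monthly dropout (default 0.002/month —
mild, realistic, keeps recovery tests clean) plus administrative censoring,
and emits monthly-resolution KM curves with 6-monthly risk tables, i.e.
exactly the statistical structure the calibration consumes.
`generate_param_catalogue()` draws plausible monthly parameters
(`alpha` ≤ 0.15, `gamma`, `delta` ≤ 0.08, `|beta|` ≤ 0.03, jointly
constrained to stay valid over 240 months) with ARPI-containing regimens
receiving lower `alpha` and `gamma` than ADT alone in the same state, so
simulated efficacy is ordered the way the trial evidence orders it.

What passing tests on these inputs show: the estimator identifies the
parameters that generated the data; the engine agrees with its analytic
expectation; the CEA layer's identities and limits hold.  What they do not
show: agreement with any real trial's digitized curves (digitization noise,
non-monthly reporting grids and subgroup structure are not emulated), nor
the published headline totals, which require the fitted parameter catalogue
for the 19 source trials; the pipeline accepts such a catalogue as input
via the same `"state|treatment"`-keyed list.

## Problem sizes used by the test suite

The default study configuration is 200,000 patients over 180 months.  The
tests exercise the same code paths at sizes chosen to keep the suite quick
while leaving no statistical check underpowered: calibration recovery uses
the full default grid (≈2.2M evaluations per fit, 50 truths) and a
100,000-patient synthetic trial for the noisy case; engine-versus-projection
agreement uses 50,000 patients × 5 catalogues; pipeline smoke tests use
2,000–5,000 patients per sequence.

## Known limitations

* Monthly cycles cannot represent 3-weekly chemotherapy protocols; cycle
  counts are calendar-month approximations.
* The nmCSPC→nmCRPC branch probability, the US/UK price tables and the
  suspension distribution ship as flagged placeholders.
* No ARPI-rechallenge sequences, PARP inhibitors, radium or lutetium; no
  societal-perspective costing; no patient covariates.
* Reported counts of admissible sequences depend on rule details that the
  main published sources under-determine (see the soft check above).
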