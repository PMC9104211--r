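---
title: "Methods: the renal-mass imaging cost-effectiveness model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the renal-mass imaging cost-effectiveness model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(renalcea)
```

## The decision problem

A 62-year-old patient presents with an incidentally detected solid renal
mass; the pre-test probability that it is malignant (renal cell carcinoma)
is 0.831. Three single-test imaging strategies are compared: contrast-
enhanced ultrasound (CEUS, sensitivity 0.991 / specificity 0.805 / USD 285
per exam), CT (0.75 / 0.72 / USD 233) and MRI (0.90 / 0.96 / USD 381). The
test result routes the patient down one of four branches:

* **True positive** — timely surgery and treatment (USD 4231 acute).
* **False negative** — the malignancy declares itself later; delayed
  treatment (USD 6346.50 acute) and a worse disease trajectory.
* **True negative** — no further action (USD 0).
* **False positive** — an unnecessary biopsy (USD 1375).

Each branch then runs a monthly-cycle Markov cohort model over four health
states — alive with no renal malignancy, alive with localized disease,
alive with metastatic disease, and dead — to a lifetime horizon (age 100,
i.e. 456 cycles from the default starting age). Costs (2020 USD) and QALYs
are discounted at 3% per year; the willingness-to-pay threshold is
USD 100,000 per QALY. No currency conversion or inflation adjustment is
applied, and combination strategies (e.g. CEUS followed by MRI) are out of
scope.

## State rewards and transitions

Utilities are annual QALY weights accrued pro rata per monthly cycle
(weight/12): 1 without tumor, 0.75 with detected localized disease, 0.66
with metastatic disease, 0 when dead. Monthly costs switch from a
first-year to a later-years regime at cycle 12: USD 108.50/month without
tumor; 2148.25 then 212.67 with detected disease; 2086.42 then 810.58 with
metastatic disease. The published narrative elsewhere quotes USD 108.50 as
the post-first-year cost for treated patients; the input table's 212.67 is
taken as authoritative and the conflict noted here.

Annual transition probabilities are converted to monthly ones under a
constant within-year hazard, `1 − (1 − p)^(1/12)`; compounding the monthly
probability twelve times recovers the annual one to better than 1e−12,
which the test suite asserts. Two inputs are per-episode rather than
annual: the probability of a non-R0 (incomplete) resection, 5.73%, and of
successful surgery for a local recurrence, 41.2%. Their product
`(1 − 0.0573) × 0.412` is treated as an annual cure probability out of the
localized state and spread over 12 cycles by the same hazard conversion.

The default (`"specified"`) wiring is:

* **No tumor** → localized at monthly(10.75%) (post-resection local
  recurrence), → metastatic at monthly(1%), → dead at the life-table
  background risk.
* **Localized** → no tumor at the monthly cure rate, → metastatic at
  monthly(13%), → dead at background combined with monthly(3.5%) excess.
* **Metastatic** → dead at background combined with monthly(35%) excess.
* **Dead** is absorbing.

Background and excess mortality combine as independent competing risks,
`1 − (1 − p₁)(1 − p₂)`. Rows are built death-first: state changes are
conditioned on surviving the cycle (`P(→X) = (1 − d)·pₓ`), which keeps
every row stochastic for all valid inputs including the forced death at the
life-table cap, where an unconditional formulation would overflow. The
difference from unconditional wiring is O(d·pₓ) per cycle — negligible at
ordinary monthly death probabilities.

Numerical conventions: rewards accrue at cycle start with cycle 0
undiscounted (`(1 + r)^(−t/12)`), no half-cycle correction — the common
default of commercial decision-tree software, and the convention the
closed-form and microsimulation oracles share. Attained age is the integer
floor of current age; the cohort stops early once dead-state occupancy
exceeds 1 − 1e−9. There are no tunnel states beyond the year-one reward
switch, which keys on the cycle index, not on time-in-state.

## Background mortality

Age-specific background mortality comes from a life table (`age,qx` CSV).
Because no national table ships with the package, the default is a
synthetic Gompertz table, `qx(age) = 1 − exp(−a·e^{b·age})` with slope
`b = 0.085`/year — a typical adult mortality doubling time of about 8
years — and scale `a` fitted by bisection so that residual life expectancy
at age 62 is 21 years, matching what a US cohort of that age would face.
Everyone alive at the cap (age 100) dies in that cycle, keeping horizons
finite. The default table triggers a log message: analyses meant to
reproduce published numbers that used an official national life table
should load that table explicitly with `load_life_table()`; the synthetic
stand-in reproduces its life expectancy but not its exact age profile, and
that difference propagates into absolute QALY levels (see below).

## Calibration: the `"reconciled"` topology

The published strategy totals this package set out to reproduce cannot be
generated by lifetime accrual of the monthly state costs: under the
specified wiring each strategy accumulates roughly USD 30–40k, three to six
times the published totals, and the strategy ordering inverts because
false-negative patients die early and therefore *save* lifetime background
costs. Solving the three published cost totals against the exact branch
probabilities shows what the original model must have done: monthly costs
accrue only during the single model year (the published input table's
"model time: 1 year"), true negatives accrue exactly 12 × 108.50 =
USD 1302, treated (true-positive) patients return to the healthy state, and
false negatives spend the year on metastatic-level costs. The published
QALY gaps likewise imply that true negatives are plain background survivors
(utility 1, no disease dynamics — consistent with reading the 10.75%
recurrence input as *post-resection* recurrence, which cannot apply to a
patient who never had a malignancy) and that the false-negative trajectory
keeps the metastatic utility 0.66 under near-background mortality.

`model_options("reconciled")` implements exactly that reading: timely
treatment returns the patient to the no-tumor state on a post-resection
trajectory that keeps the recurrence dynamics; true negatives and false
positives are background survivors; the false-negative branch is an
absorbing delayed-treatment trajectory carrying the metastatic cost rows
and utility with background-only mortality; monthly costs accrue for 12
cycles only while QALYs run to the lifetime horizon. Recurrent localized
disease on the healthy trajectories is charged at the later-years detected-
tumor rate (212.67), since the first-year rate belongs to the initial
treatment episode.

Under this calibration the package reproduces the published cost totals to
within about 2% and the dominance structure exactly (CEUS cheapest and most
effective; CT and MRI strictly dominated). QALY levels come out 0.6–0.8
low across all three strategies: roughly 0.3 of that is the synthetic life
table's flatter survival profile versus the official table the original
analysis used, and the remainder sits in the treated-trajectory internals,
which the published material under-determines (its printed totals imply a
treated-patient value of about 11.9 discounted QALYs, whereas a
post-resection trajectory that faces the full recurrence-progression
cascade yields about 11.0). Because the QALY *differences* between
strategies are driven by the same branch probabilities in both
formulations, the ranking and all incremental conclusions are unaffected.
The published incremental ratios (−10,115.05 and 9,703.86 USD/QALY) cannot
be reproduced from any pairing of the published rounded totals either and
are reported as computed, not matched.

The calibration was derived analytically from the published totals — a
linear solve, documented above — and then frozen; it is not a free
parameter tuned against test outcomes. The specified topology remains the
default because it is the transparent, fully-documented wiring; the
reconciled one exists to connect the package to the published table and
for users who prefer a cost model restricted to the acute year.

## Sensitivity analyses

**Deterministic.** `tornado()` re-runs the full pipeline with one parameter
pinned at each end of its range. Published ranges are not available, so the
default is ±20% of the base value, clipped to [0, 1] for probabilities, for
every test sensitivity/specificity and every cost (19 parameters). Because
incremental ratios are sign-unstable under dominance, the default outcome
metric is the net-monetary-benefit margin of CEUS over its best alternative
at the threshold; `metric = "icer"` instead reports the ICER of CEUS
against its highest-NMB alternative, the conventional tornado axis. A
negative ICER under that metric means CEUS is dominant (cheaper and more
effective) or dominated (the sign alone does not distinguish them, which is
exactly why the NMB margin is the default).

**Probabilistic.** Each parameter carries a distribution on its natural
scale: beta for probabilities and utilities strictly inside (0, 1), gamma
for strictly positive costs, fixed for structural values (WTP, discount
rate, starting age, boundary utilities, zero costs). Dispersion is a
coefficient of variation, by default 0.2 — a common convention when source
uncertainty is unreported — converted by method of moments. For beta means
near 1 a cv of 0.2 is infeasible (it requires `cv² < (1 − μ)/μ`); the
default assignment truncates the cv at 70% of that bound, so e.g. the CEUS
sensitivity of 0.991 samples with cv ≈ 0.067. An explicitly requested
infeasible spec raises an error naming the parameter. Parameters are drawn
independently — no correlation structure is published — and the life table
is held fixed: the age-dependent mortality input is a curve, not a scalar,
and no dispersion for it is available. All draws come from a single seeded
stream in a fixed parameter order, so a PSA is bit-identical given its
seed; the per-iteration Markov stages are propagated vectorized across
iterations, which is exact because iterations are independent and the
cohort recursion is elementwise. 30,000 iterations run in a few seconds;
the shipped tests and the acceptance script use 3,000, which bounds the
Monte Carlo error of an acceptance fraction near 0.5 by about ±0.9
percentage points.

The acceptability curve reports, per willingness-to-pay value, the fraction
of iterations in which each strategy attains the maximal net monetary
benefit. NMB ties go to the cheaper strategy; exact ties on both NMB and
cost split the iteration equally, so fractions sum to 1 by construction.

## What the synthetic generators do and do not show

`random_parameter_set()` samples every input uniformly inside invariant-
respecting bounds (probabilities in type-appropriate intervals, costs
nonnegative, utility of death pinned at 0) and is used for property-style
tests: occupancy conservation, dominance-flag agreement with a brute-force
all-pairs oracle, monotonicity of QALYs in sensitivity and of cost in
specificity. The monotonicity claims presume the clinically plausible
ordering (metastatic no better than localized in utility and mortality), so
the tests symmetrize random draws to that ordering; outside it the claim is
genuinely false, not a bug.

`microsim_oracle()` replays the identical decision tree and transition
process patient by patient with direct random draws — no occupancy algebra
— and the tests require the cohort engine to agree within 3 Monte Carlo
standard errors at 100,000 patients on five random parameter sets. This
validates the propagation and reward machinery, including the death-first
decomposition, against an independent implementation. It does not validate
the inputs: agreement says nothing about whether 0.831, 0.991 or USD
2148.25 describe any real population, and the synthetic life table
emulates only life expectancy, not the age shape of real mortality.
Passing tests therefore demonstrate internal correctness and published-
table reproduction under the documented calibration, not external validity.

## Known limitations

* Three disease states compress a clinically heterogeneous spectrum; there
  are no treatment-line, surveillance or histology subgroups.
* The year-one/later reward switch keys on model time, so disease acquired
  in cycle 30 never incurs first-year treatment intensity (no tunnel
  states).
* The false-negative branch charges its delayed-treatment cost at model
  start; no detection-delay duration is modelled.
* True-positive patients are charged no confirmatory biopsy (the input
  table ties biopsy costs to false positives only).
* PSA parameters are independent; in reality test accuracies and costs
  co-vary.
* Absolute QALY levels depend on the life table supplied; the shipped
  synthetic table is a stand-in, and conclusions should be read as
  incremental, not absolute.
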