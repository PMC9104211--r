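# renalcea

Decision-analytic cost-effectiveness modelling of the diagnostic workup of
solid renal masses: contrast-enhanced ultrasound (CEUS) versus computed
tomography (CT) versus magnetic resonance imaging (MRI).

Incidentally detected solid renal masses must be characterised as benign or
malignant (renal cell carcinoma) before treatment. The three imaging
strategies differ in sensitivity, specificity and examination cost, and a
missed malignancy carries large downstream costs and quality-of-life losses.
`renalcea` models this trade-off for health economists and imaging
researchers who want a transparent, fully testable re-implementation of the
published analysis, with every input swappable.

## The model

For each strategy with sensitivity *Se*, specificity *Sp* and pre-test
probability of malignancy *p*, a decision tree splits the cohort into

> TP = p·Se, FN = p·(1−Se), TN = (1−p)·Sp, FP = (1−p)·(1−Sp)

Each branch pays an acute entry cost (examination plus timely treatment,
delayed treatment, nothing, or an unnecessary biopsy) and enters a four-state
monthly-cycle Markov cohort model — *alive, no renal malignancy*; *alive,
localized renal malignancy*; *alive, metastatic renal malignancy*; *dead* —
that accrues discounted costs and quality-adjusted life years (QALYs) to a
lifetime horizon. Background mortality comes from an age-indexed life table;
disease states add excess monthly death risks as competing hazards. Annual
probabilities convert to monthly ones under a constant hazard,
`1 − (1 − p)^(1/12)`.

Strategies are compared by incremental cost-effectiveness ratio,

> ICER = (E₁ − E₀) / (O₁ − O₀)   [USD per QALY]

with strict and extended dominance flagged on the cost-effectiveness
frontier, and by net monetary benefit `NMB = λ·O − E` at a willingness-to-pay
λ (default USD 100,000/QALY). One-way (tornado) and probabilistic sensitivity
analyses are built in: the PSA draws every parameter from its assigned beta
(probabilities, utilities) or gamma (costs) distribution via
method-of-moments and summarises decision uncertainty as cost-effectiveness
acceptability curves. A patient-level microsimulation oracle validates the
cohort engine, and a synthetic Gompertz life table plus a randomized
parameter generator make every analysis runnable offline.

## Worked example

```r
library(renalcea)

ps  <- default_parameter_set()            # published baseline inputs
lt  <- default_life_table()               # synthetic Gompertz life table
res <- evaluate_strategies(ps, lt, opts = model_options("reconciled"))
rank_and_dominance(res)
```

```
Cost-effectiveness ranking (by cost):
  CEUS        5460.94 USD   11.6086 QALYs  [frontier]
  MRI         7428.70 USD   11.5223 QALYs  [dominated]
  CT         10481.15 USD   11.3801 QALYs  [dominated]
```

CEUS costs the least *and* yields the most QALYs, so CT and MRI are strictly
dominated and the frontier holds CEUS alone — the qualitative conclusion of
the underlying study, with costs within about 2% of its published totals
(QALY levels sit lower; see the methods vignette for why). The
`"reconciled"` topology is the calibration that reproduces the published
strategy table; `model_options("specified")` selects the package's default
lifetime-accrual wiring. Sensitivity analyses:

```r
tor <- tornado(ps, lt, metric = "icer", opts = model_options("reconciled"))
max(tor$outcome_at_low, tor$outcome_at_high)   # -15078.84, far below 100k
psa <- run_psa(ps, lt, n_iterations = 3000, seed = 1,
               opts = model_options("reconciled"))
subset(psa$ceac, wtp == 1e5)                   # CEUS accepted in ~67%
```

A thin command-line wrapper lives at `inst/cli/renalcea.R`:

```sh
Rscript inst/cli/renalcea.R run --topology reconciled --out results/
Rscript inst/cli/renalcea.R psa --iterations 30000 --seed 1 --out results/
```

Parameter configs are YAML (`inst/extdata/baseline_params.yaml` reproduces
the baseline exactly); life tables are two-column `age,qx` CSVs
(`inst/extdata/synthetic_life_table.csv` is the shipped synthetic stand-in,
fitted so residual life expectancy at age 62 is 21 years).

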