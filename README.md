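# ridsim

Simulation-based evaluation of the **retinol isotope dilution (RID)**
method for estimating vitamin A total body stores (TBS) in humans.

## The problem

RID is the standard indirect assay of vitamin A status: a subject ingests
a dose of stable-isotope-labeled retinyl acetate, a blood sample is drawn
days later, and plasma retinol specific activity is converted into an
estimate of whole-body vitamin A stores. The prediction equation is

    TBS (μmol) = Fa × S × 1/SAp

where, at sampling time *t* after dosing,

* **Fa** — fraction of the dose residing in the two vitamin A storage
  pools,
* **SAp** — plasma retinol specific activity: fraction of dose in plasma
  (FDp) divided by the plasma retinol pool size M(5) (μmol),
* **SAs** — specific activity of the stores: Fa divided by TBS,
* **S** — the ratio SAp/SAs,
* **FaS** — the composite coefficient Fa × S that multiplies 1/SAp;
  algebraically FaS = SAp × TBS, and FaS/FDp = TBS/M(5).

In a field study only SAp is measured; Fa and S (i.e. FaS) must come from
modeling or the literature, and the choice of blood-sampling day strongly
affects accuracy for individuals. `ridsim` answers "when should one
sample?" by forward simulation: it builds *theoretical subjects* — linear
eight-compartment whole-body vitamin A models with known ("assigned")
TBS — simulates their tracer kinetics exactly, applies the RID equation
with the cohort geometric-mean FaS at each candidate day, and scores the
predictions against the assigned truth. It is intended for researchers
designing RID protocols and for anyone studying the method's error
structure.

## What is in the package

* `compartmental_system()`, `solve_tracer()`, `steady_state_masses()`,
  `assigned_tbs()` — the linear compartmental model: exact spectral
  solution of the tracer kinetics (fraction of dose, with mass balance as
  a structural property) and the steady-state tracee masses anchored at a
  prescribed plasma pool size.
* `rid_quantities()`, `predict_tbs()`, `cohort_rid()` — the RID equation
  terms along a time course and the TBS prediction.
* `summarize_fas()`, `evaluate_sampling_days()`, `fit_biexponential()` —
  cohort statistics: geometric-mean FaS and its CV% over time,
  per-day regressions of predicted on assigned TBS, percentages of
  subjects within 10/25/50% of truth, best-day frequencies, and
  curve-peeled biexponential fits of the FaS decline.
* `cohort_design()`, `generate_cohort()`, `read_parameter_table()`,
  `write_cohort()` — a reproducible synthetic-cohort generator (20
  adults / 20 children by default, assigned TBS spanning roughly
  160–2700 / 29–1100 μmol) and CSV/JSON I/O for externally supplied
  per-subject kinetic parameter tables.
* `run_config()`, `run_pipeline()` — the end-to-end reporting pipeline
  (tidy CSV bundle + JSON run manifest);
  `inst/scripts/rid_pipeline.R` is a thin command-line wrapper with
  `generate`, `simulate` and `evaluate` subcommands.

## Worked example

```r
library(ridsim)

cohort <- generate_cohort(cohort_design(n_subjects = 20, seed = 1))
rid_df <- cohort_rid(cohort)                 # tracer + RID terms, days 1-30
report <- evaluate_sampling_days(rid_df)     # the sampling-day analysis
report
#> <accuracy_report: 20 subjects, days 1-30>
#>   r_squared by selected day:
#>     day  4: 0.526
#>     day  7: 0.894
#>     day 10: 0.949
#>     day 14: 0.950
#>     day 21: 0.954
#>     day 28: 0.957

round(subset(report$fas_summary, day %in% c(4, 7, 10, 14, 21, 28)), 3)
#>  day gm_fas sd_fas cv_pct
#>    4  1.387  0.485 33.332
#>    7  0.859  0.178 20.377
#>   10  0.773  0.153 19.412
#>   14  0.742  0.142 18.876
#>   21  0.712  0.125 17.322
#>   28  0.685  0.110 15.897
```

Reading the output: the cohort coefficient FaS declines with time and its
dispersion (CV%) shrinks as the tracer equilibrates with the stores, so
group-coefficient predictions for *individuals* sharpen at later sampling
days — the squared correlation between predicted and assigned TBS climbs
from 0.53 at day 4 to 0.96 at day 28, while the group geometric mean is
predicted exactly at *every* day (an algebraic identity of the
geometric-mean coefficient). `report$pct_within` carries the percentage
of subjects within 10/25/50% of their true stores per day, and
`report$best_day_frequency` how often each candidate day was a subject's
most accurate.

The full bundle of tables (FaS by day, CV curves, predictions,
regressions, best-day frequencies, subjects, run manifest) is written by

```r
run_pipeline(run_config(out_dir = "rid_report", seed = 1))
```

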