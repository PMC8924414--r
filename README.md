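# markovcea

Cost-effectiveness analysis of pembrolizumab versus chemotherapy as
second-line treatment for advanced or metastatic esophageal cancer, from the
Chinese healthcare perspective, as a reusable three-state Markov cohort
model. It is aimed at health-economics analysts who want the published
decision model as runnable, testable code: the base-case engine, the
survival-curve calibration step, one-way and probabilistic sensitivity
analysis, and a synthetic patient-level data generator for end-to-end
validation.

## The model

Patients occupy one of three states — progression-free survival (PFS, on
study drug), progressive disease (PD, on subsequent-line therapy), or death
(absorbing) — and move each month according to a time-homogeneous transition
matrix calibrated to the KEYNOTE-181 trial's OS/PFS Kaplan-Meier curves.
Over a 5-year horizon (60 one-month cycles) each arm accrues discounted
(3%/year) costs and QALYs with half-cycle correction:

```
Cost  = Σ_t d(t) · ½(x_t + x_{t+1}) · c        d(t) = 1.03^(−t/12)
QALY  = Σ_t d(t) · ½(x_t + x_{t+1}) · u/12
ICER  = (Cost_pembro − Cost_chemo) / (QALY_pembro − QALY_chemo)
```

where `x_t` is the state-occupancy row vector at cycle `t`, `c` the monthly
state costs and `u` the annual utilities (0.75 PFS / 0.67 PD / 0 death).
Three trial populations ship as config files: `total`, `cps10` (PD-L1
combined positive score ≥ 10) and `scc` (squamous cell carcinoma). The
willingness-to-pay reference is $11,105.8/QALY (1× 2020 China GDP per
capita); all amounts are 2021 USD.

## Worked example

```r
library(markovcea)
run_comparison("cps10")
#> Subgroup: cps10
#> -- pembrolizumab --
#> Discounted cost  :   50961.12 USD (PFS 50117.04, PD 844.08)
#> Discounted QALYs :     0.6913     (PFS 0.3774, PD 0.3139)
#> -- chemotherapy --
#> Discounted cost  :   13708.28 USD (PFS 13189.91, PD 518.37)
#> Discounted QALYs :     0.4595     (PFS 0.2667, PD 0.1928)
#> -- incremental --
#> Incremental cost :   37252.84 USD
#> Incremental QALY :     0.2318
#> ICER             :  160702.94 USD/QALY
```

In the CPS ≥ 10 population pembrolizumab buys 0.23 extra QALYs for an extra
$37,253 — about $160,700 per QALY gained, fourteen times the $11,105.8/QALY
willingness-to-pay reference, so it is not cost-effective at list price.
The tornado and acceptability analyses show which inputs could change that
conclusion:

```r
run_owsa("cps10")[1:3, c("parameter", "icer_at_low", "icer_at_high", "spread")]
#>                 parameter icer_at_low icer_at_high   spread
#> 1 drug_cost_pembrolizumab    122304.5     199101.4 76796.88
#> 2              utility_pd    179456.7     145498.0 33958.70
#> 3             utility_pfs    177669.9     146694.1 30975.83

s <- run_psa("cps10", n_draws = 10000, seed = 1)
curve <- ceac(s)
curve$prob_pembrolizumab[curve$wtp == 11105.8]
#> [1] 0
```

The pembrolizumab price dominates the one-way analysis, and no PSA draw is
cost-effective at the reference threshold. Under the patient-assistance
scheme (two cycles bought, two donated — drug cost halved),
`run_scenario("cps10", c(drug_cost_pembrolizumab = 0.5))` drops the ICER to
about $64,707/QALY.

The same analyses run from a shell via the bundled script
(`system.file("cli", "cea.R", package = "markovcea")`):

```sh
Rscript cea.R run --config cps10 --out-dir results
Rscript cea.R psa --config cps10 --n 10000 --seed 1 --out-dir results
Rscript cea.R simulate --config cps10 --n 20000 --seed 1 --out-dir results
Rscript cea.R calibrate --os results/km_os.tsv --pfs results/km_pfs.tsv --out-dir results
```

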