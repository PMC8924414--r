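---
title: "Methods: a three-state Markov cohort model for second-line esophageal cancer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a three-state Markov cohort model for second-line esophageal cancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markovcea)
```

## The decision problem and the model

`markovcea` evaluates whether pembrolizumab is good value compared with
investigator's-choice chemotherapy (paclitaxel, docetaxel or irinotecan) as
second-line treatment of advanced or metastatic esophageal cancer, from the
perspective of the Chinese healthcare system. Effectiveness evidence comes
from the KEYNOTE-181 randomized trial, which reported overall survival (OS)
and progression-free survival (PFS) for the total population, for patients
with PD-L1 combined positive score (CPS) ≥ 10, and for squamous cell
carcinoma (SCC); the package ships one parameter set per population
(`subgroups()`).

The disease course is modelled as a cohort Markov chain over three states —
progression-free (PFS, on study drug), progressed (PD, on subsequent-line
therapy) and death, which is absorbing. Backward transitions are impossible,
so a monthly transition matrix has five free entries and the chain is fully
described by `transition_matrix()`. The whole cohort starts progression-free
and is pushed through the matrix for 60 one-month cycles (5 years — roughly
the survival envelope of metastatic esophageal cancer, where 5-year survival
is about 5%). No background other-cause mortality is added: the calibrated
death transitions already absorb all observed mortality over this short
horizon. Probabilities are time-homogeneous; a single monthly value per
transition is what the evidence base supports.

Each cycle in a living state accrues a cost (monthly drug, tests and
adverse-event management while progression-free; subsequent-line therapy
after progression) and a quality-adjusted life-year (QALY) contribution of
utility/12 (utilities 0.75 in PFS, 0.67 in PD, 0 dead). The incremental
cost-effectiveness ratio (ICER) between arms is ΔCost/ΔQALY on
full-precision totals; reports round half-up to 2 decimals only at the
boundary (`cea_table()`). The willingness-to-pay (WTP) reference is
$11,105.8/QALY — one times 2020 China GDP per capita — and all amounts are
2021 USD (¥6.4831 per $, kept as metadata only).

## Accumulation conventions

Two conventions materially affect the totals and are explicit in
`model_config()`:

* **Half-cycle correction** (default on). Transitions happen continuously,
  not at cycle boundaries, so counting full cycles at state entry biases
  person-time upward by up to half a cycle. The engine credits each cycle
  with the trapezoid average of start- and end-of-cycle occupancy.
  Uncorrected sums overshoot the corrected discounted PFS person-time by
  roughly 10% at these transition rates, which is far outside the
  reproduction tolerances used in the tests, so the correction is clearly
  part of the reference results.
* **Discount compounding** (default `"compound"`). Only an annual rate (3%)
  is given by the evidence base; the monthly rate is taken as
  `(1.03)^(1/12) − 1`, i.e. cycle `t` is discounted by `1.03^(−t/12)`. The
  alternative `r/12` (`"simple"`) differs by well under 0.1% over 5 years
  and is selectable; both reproduce the reference totals within tolerance,
  and the compound form was kept as the default because it is the exact
  per-month equivalent of an annual rate.

`accumulate()` has an independent oracle in the test suite: for short
horizons it must agree, to 1e-9, with brute-force enumeration of all state
paths weighted by path probability, with the half-cycle correction and
discounting applied path-wise.

### Reproduction accuracy and a known limit

With the packaged inputs the engine reproduces the reference per-state and
total costs and QALYs closely (the acceptance tests assert 1% on cost totals
and 0.01 on QALY totals), and the incremental costs to about 0.1%. The
ICERs themselves are a harder target: the incremental QALY difference is a
small number (0.09–0.23) obtained by subtracting two similar totals, so its
relative error is roughly 20–40 times the error of the inputs. The packaged
transition probabilities carry three decimals; perturbing them within
±0.0005 moves the incremental QALYs by amounts comparable to the observed
gaps. In consequence the CPS ≥ 10 ICER lands within about 1.5% of the
reference value, while the total-population and SCC ICERs differ by several
percent under every accumulation convention. This is an irreducible
precision limit of three-decimal transition inputs, not a model choice; the
corresponding acceptance assertions are intentionally left failing rather
than loosened.

## Cost inputs

Monthly state costs are model inputs, shipped in the per-subgroup YAML
configs. Two helpers validate them against unit prices rather than define
them:

* `monthly_drug_cost()` converts vial prices to a monthly cost under a
  **28-day month**: cost per administration is
  `ceiling(required mg / vial size) × vial price` (whole vials, no sharing —
  the standard conservative costing convention), scaled by
  `28/cycle_days` administrations per month, with chemotherapy doses scaled
  by a 1.72 m² body surface area. This convention reproduces the packaged
  pembrolizumab cost ($2,763.80 per 100 mg, 200 mg q21d → $7,370.13/month
  vs $7,370.14 packaged) to the cent; a 30- or 30.44-day month does not.
  The packaged chemotherapy arm cost ($2,231.66/month) blends the three
  regimens with unstated usage weights, so it is taken as given rather than
  re-derived.
* `expected_ae_cost_per_month()` reconstructs the monthly grade ≥ 3
  adverse-event cost as Σ probability × per-event management cost over the
  trial's safety table. Two events (grade 3/4 diarrhea and alopecia) have
  no published unit cost and are excluded, so the reconstruction
  undershoots the packaged monthly values ($10.40 vs $12.23 for
  pembrolizumab, $130.23 vs $131.79 for chemotherapy). The packaged values
  are authoritative; the helper documents the gap instead of resolving it.

## Calibration to survival curves

`calibrate_transitions()` reverses `predict_curves()`: given OS and PFS
curves tabulated at integer months (the chain's native grid;
`interpolate_curve()` snaps digitised curves onto it), it fits the three
free parameters — the monthly PFS stay probability, the share of PFS exits
that are deaths, and the PD stay probability — by least squares on the sum
of both curves' squared errors.

The evidence base reports no calibration algorithm, so reproducibility
drove the design: the procedure is deterministic with no random starts.
The PFS stay probability has a log-linear closed form
(`exp(mean Δ log PFS)`) used as an initialiser and is refined against the
PFS curve alone, exploiting the triangular structure of the model (PFS
dynamics do not depend on the PD parameters). The two OS-linked parameters
are then scanned on a fixed 0.05-step grid (ties broken by lexicographic
order) and polished with Nelder-Mead on the log-odds scale — the simplex
constraints hold by construction there — followed by a joint three-parameter
polish (tolerance 1e-10, at most 10,000 evaluations split across the two
polish stages). The best objective seen is tracked and never increases; a
candidate step is accepted only if it does not worsen the fit.

Identifiability has one failure mode the code flags instead of hiding: a
flat PFS curve at 1 means no exits were observed, so the exit split and the
PD parameters are arbitrary; `converged = FALSE` with a diagnostic is
returned. Because the reference publication's digitised curve coordinates
are not available, the calibrator is validated by round-trip recovery
(model curves in, generating matrix out, within 0.005 per parameter
noiseless at 24 months) and by simulation through the synthetic-data
module, not against the published figures.

## Synthetic patient-level data

No patient-level trial data are deposited, so `simulate_cohort()` generates
pseudo-patients directly from the assumed data-generating process: monthly
geometric sojourns in PFS, a Bernoulli exit split, then geometric survival
in PD, on the integer-month grid with optional administrative censoring.
`km_estimate()` turns a cohort into product-limit OS/PFS curves (via the
survival package). The full pipeline — simulate 20,000 patients, estimate
Kaplan-Meier curves, recalibrate — recovers the generating matrix within
0.01 per parameter in the tests.

What this does and does not show: passing these tests demonstrates the
estimator and calibrator are mutually consistent with the Markov assumption
(exponential-like, time-homogeneous hazards on a monthly grid). Real trial
curves have interval-censored assessments, dropout, treatment switching and
non-constant hazards; none of that is emulated, and agreement here does not
certify behaviour on such data.

## Sensitivity analysis

* **One-way (tornado)** (`run_owsa()`): each registered parameter — drug,
  test, adverse-event and subsequent-therapy costs per arm, both utilities,
  and the discount rate — is varied to ±20% of baseline holding the rest
  fixed, both arms rerun, rows ordered by ICER spread (ties by registration
  order, degenerate zero-spread rows last). Varying `utility_pfs` down 20%
  may legitimately drop it below `utility_pd`; one-way ranges intentionally
  bypass the base-case ordering constraint.
* **Probabilistic** (`run_psa()`): costs are drawn from gamma and utilities
  from beta distributions, matched by method of moments to mean = baseline
  and SD = 20% of baseline (`se_fraction`, exposed). The evidence base
  names the distribution families but no variances; the 20% relative SD
  mirrors the one-way range and is the package's own choice, so published
  acceptability curves can only be matched qualitatively, and the tests
  assert exactly that (acceptability below 0.5 at the WTP threshold in all
  populations; the CPS ≥ 10 curve crosses 0.5 between $150,000 and
  $200,000/QALY). Transition probabilities stay fixed — no Dirichlet draws
  are attempted because no sampling variances are available for them
  either. Each parameter draws from its own RNG substream seeded by a
  stable hash of its name plus the root seed, so adding a parameter leaves
  the other draws untouched, and a fixed seed makes runs bitwise
  reproducible. With transitions fixed, discounted person-time per state is
  a per-arm constant, so each draw's totals are inner products; 10,000
  draws take well under a second.
* **Acceptability** (`ceac()`): at each WTP λ the intervention counts as
  cost-effective in a draw when λ·ΔQALY − ΔCost > 0, strictly — ties go to
  the comparator, so a zero-variance PSA yields probability exactly 0 below
  the base-case ICER and 1 above it. The default grid is $0–250,000 in
  $2,500 steps, always including $11,105.8.

## Problem sizes used by the shipped checks

The test-suite and acceptance-script problem sizes are chosen to keep the
full run in seconds while leaving Monte Carlo error well inside the asserted
tolerances: 60-cycle deterministic runs everywhere; brute-force engine
cross-checks at horizons ≤ 5 (≤ 243 paths); calibration round trips on
24-month curves; 20,000 synthetic patients for end-to-end recovery (KM
standard error ≈ 0.003 at month 12); 10,000 PSA draws as in the reference
analysis.

## Known limitations

* Three-decimal transition inputs bound the achievable ICER precision (see
  above); per-state costs and QALYs are unaffected at the reported
  precision.
* The chemotherapy arm is a single blended comparator, not three regimens.
* No extrapolation beyond 60 cycles, no tunnel states, no time-varying
  hazards, no correlated PSA draws, and no EVPI computation.
* Utilities come from published Western sources; the trial's own
  quality-of-life instruments were never mapped to utilities.
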