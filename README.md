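# hsctbench

Risk-adapted benchmarking of 1-year survival after haematopoietic stem
cell transplantation (HSCT), for registry statisticians and quality
teams who need to compare transplant-centre outcomes fairly across
heterogeneous case mixes.

Raw 1-year mortality differences between centres mostly reflect *who*
was transplanted, not *how well*. hsctbench implements the standard
indirect-standardisation answer: a Cox proportional-hazards case-mix
model is fitted to the whole registry, each centre's observed deaths
within one year (O) are compared with the deaths expected under that
model (E), and the ratio O/E is placed on a funnel plot against the
centre's effective sample size `n_eff = E / p̄`. Exact Poisson tail
probabilities `P(Pois(E) ≥ O)` and `P(Pois(E) ≤ O)` flag centres
outside the multiplicity-adjusted control limits (`α/K`, Bonferroni over
the K benchmarked centres) as worse or better than average.

Around that core the package provides the full registry pipeline:

* **Eligibility** — first transplants only; diagnosis and age rules per
  transplant type; centre gates on membership, mean annual volume
  (≥10 allo, ≥5 auto) and registry-vs-Activity-Survey reporting
  (>80%); a follow-up completeness gate (observed/potential follow-up
  >80%) with green/amber/red traffic lights.
* **Composite risk indices** — the HCT-specific Comorbidity Index from
  17 weighted comorbidities with its reporting conventions, and an
  adapted Disease Risk Index (MDS substage rule, MRC-style AML
  cytogenetics, extra low-risk diagnostic groups, imputation of
  undefined DRI as intermediate); both tables ship as editable YAML.
* **Two imputation schemes** — chained equations (5 datasets × 10
  sweeps, Nelson–Aalen cumulative hazard + event indicator as outcome
  carriers, Rubin pooling) for estimating the model, and single-value
  imputation among 12-month survivors for prediction, which
  deliberately biases a centre's E downward when its data are
  incomplete.
* **A synthetic multi-centre registry generator** with known ground
  truth (true log hazard ratios, per-centre hazard factors, uncensored
  365-day death indicators), so every stage is testable without access
  to any real registry.
* **Reporting** — per-centre HTML reports plus a machine-readable
  CSV/JSON bundle, and a small CLI (`simulate`, `score`, `select`,
  `benchmark`).

## Worked example

```r
library(hsctbench)

reg <- generate_registry(sim_config(n_centers = 30), seed = 2024)
run <- run_benchmark(reg$patients, reg$activity, reg$config$window, seed = 1)
run
#> HSCT benchmark (allogeneic), window 2015-01-01..2019-12-31
#>   3039 input records; 24 centre(s) selected, 24 benchmarked
#>   cohort n = 2784, deaths O = 782, expected E = 762.9, O/E = 1.025
#>   1-year survival 71.3%; flags: 0 worse, 0 better of 24
```

Six of the 30 simulated centres fail the volume or reporting gates; the
24 remaining centres all clear the follow-up gate and are benchmarked.
The cohort O/E of 1.025 sits slightly above 1 because missing case-mix
values are completed from 12-month survivors, which lowers E — the
built-in incentive for complete data. With every centre on-model, none
is flagged.

```r
head(summary(run)$centers[c("center_code", "n", "O", "E", "oe_ratio", "n_eff", "flag")], 5)
#>   center_code   n  O        E  oe_ratio     n_eff   flag
#> 1        C001 190 50 51.10408 0.9783954 186.49819 within
#> 2        C002 125 45 34.98443 1.2862863 127.67148 within
#> 3        C003  83 23 22.11506 1.0400153  80.70624 within
#> 4        C004  84 25 22.63629 1.1044213  82.60841 within
#> 5        C005 164 39 43.19009 0.9029850 157.61702 within
```

Centre C002 observed 45 deaths against 35 expected (O/E 1.29) but stays
inside the funnel: at `n_eff ≈ 128` the adjusted limits are far wider
than a 29% excess. The pooled case-mix model behind E:

```r
summary(run$fit)
#> Pooled case-mix hazard ratios (n = 2784, events = 782, m = 5):
#>                     term    coef     se     hr hr_lower hr_upper       z p_value
#>               age_decade  0.2434 0.0308 1.2756   1.2009   1.3549  7.9092  0.0000
#>  dri_overallintermediate  0.0967 0.1100 1.1016   0.8879   1.3667  0.8791  0.3793
#>          dri_overallhigh  0.4353 0.1280 1.5454   1.2026   1.9859  3.4019  0.0007
#>     dri_overallvery_high  1.0014 0.2987 2.7222   1.5158   4.8886  3.3524  0.0008
#>   hctci_bandintermediate  0.1045 0.0899 1.1102   0.9308   1.3241  1.1625  0.2450
#>           hctci_bandhigh  0.2667 0.1375 1.3057   0.9972   1.7095  1.9394  0.0524
#>                   perf10 -0.1029 0.0360 0.9022   0.8408   0.9680 -2.8634  0.0042
```

Hazard rises by ~28% per decade of age and up to 2.7-fold for very-high
DRI — close to the generator's true log hazard ratios (0.25 per decade;
DRI 0.35/0.70/1.00), as they should be on 2,784 patients.
`plot(run, highlight = "C002")` draws the funnel with inner (nominal)
and outer (adjusted) exact-Poisson limits; `write_bundle(run, "out/")`
emits the CSV/JSON bundle and one HTML report per centre, with
completeness-only reports for centres below the follow-up gate.

## Layout

```
R/                  pipeline stages (schema, simulate, risk-scores,
                    eligibility, imputation, casemix, benchmark,
                    completeness, pipeline/CLI)
inst/extdata/       editable YAML: HCT-CI weights, DRI lookup,
                    eligibility criteria, model specification
inst/scripts/       command-line wrapper
tests/testthat/     unit, property and acceptance tests
vignettes/          methods vignette (model, assumptions, design choices)
```
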