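---
title: "Risk-adapted benchmarking of 1-year HSCT survival: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Risk-adapted benchmarking of 1-year HSCT survival: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Transplant centres reporting to a multi-centre registry differ widely in
the patients they treat. Comparing raw 1-year mortality across centres
would mostly compare case mix, not quality of care. hsctbench implements
a risk-adapted benchmarking pipeline of the kind used for institutional
profiling of haematopoietic stem cell transplantation (HSCT) outcomes:
each centre's observed number of deaths within one year (O) is compared
with the number expected (E) under a case-mix model fitted to the whole
registry, and the O/E ratio is placed on a funnel plot whose control
limits narrow with the centre's effective sample size. Centres outside
the multiplicity-adjusted outer funnel are flagged as performing worse
(upper half) or better (lower half) than average; everything inside is
treated as indistinguishable from the registry average — the funnel
philosophy deliberately avoids league tables.

Because reliable benchmarking presupposes reliable data, the pipeline is
as much about data quality as about outcomes: centres are admitted only
if their registry reporting is consistent with their declared activity,
and 1-year mortality is assessed only where follow-up completeness
clears a gate. Incomplete case-mix data are imputed in a way that is
deliberately unfavourable to the centre, so that completeness is
incentivised rather than rewarded by the imputation.

Autologous and allogeneic transplants are benchmarked fully separately
throughout; `run_benchmark()` drops records of the other type before any
computation, and the package's tests assert this independence.

## Eligibility and the follow-up gate

Patient selection keeps first transplants inside the observation window
and excludes solid tumours in allogeneic transplants, non-haematological
diagnoses in autologous transplants, and paediatric autologous patients.
Patients who receive a second transplant within the first year are *not*
censored at retransplantation; the 1-year endpoint is all-cause
mortality from the first transplant.

Centre selection requires full registry membership, a minimum mean
annual volume over the window, and registry reporting above 80% of the
activity declared in the annual Activity Survey. Where the sources are
silent on boundary behaviour the package fixes conventions and treats
them as part of the method:

* volume thresholds are inclusive — 10 allografts/year and 5
  autografts/year on average qualify;
* the reporting gate is strict (`> 0.80`), computed pooled over the
  window years (a per-year variant is a one-line change around
  `select_centers()`);
* the follow-up outcome gate is strict (`> 0.80`);
* follow-up traffic lights: green `> 0.90`, red `< 0.80`, amber
  otherwise; red and amber centres keep their completeness report, but
  only centres above the outcome gate enter the funnel;
* "paediatric" means age below 18 at transplant.

Follow-up completeness is the ratio of total observed to total potential
follow-up days, with potential follow-up truncated at
`min(365, extraction date - transplant date)`. A death within the
potential window counts as fully observed — a dead patient cannot be
lost to follow-up, and crediting deaths with full follow-up removes any
incentive ambiguity in the ratio.

## Composite risk indices

Two composite case-mix variables are derived from raw record fields, and
both of their tables ship as editable, versioned YAML
(`inst/extdata/hctci_weights.yaml`, `inst/extdata/dri_table.yaml`)
rather than as code, because the weight and cell assignments are
reviewable data.

**HCT-CI.** The HCT-specific Comorbidity Index is the weighted sum of 17
comorbidity categories (weights 1–3), banded low (0), intermediate
(1–2), high (3+). The reporting convention drives its derivation status:
"no comorbidity" scores 0 and is complete; if any comorbidity is flagged
present at least one must be entered, and unlisted ones are assumed
absent (partial derivation); a present flag without entries, or a
missing flag, leaves the score undefined, to be imputed downstream. The
age-adjusted HCT-CI variant is intentionally not used — age is a
covariate of the benchmarking model itself.

**Adapted DRI.** The Disease Risk Index crosses a disease group
(low/intermediate/high) with a stage group (early/advanced) to an
overall class low/intermediate/high/very high. The adaptations
implemented here: MDS other than RAEB-1, RAEB-2 or transformation to AML
is low-risk MDS (disease group low, no cytogenetics required); AML
cytogenetic risk follows the MRC-style favorable/intermediate/adverse
grouping; cytogenetics count as missing when no chromosome analysis is
registered or the result is abnormal with no further detail; five
diagnostic groups outside the original index (bone marrow failure,
inherited disorders, autoimmune diseases, histiocytic disorders,
hemoglobinopathies) short-circuit to overall low; and a record whose
required cytogenetics or stage is missing is imputed overall
*intermediate* and flagged with its reason. The cytogenetics requirement
is applied to AML and to non-low-risk MDS only — under the adaptation,
low-risk MDS is classified without karyotype information. The same index
is applied to autologous transplants, for want of a validated
autologous-specific alternative. The index depends only on diagnosis,
stage and cytogenetics — never on age, conditioning, graft source or
donor type — and the test suite asserts that invariance.

## Imputation: two schemes with different purposes

Missing case-mix values are handled twice, differently, on purpose.

**Estimation (MICE).** The case-mix model is fitted on `m = 5` datasets
completed by chained equations with 10 sweeps each. Each conditional
model regresses one variable on all other case-mix covariates (the full
predictor matrix) plus two outcome carriers: the marginal Nelson–Aalen
cumulative hazard evaluated at the patient's horizon-truncated follow-up
time, and the event indicator. Continuous variables use Bayesian
normal-model draws; categorical variables use bootstrap-plus-multinomial
draws (`nnet::multinom`). Including the outcome carriers keeps the
imputation compatible with the survival model, so the pooled hazard
ratios are estimated without the attenuation that outcome-free
imputation would cause. The chained-equation engine is implemented in
the package (initialisation from observed margins, fixed variable order,
deterministic given a seed); `mice_impute()` aborts, naming the
variable, if one is 100% missing and cannot be initialised.

**Prediction (single-value).** After the model is fitted, expected
probabilities for benchmarking are computed on a singly completed
dataset: each missing continuous value is replaced by the median, each
missing categorical value by the mode, computed once among the 12-month
survivors of the benchmarked cohort of the same transplant type. Mode
ties break lexicographically on the label, making the completion
deterministic. Because survivors are a relatively healthy
sub-population, this lowers the predicted death probability of
incompletely reported patients, lowers the centre's E and pushes O/E
upward — the deliberate incentive for centres to complete their data.
The acceptance suite verifies this direction on simulation: with
missingness concentrated in sicker patients, mean E under single-value
imputation does not exceed the oracle complete-data E, and mean O/E does
not fall below it.

## The case-mix model and expected events

`fit_casemix()` fits a Cox proportional-hazards model for death within
365 days to each completed dataset (Breslow ties and baseline), pools
coefficients by Rubin's rules
(`T = W + (1 + 1/m) B`), and averages the Breslow baseline cumulative
hazard across imputations on a common time grid. The default covariates
— age per decade (centred at 55), overall DRI, HCT-CI band, and
performance score per 10 points (centred at 90) — are an editable list
in `inst/extdata/model.yaml`; the parsimonious default matches the
structure of the synthetic generator so that parameter recovery is
testable against ground truth. A separated or non-converged covariate
aborts the fit with its name.

Expected probabilities follow the fixed-horizon transform

```
p_i = 1 - exp(-Lambda0(tau_i) * exp(lp_i))
```

with the evaluation time `tau_i` implementing the follow-up adjustment:
patients who died within the horizon contribute `tau = 365` (a death is
fully observed), censored patients contribute their censoring time. A
centre that loses patients early therefore accrues less expected — and
less observed — mortality, symmetrically. On the fitting sample the
expected total is calibrated in the large: the acceptance suite requires
`|sum(O) - sum(E)| / sum(O) < 1%` on complete data.

## Funnel limits and flags

Per centre, `O` and `E` are summed and the effective sample size is
defined as `n_eff = E / p_bar`, where `p_bar` is the cohort mean
expected death probability — expected deaths rescaled to patient units,
which makes centres with poorer follow-up correctly look smaller. This
definition is a documented convention of the package.

Flags come from an exact Poisson test of O given mean E: upper tail
`P(Pois(E) >= O)`, lower tail `P(Pois(E) <= O)`, compared with half the
multiplicity-adjusted level `alpha/K` (Bonferroni over the K benchmarked
centres of the same transplant type; `BH` and `none` are available
behind a flag). The exact test is used instead of a normal approximation
because small centres dominate a transplant registry. O/E is plotted as
0 when O = 0; the lower-tail test is still computed from E.

The plotted limits invert the same exact tails through the gamma
representation of the Poisson distribution
(`P(Pois(E) >= k) = pgamma(E, k)`), solving for a continuous `k`. This
yields smooth limits, monotone in `n_eff`, that agree with the integer
tests to within the discreteness of the Poisson — integer-valued exact
limits would sawtooth. Inner curves are drawn at the nominal level,
outer curves at the adjusted level; flags always come from the exact
integer tails, not from the curves.

## The synthetic registry

`generate_registry()` draws a registry whose statistical structure
matches the model's assumptions by construction, with every ground truth
retained (`truth`: per-patient linear predictor and uncensored 365-day
death indicator, per-centre hazard factor; `patients_complete`: the
table before missingness injection).

* **Centres and volume:** log-normal annual volumes (default ~20
  allografts/centre/year across 50 centres), yearly Poisson counts.
* **Death process:** exponential within the 1-year horizon, rate
  `h0 * exp(lp) * centre effect`, with `h0 = 5.5e-4`/day (about 18%
  baseline 1-year mortality before case mix, in the range registries
  report for allogeneic HSCT). The proportional-hazards model is
  agnostic to the baseline shape; the exponential is the simplest
  correct choice for testing.
* **True coefficients:** age +0.25 per decade, DRI
  0/0.35/0.70/1.00, HCT-CI band 0/0.20/0.45, performance score
  −0.10 per 10 points — hazard-ratio magnitudes typical of published
  transplant risk indices.
* **Loss to follow-up:** per-centre exponential censoring hazards
  (log-normal around 1.2e-4/day, roughly 4%/year), plus administrative
  censoring at the extraction date.
* **Missingness:** injected after outcome generation, missing at random
  given transplant year, centre, and (optionally) observed disease
  stage; the default per-year linear trends emulate a registry whose
  completeness improves across the window — comorbidities 49% → 9%
  missing, cytogenetics 25% → 7%, stage ~3%, performance 20% → 10% —
  so that the completeness summaries show the familiar pattern of
  HCT-CI availability rising from about half to about nine-tenths.
* **Activity:** survey counts are generated counts inflated by an
  under-reporting factor (default 0.95), so reporting ratios sit above
  the gate unless configured otherwise.
* **Day conventions:** deaths are recorded on the day they occur
  (rounded up), censoring at the last completed day, so "death within
  365 days" is exactly `death_days <= 365`.

What the generator does **not** emulate: real marginal distributions of
any specific registry, correlated comorbidity clusters, non-proportional
or time-varying hazards, informative (outcome-dependent) loss to
follow-up, and missingness that is not at random. Passing tests
therefore demonstrate that the machinery is correct under its stated
assumptions — not that those assumptions hold in any particular
registry.

## Numerical and design choices

* One year is 365 days everywhere; the choice is fixed in
  `criteria.yaml` rather than code.
* Dates are ISO-8601 by default; alternate formats and enum spellings
  of source registries are mapped in the schema configuration, not in
  code. Values outside the dialect become the field's missing level
  with a warning; rows violating invariants become structured
  rejections, and accepted plus rejected rows always partition the
  input.
* Percentages in the distribution ledger round half-up to integers.
* Mode ties in single-value imputation break lexicographically.
* The baseline cumulative hazard of `~ 1` fits equals the Nelson–Aalen
  estimator exactly (Breslow with no covariates), which the tests use
  as a closed-form cross-check; the Nelson–Aalen implementation itself
  is cross-checked against `survival::survfit`.
* One model is fitted per transplant type with diagnosis-level risk
  entering through the DRI; fitting per-diagnosis models is possible by
  filtering the input, but is not the default.
* Survivor statistics for single-value imputation are computed per
  transplant type, since the two benchmarks never share data.

## Problem sizes in the tests

The test suite and the acceptance script run entirely on generated
data, at sizes chosen to give the Monte-Carlo assertions comfortable
margins while staying desk-scale: cohorts of roughly 5,000 patients in
50 centres for parameter recovery (20% MAR missingness, MICE 5×10) and
calibration; 200 replicates of 100-centre on-model registries for null
funnel coverage; 100 replicates for detecting a centre with a threefold
hazard and ~100 patients; 50 replicates for the imputation-incentive
direction. Determinism is asserted by running the pipeline twice under
one seed.

## Known limitations

The funnel's exact-Poisson model treats E as known, ignoring the
estimation uncertainty of the case-mix fit; with thousands of patients
behind the fit this is second order, but for very small registries a
hierarchical model would be more honest (and is out of scope here). The
Bonferroni adjustment is conservative when centres are many and small.
DRI and HCT-CI cell assignments are shipped defaults and should be
reviewed against the index versions a registry actually uses. The
single-value imputation is intentionally biased; its output must not be
read as an unbiased prediction of any patient's risk.
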