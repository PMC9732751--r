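---
title: "Societal-perspective costing and avoided-travel emissions: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Societal-perspective costing and avoided-travel emissions: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telecost)
```

## The analysis

`telecost` implements a cost-minimization analysis for two-arm randomized
trials that substitute in-clinic follow-up visits with video consultations.
Cost-minimization presumes clinical equivalence of the two arms, so the
entire comparison is a costing exercise — and from the societal perspective
the relevant costs are the patient-side and environmental ones, not the
payer's consultation fees (which are equal across arms in any case under a
substitution design):

1. **Travel costs.** A clinic visit costs `cost_per_km * 2 * d` euros for a
   one-way distance `d`, the factor 2 for the round trip. Distances are
   stored one-way throughout the package; the doubling lives inside the cost
   and emission operations. The telemedicine arm incurs an actual travel
   cost of exactly zero; the cost it avoided is computed with the same
   formula and carried as a *counterfactual* that never enters totals.

2. **Time costs.** Patient time — whether spent travelling, waiting, or in
   the appointment — is unpaid work or leisure time and is valued at a flat
   `time_value_per_hour`. Travel time is doubled (round trip); the *total*
   time spent on the appointment is valued as a whole.

3. **Production losses.** Each employed patient who reports a work absence
   for the appointment is costed at one full average working day:
   `gross_hourly_wage * working_hours_per_day`. The arm total is
   `absences * per-day loss` and the arm mean divides by the number of
   *employed* patients, since the loss is undefined for the unemployed.
   Full-day valuation is the interpretation consistent with the arm totals
   being exact integer multiples of the per-absence loss; the sensitivity
   scenarios (8.2 h full-time, 3.9 h part-time) bound the error from not
   knowing individual working hours.

**Totals by employment status.** The unemployed-patient total is
`travel cost + total time cost`; the employed-patient total adds the mean
production loss per employed patient. Travel-time and waiting-time costs
are reported as separate lines but deliberately *not* added: both are
contained in the total time spent on the appointment, and adding them would
double-count. This is the only composition under which the component lines
and the totals of the standard cost table are mutually consistent.

**Emissions and environmental costs.** A substituted visit avoids
`2 * d` passenger-kilometers (pkm) of car travel. Per-pollutant masses are
`factor[g/pkm] * pkm / 1000` kg for five pollutants (greenhouse gases 152,
carbon monoxide 0.94, volatile hydrocarbons 0.15, nitrogen oxides 0.38,
particulates 0.006 g/pkm). The factors are published *already normalized*
to an average car occupancy of 1.4 passengers; the occupancy is stored as
provenance metadata and never divides anything — the per-patient arithmetic
of the source data (152 g/pkm × 74 pkm = 11.248 kg) confirms this reading.
Environmental cost is `env_cost_per_pkm * pkm`, with the per-pkm rate an
independent agency parameter rather than something derivable as carbon
price × greenhouse-gas factor (0.152 kg/pkm × 195 EUR/t ≈ 0.030 EUR/pkm,
well below the published 0.05045 EUR/pkm — the agency rate covers damages
beyond CO2-equivalents). The two (carbon price, rate) pairs
{195 → 0.05045, 680 → 0.12885} are therefore bundled as linked presets, and
overriding one member without the other is flagged.

**Annual extrapolation.** `patients_per_week * weeks_per_year` substituted
visits per year, each avoiding the round trip of the *pooled* mean one-way
distance (the n-weighted mean of the two arms' distance means). The default
of 48 operating weeks per year makes 8 patients/week equal 384 patients
annually, matching the source analysis; it is configurable. The model is
strictly linear in pkm, so the 16-patients-per-week scenario is exactly
twice the 8-patients one — a property the tests assert as an identity.

## Trial statistics

Continuous between-arm comparisons use the Mann-Whitney U test: the exact
null distribution when `n1 * n2 <= 400` and the pooled sample is tie-free,
otherwise the normal approximation with midrank tie correction and
continuity correction; the route taken is recorded in the result. A pooled
sample with no variation at all returns p = 1. Categorical comparisons use
the Fisher exact test with the two-sided minimum-likelihood rule (sum of
hypergeometric point probabilities no larger than the observed table's).
The a priori sample size for a two-sided two-sample t test is found by
iterating n through the noncentral t power function (noncentrality
`d * sqrt(n/2)` on `2n - 2` degrees of freedom) to the smallest integer
reaching the requested power; the suite cross-checks it against
`stats::power.t.test` and against a Monte-Carlo power simulation.

## The synthetic cohort generator

Real questionnaire data of this kind are rarely shareable, so the package
includes a generator whose defaults *are* the study conditions of the
motivating trial: 26 patients per arm; employment 20/26 (telemedicine) and
19/25 (control, one missing item); work absences 1/20 and 3/19 among the
employed; category frequencies for indication, age band and sex; and per-arm
target (mean, SD) pairs for the five continuous items.

Design choices, and why:

* **Right-skewed marginals.** Distances and waiting times are right-skewed
  (published medians sit below means), so the default family is the
  lognormal, moment-matched on the natural scale; a zero-truncated normal is
  offered as an alternative, with its parent parameters solved numerically so
  the *truncated* distribution hits the target moments.
* **Systematic quantile sampling.** Values are drawn by inverse CDF on
  midpoint-stratified uniforms (one point per probability stratum, randomly
  assigned to patients). Each arm is thus a systematic sample of the fitted
  distribution: sample moments track the targets closely at moderate n —
  within a few percent at 2000 per arm even for the heavy-tailed distance
  marginal, where plain iid sampling would need far larger n for the SD.
  The cost is that the extreme upper tail beyond the top stratum is never
  drawn, which biases small-cohort SDs slightly low.
* **Within-patient dependence.** Travel time should grow with distance. The
  generator couples the two via a Gaussian copula on the ranks (correlated
  normal scores decide which stratum each patient receives; default
  correlation 0.8), which induces a strong positive rank correlation while
  leaving both marginals exactly on their matched families. A multiplicative
  distance × speed-noise construction was considered and rejected: with the
  distance coefficient of variation near 0.87, the product's dispersion
  already exceeds the travel-time target before any noise is added, so that
  design cannot keep both marginals on target.
* **Missingness.** Per-item missingness (default: none in the telemedicine
  arm, 1/26 in the control arm) emulates incomplete questionnaires; all
  aggregation is per-variable over non-missing values, never whole-record
  deletion, so per-variable denominators vary as they do in real tables.

What the generator does **not** emulate: the published medians/IQRs
(a two-parameter family moment-matched to mean and SD cannot also be pinned
to them — the defaults' implied medians are close but not equal), any joint
structure beyond the distance–travel-time coupling, and real questionnaire
quirks such as digit preference (distances reported as multiples of 5).
Passing tests on synthetic cohorts therefore demonstrate the pipeline's
arithmetic and invariances, not distributional realism of any particular
patient population.

## Numerical conventions

* **Full precision inside, reporting precision at the edge.** All arithmetic
  is double precision; nothing is rounded until a table is printed or
  rendered. Published cost tables, however, round each component to cents
  *before* summing (e.g. 18.95 + 41.28 + 32.40 = 92.63, which full-precision
  components miss by under a cent), so totals are exposed both ways:
  `total` (full precision) and `total_rounded_components` (sum of
  cent-rounded components, the reporting convention and the default of
  `total_cost_per_patient()`). The two differ by less than EUR 0.01.
* **Sample SD** (n−1) throughout; every cost is a scale transform of its
  input, so cost SDs are the input SDs times the same factor.
* **Quantiles** use linear interpolation between order statistics
  (R type 7). Published tables rarely state their quantile rule; under a
  different rule IQRs can differ in the last digit, which is why the
  packaged reference summary stores the printed quartiles verbatim rather
  than recomputing them.
* **Degenerate inputs.** A zero-variance Mann-Whitney sample yields p = 1;
  an arm with zero records errors naming the arm; a zero-patients-per-week
  scenario warns and returns zeros; `n_employed = 0` makes the mean
  production loss undefined and errors.
* **Annual figures tolerance.** The published annual outputs imply an
  unrounded pooled mean distance (≈ 34.35 km) that cannot be recovered from
  the printed, rounded arm means (which give 34.343 km). The pipeline
  computes from the printed means and reproduces the annual figures within
  0.1%; the tests assert that band rather than tuning the distance to hit
  the printed numbers.

## Problem sizes in the test suite

The suite exercises generation at up to 2000 patients per arm for the
moment-recovery property and 5000 for a standard-error check, and the
Monte-Carlo power oracle uses 100,000 replicated t tests per sample size —
sizes chosen so each property is tested with comfortable statistical margin
while the whole suite stays fast on one CPU.

## Limitations

The package prices no payer-side costs (consultation fees, software
licences), no companion time, no QALYs, and no emissions of the digital
infrastructure itself; public-transport trips are excluded from car-emission
sums (their records are retained and flagged). The deterministic sensitivity
engine substitutes fixed alternative parameter values; probabilistic
sensitivity analysis is out of scope. These boundaries mirror the societal
costing framework the package implements rather than technical constraints.
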