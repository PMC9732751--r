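# telecost

Societal-perspective cost-minimization and avoided-travel emissions analysis
for two-arm telemedicine trials.

When a video consultation substitutes an in-clinic follow-up visit, the
clinical outcome is (by design of such trials) equivalent, so the comparison
reduces to costs — and from the societal point of view those costs are not
the payer's fees but the patient's travel, the patient's time, the
production lost to work absences, and the environmental damage of the
avoided car trip. `telecost` implements that full accounting for a
randomized telemedicine-vs-control trial, from patient-level questionnaire
records (or published group summaries) to report tables and deterministic
sensitivity scenarios.

## The model

For a patient with one-way home-to-clinic distance *d* (km), one-way travel
time *t*, waiting time *w*, and total appointment time *T* (minutes), with
unit costs *c*km (EUR/km) and *v* (EUR/h):

- **Travel cost** = *c*km · 2*d* (round trip; zero actual cost in the
  telemedicine arm, with the avoided cost kept as a counterfactual);
- **Time costs** = *v* · 2*t*/60, *v* · *w*/60 and *v* · *T*/60 for travel,
  waiting and total time;
- **Production loss** = one full working day per absent employed patient,
  valued at the gross hourly wage × average daily hours (human-capital
  approach); arm total = absences × per-day loss, mean = total / employed;
- **Totals by employment status**: unemployed = travel + total-time cost;
  employed adds the mean production loss per employed patient. Travel-time
  and waiting-time costs are reported but not added — they are subsets of
  the total appointment time.

The avoided car trip of 2*d* passenger-kilometers (pkm) is converted to
emissions with per-pkm factors (at average occupancy 1.4): 152 g/pkm
greenhouse gases, 0.94 CO, 0.15 volatile hydrocarbons, 0.38 NOx, 0.006
particulates; and to environmental costs at an agency damage rate per pkm
that comes in two linked presets (0.05045 EUR/pkm at a carbon price of 195
EUR/t CO2e; 0.12885 EUR/pkm at 680 EUR/t CO2e). An annual model scales this
to `patients_per_week × weeks_per_year` substituted visits at the pooled
mean distance of the two arms.

Supporting trial statistics are included: Mann-Whitney U (exact for small
tie-free samples), the Fisher exact test, and the a priori sample size of a
two-sided two-sample t test via the noncentral t distribution.

## Worked example

The package ships the published arm-level summary of the motivating German
follow-up-care trial (52 analyzed patients, knee and shoulder indications),
so the whole pipeline runs without patient-level data:

```r
library(telecost)
report <- run_base_case(reference_summary())
print(report)
#> Societal-perspective analysis report (aggregate input; n = 26 + 26)
#>
#> Costs per appointment (euros):
#>           component telemedicine_mean telemedicine_sd control_mean control_sd difference
#>        Travel costs              0.00            0.00        18.95      13.57      18.95
#>   Travel time costs              0.00            0.00        18.56      11.14      18.56
#>  Waiting time costs              1.79            1.82         9.83       7.34       8.04
#>    Total time costs              5.85            2.77        41.28      21.27      35.43
#>     Production loss            205.18              NA       615.54         NA     410.36
#>
#> Headline saving per employed patient: EUR 76.52
#> Avoided greenhouse gases per patient: 11.248 kg (EUR 3.73 environmental cost)
```

A video consultation saves an employed patient EUR 76.52 per appointment
(EUR 92.63 in clinic vs EUR 16.11 by video) and avoids 11.248 kg of
greenhouse-gas emissions from the 74 km round trip. The deterministic
sensitivity scenarios re-run only the stage they touch:

```r
res <- run_scenarios(report, default_scenarios())
res$equal_weight_carbon
#> Scenario 'equal_weight_carbon' (affects: emissions, annual)
#>   carbon_price_eur_per_tonne_co2e = 680
#>   env_cost_per_pkm = 0.12885
#>   annual greenhouse gases: 4009.08 kg, environmental cost EUR 3398.49
```

Synthetic patient-level cohorts with the same statistical structure are one
call away (`generate_cohort(cohort_config(), seed = 1)`), and
`render_report()` writes the tables as CSV or markdown. A small command-line
front end lives at `inst/cli/telecost.R` with verbs `simulate`, `analyze`
and `reproduce`.

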