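# dhicost

Cost-of-illness modelling for surgically treated diabetic hand infections.

Diabetic hand infections are rarer than diabetic foot ulcers but carry
comparable per-patient costs and far less attention. `dhicost` is aimed at
health-economics and clinical-epidemiology analysts who want to model the
direct and indirect one-year costs of these infections: it packages a
synthetic cohort generator calibrated to a published 75-patient surgical
case series, a bottom-up cost aggregator with human-capital indirect
costs, a currency/inflation restatement pipeline, a Monte Carlo cost
simulator with probabilistic sensitivity analysis (PSA), and tie-corrected
Kruskal–Wallis comparisons of visits and costs across surgical-intervention
groups.

## The model

**Bottom-up costing.** Each patient carries itemized cost lines
(medications, ward stay, ICU, outpatient follow-up, surgery) tagged with
the currency and year they were incurred. Indirect cost follows the
human-capital approach:

    indirect = incapacity_days × daily_wage

Every amount is restated in Q4-2022 US dollars in two fixed steps — FX
first, CPI second:

    usd_y   = amount_y / fx[y]            (annual-average rate, local/USD)
    usd_tgt = usd_y × cpi[2022Q4] / cpi[y]

**Monte Carlo simulation.** Five uncertain inputs are drawn per iteration —
hospitalization cost ~ Triangular(8000, 12000, 18000 TRY), surgical cost ~
Normal(6500, 1200 TRY), antibiotic duration ~ Uniform(10, 21 days),
re-infection rate ~ Beta(3, 20), lost workdays ~ Triangular(7, 14, 28
days) — and composed linearly:

    total = hosp + surg + abx_days·c_abx + I(reinfect)·c_episode + lost_days·wage

where the re-infection indicator is two-stage (a Beta-distributed
probability, then a Bernoulli event), so rate uncertainty propagates. The
default run is 10,000 iterations summarized as the mean with a percentile
95% CI; PSA reports the Spearman rank correlation of each input's draws
with the totals. The three unit-cost coefficients (`c_abx`, `c_episode`,
`wage`) are user configuration, with documented placeholder defaults.

**Group comparison.** The Kruskal–Wallis H statistic on average ranks with
the standard tie correction, with p-values from the χ²(k−1) approximation,
from full enumeration of group assignments when feasible, or from random
permutations.

## Worked example

```r
library(dhicost)

cohort <- build_reference_fixture()   # deterministic 75-patient cohort
cohort
#> <dhi_cohort: 75 patients, 328 cost items>
#>   Drainage                                 24
#>   Drainage + VAC                           4
#>   Open Amputation + VAC                    5
#>   Ray Amputation                          18
#>   ...

compare_by_intervention(cohort, "outpatient_visits")
#> Comparison of outpatient_visits by surgical intervention
#>   Drainage                                24  20.58 ± 12.07 17.00 (7.00–59.00)
#>   Drainage + VAC                           4  18.75 ± 2.99 18.00 (16.00–23.00)
#>   ...
#>   K-W 6.748, p = 0.456 (chi2_approx)

tables <- example_conversion_tables() # packaged FX/CPI demo series
run_simulation(scenario_model(seed = 1L), tables)
#> <simulation_result: 10000 iterations, USD-2022Q4>
#>   mean total 1991.25, 95% CI [1539.81, 2655.78] (percentile)
#>   sensitivity (|Spearman rho|): lost_workdays=0.51, hospitalization_cost=0.48,
#>     surgical_cost=0.26, antibiotic_days=0.18, reinfection_rate=0.11
```

The fixture reproduces every published marginal count exactly (75
patients; 11 female / 64 male; 62 type-2 diabetics; intervention groups of
24/4/5/18/7/10/6/1; 15 patients with ≥30 outpatient visits; pooled median
of 20 visits). The Kruskal–Wallis line compares visit counts across the
eight intervention groups; the simulation line is the mean one-year cost
per patient under the default scenario after conversion to Q4-2022 USD,
with the PSA ranking showing which inputs drive the spread. Under the
placeholder unit-cost coefficients the simulated total is dominated by
lost workdays and hospitalization; set the coefficients to local values
before interpreting magnitudes.

A thin command-line wrapper ships in `inst/cli/dhicost`:

```sh
Rscript inst/cli/dhicost all --out run1 --seed 7
Rscript inst/cli/dhicost generate --cohort generate --seed 7 --out cohort.csv
```

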