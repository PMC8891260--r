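# vaxtea

Techno-economic assessment of pandemic-response vaccine manufacturing
platforms under uncertainty.

`vaxtea` is for process economists, vaccine manufacturers and policy
analysts who need to compare the three genetic vaccine platform
technologies — adenovirus-vectored (AVV), messenger RNA (mRNA) and
self-amplifying RNA (saRNA) — on productivity, cost and capacity, while
accounting for the large design and operational uncertainties that
dominate pandemic-response manufacturing.

## What it computes

Each platform's uncertain input factors *X* (production scale, batch
failure rate, titre net of downstream losses, cap-analogue price for RNA,
labour rate, drug-substance amount per dose, QC cost share) carry
triangular or uniform distributions. A Sobol quasi-random design of
n = 10,000 scenarios is propagated through a lumped batch model to eight
KPIs per scenario:

    doses/yr   = scale × titre × (1 − failure) × batches/yr / dose
    CapEx      = CapEx_ref × (scale / scale_ref)^0.6
    OpEx       = annualised CapEx + labour·(1 + QC%) + materials × batch starts
    cost/dose  = OpEx / doses-per-year

Variance-based global sensitivity analysis attributes each KPI's variance
to the factors via first-order and total-effect Sobol indices
(Saltelli A/B/AB design, Jansen estimators, bootstrap CIs), with an
RS-HDMR orthonormal-polynomial metamodel as a validated surrogate:

    S_i  = V_{X_i}( E[Y | X_i] ) / V(Y)        (first order)
    S_Ti = E[ V(Y | X_{~i}) ] / V(Y)           (total effect)

Capacity projections linearly extrapolate single-line performance to
multi-billion-dose targets (1e9/yr, the 2.4e9 annual booster demand, the
11.3e9 global gap), with and without fill-to-finish lines.

## Worked example

```r
library(vaxtea)

run <- run_pipeline("sarna", n = 10000)   # full saRNA uncertainty analysis
glance(run)
#> # A tibble: 1 × 8
#>   platform     n median_doses_per_year median_specific_productivity
#> 1 sarna    10000          11885411037.                   721255976.
#>   median_time_to_target_years median_cost_per_dose median_required_scale ...
#> 1                      0.0841               0.0425                  1.39
```

A single saRNA line is predicted to produce one billion drug-substance
doses in a median 0.084 years (IQR 0.042–0.168), at a median specific
productivity of 721 million doses per litre of bioreactor working volume
per year — meeting the 1e9 doses/yr target needs a median of only ~1.4 L
of total working volume. The deterministic baseline cost per dose,
including fill-to-finish:

```r
baseline_cost_per_dose("avv")             # filled into 10-dose vials
#>   platform fill_finish doses_per_year ds_cost_per_dose ff_cost_per_dose cost_per_dose
#> 1 avv      vial10          210517241.            0.351            0.189         0.540
```

i.e. 0.35 USD of drug-substance cost plus 0.19 USD of filling per dose.
Sensitivity analysis and the surrogate:

```r
gsa <- run_gsa("avv", n = 1024)           # Si/St per factor per KPI
additivity_gap(gsa)                       # interaction share per factor
autoplot(gsa)

scen <- sample_scenarios(platform_factors("mrna"), 10000)
kpis <- simulate_kpis(scen)
fit  <- fit_rshdmr(scen, log(kpis$doses_per_year))
glance(fit)                               # training R^2, coefficients
```

## Acceptance script

`scripts/acceptance.R` re-runs the whole pipeline from scratch against
the installed package — 10,000-scenario designs for each platform through
production, cost and projection, plus the deterministic AVV baseline —
and writes the headline quantities (median times to one billion doses,
specific productivities, required AVV scale, saRNA CapEx, mRNA OpEx and
batch counts, baseline AVV cost per dose) as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The scenario designs are quasi-random and reproducible from their
metadata; `--seed` pins the RNG for any pseudo-random component.

## Package layout

- `R/` — sampler (`sobol_points`, `sample_scenarios`), production model
  (`simulate_production`, `time_to_doses`), cost model (`simulate_costs`,
  `capex_estimate`), fill-to-finish (`ff_annual_doses`,
  `locate_bottleneck`), GSA (`saltelli_design`, `sobol_indices`,
  `fit_rshdmr`), projections (`project_resources`, `booster_demand`) and
  orchestration (`run_pipeline`, `summarise_distribution`).
- `inst/extdata/` — the factor distributions and the frozen calibration
  constants, both JSON.
- `vignettes/techno-economics.Rmd` — the model, its assumptions,
  calibration procedure and limitations.
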