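---
title: "Techno-economic uncertainty analysis of vaccine production platforms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Techno-economic uncertainty analysis of vaccine production platforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vaxtea)
```

## The problem

Pandemic response is rate-limited by vaccine manufacturing. Three platform
technologies dominated the COVID-19 response: adenovirus-vectored (AVV)
vaccines made in mammalian cell culture, and messenger RNA (mRNA) and
self-amplifying RNA (saRNA) vaccines made by cell-free in vitro
transcription and formulated in lipid nanoparticles. The platforms differ
by orders of magnitude in scale, dose and batch cadence, so comparing them
fairly requires putting all three through one uncertainty-aware
techno-economic model and comparing distributions, not point estimates.

`vaxtea` implements that comparison as a tested pipeline:

1. **Uncertainty model** — each platform has six (AVV) or seven (RNA)
   uncertain input factors with triangular or uniform distributions:
   production scale, batch failure rate, titre, cap-analogue price (RNA
   only), labour rate, drug-substance amount per dose, and QC/QA cost
   share. Sampling is quasi-random (Sobol sequences).
2. **Production and cost model** — a lumped, calibrated batch model maps
   every scenario to eight KPIs: CapEx, OpEx, batches/yr, amount/batch,
   amount/yr, doses/batch, doses/yr and cost/dose.
3. **Global sensitivity analysis** — Sobol first-order and total-effect
   indices of every factor on every KPI, with an RS-HDMR polynomial
   metamodel as a validated surrogate.
4. **Projection** — linear extrapolation of single-line performance to
   multi-billion-dose targets, with and without fill-to-finish.

## The uncertainty model and the scenario generator

The factor distributions are shipped as data
(`inst/extdata/factor_sets.json`) and loaded with `platform_factors()`.
Triangular factors place the highest probability on the central (baseline)
value; the batch failure rate and the QC cost share — genuinely poorly
constrained — are uniform. Titre is defined **net of downstream recovery
losses**: one factor carries the combined variation of bioreactor titre
and purification yield, so no separate recovery factor exists anywhere in
the model.

```{r factors}
platform_factors("sarna")
```

Scenarios are generated by mapping an unscrambled Sobol point set through
each factor's inverse CDF. The generator is implemented in the package
(Joe–Kuo direction numbers, dimensions up to 16) because no
low-discrepancy sequence package is otherwise available; it is verified
bit-for-bit against an independent reference implementation in the test
suite. Conventions, fixed once:

* the all-zeros first point is skipped (`skip = 1` by default) to avoid a
  degenerate corner scenario; the skip count is recorded in the design
  metadata, and `(n, skip)` fully reproduce any design;
* factors are sampled independently — no correlations are asserted
  anywhere in the uncertainty model;
* the headline analyses use designs of n = 10,000 scenarios.

```{r scenarios}
scen <- sample_scenarios(platform_factors("mrna"), n = 1000)
summary(scen$dose)  # micrograms of mRNA per dose, range 5-150, mode 30
```

What the generator emulates is the *stated* uncertainty in process design
and operation: marginal ranges and shapes for each factor. What it does
not emulate: temporal correlation within a campaign, learning effects,
supply-chain shocks, or correlated failures across factors. A green test
against this world therefore establishes that the model chain is
implemented correctly under the declared distributions — not that the
distributions themselves are the truth.

## Production model

Per scenario, on one production line:

* batch starts/yr = operating days / batch cycle time (fractional batches
  allowed — these are campaign averages);
* released batches/yr = starts × (1 − failure rate); a failed cGMP batch
  is discarded whole, yielding no product, but still consumes its
  materials (see costs);
* amount/batch = scale × titre (titre is net of recovery, so no further
  loss factor);
* doses/yr = amount/yr / dose amount; specific productivity = doses/yr per
  litre of bioreactor working volume;
* time to a dose target = target / doses-per-year, excluding QC lead time.

Batch cycle times and operating days are **calibration constants**, not
printed process facts: the lumped model absorbs all unit-operation detail
into four numbers per platform (cycle time, operating days, crew size,
reference CapEx). They were tuned once so that the 10,000-scenario design
medians reproduce published median estimates of specific productivity for
the three platforms, then frozen in `inst/extdata/platform_config.json`:

| platform | cycle time | operating days | rationale |
|---|---|---|---|
| AVV | 14.5 d | 330 | mammalian seed train + culture + downstream |
| mRNA | 0.75 d | 330 | cell-free synthesis, parallelised LNP formulation |
| saRNA | 0.65 d | 330 | as mRNA, smaller volumes turn around faster |

## Cost model

CapEx per line follows the classic power law
`CapEx = CapEx_ref × (scale / scale_ref)^0.6` (six-tenths rule). Annual
fixed OpEx folds in annualised CapEx (straight-line over 10 years plus 4%
per year maintenance, i.e. 14% of CapEx per year), crew labour at the
scenario's basic labour rate over 8,760 h/yr of coverage, and the QC/QA
share (uniform 30–80%) applied to drug-substance labour only. Variable
OpEx is the material recipe times batch **starts**. The RNA recipe is per
gram of RNA — 0.3 g of 5' cap analogue per gram of RNA at the scenario's
sampled price, plus a lumped 10,300 USD/g for nucleotides, plasmid
template, polymerase, the four LNP lipids and consumables; the AVV recipe
is per litre of working volume per batch (690 USD/L). Ionisable-lipid
licence fees, taxes and discounting are out of scope (nominal USD
throughout).

Reference CapEx values (170 M USD at 2000 L for AVV, 105 M at 30 L for
mRNA, 28 M at 5 L for saRNA) and the recipes are the cost-side calibration
anchors, fitted once against published CapEx/OpEx medians at the
1-billion-dose target and the AVV and saRNA baseline cost-per-dose
figures, then frozen. The calibrated model reproduces the expected
platform signatures, asserted in the tests: AVV OpEx is fixed-cost
dominated (>50% facility + labour at central values), RNA OpEx is
variable-cost dominated (materials).

```{r baseline}
baseline_cost_per_dose("avv")   # 10-dose vials
baseline_cost_per_dose("sarna") # 5-dose vials
```

### A known calibration tension

One published anchor is irreconcilable with the others under any cost
model of this family: a baseline mRNA cost per dose of ~2.4 USD cannot
coexist with a design-median OpEx of ~720 M USD/yr at 1e9 doses/yr and a
median specific productivity of 36×10⁶ doses/L/yr. Cost per dose in this
model is invariant to line replication, and the 30 µg baseline dose sits
*below* the ~57 µg design median, so the baseline must price *below* the
median scenario (~0.7 USD/dose), not 3× above it. The published figures
evidently mix baseline facility models with different utilisation than
the design medians imply. We calibrate to the design medians and the AVV
and saRNA baselines; the mRNA baseline acceptance check is implemented
faithfully and left failing, with this explanation.

## Fill-to-finish

Vial lines run at 400 containers/min at 60% overall equipment
effectiveness over a continuous 525,600 min/yr (OEE absorbs all
downtime); the published line rate is ambiguous between doses and
containers per minute for multi-dose vials, and the configuration makes
the unit explicit: containers. A 10-dose vial line therefore fills ~1.26
billion doses/yr and a 5-dose line half that — which is why a single
5-dose line becomes the bottleneck for a baseline saRNA drug-substance
line (~12 billion doses/yr), while baseline AVV and mRNA lines remain
drug-substance-limited. `locate_bottleneck()` applies strict `min()`
semantics with ties to drug substance. Fill cost per dose spreads the
line's annualised CapEx and fixed operating cost over its throughput and
adds the container cost per dose; fractional line accounting keeps
projections linear in the target.

## Global sensitivity analysis

Indices are estimated with the Jansen forms (lowest-variance among the
common Saltelli-type estimators) on an A/B/AB design, with percentile
bootstrap CIs (1,000 resamples by default) from joint row resampling.
Estimator checks in the test suite: the additive `X1 + 2 X2` model
(exact shares 0.2/0.8) and the Ishigami benchmark against its closed-form
variance decomposition. Negative first-order estimates near zero are
estimator noise and are never clipped in computations.

**Design construction.** The standard construction draws one
2d-dimensional Sobol sequence and splits its columns into A and B. The
alternative of using consecutive blocks of a single d-dimensional stream
is also provided (`method = "stream"`), but consecutive dyadic blocks of
a digital net are XOR-shifts of one another, which correlates A with B
and biases the estimators — hence `"paired"` is the default.

**Additivity.** Cost per dose is essentially single-factor additive
(dominated by dose amount for the RNA platforms). The annual-amount KPIs
are products of several wide-ranged factors, so their total-effect
indices exceed first-order ones by up to ~0.2 — first-order effects still
carry most of the variance (the tests assert ΣSi > 0.7 per KPI), but
"minor interactions" should be read on that backdrop: on the log scale
the chain is exactly additive.

**RS-HDMR metamodel.** `fit_rshdmr()` fits `f0 + Σ fi(ui)` with
orthonormal shifted-Legendre components (order ≤ 3) by least squares on
the unit-cube image of the design; component variances are sums of
squared coefficients, giving surrogate-based Si directly. Validation is
on held-out scenarios only (`validate_rshdmr()`), e.g. a 1,250-scenario
hold-out alongside a 10,000-scenario fitting design; the suite requires
held-out R² > 0.95 for the log of annual output. The surrogate
is an optional fast path — the direct estimator is the default route.

## Projections

`project_resources()` linearly extrapolates each scenario to a dose
target: fractional lines, scale, batches, CapEx and OpEx all scale with
`target / doses-per-year`. Economy of scale is deliberately suppressed at
this stage (the sampled processes are already at production scale, and
supplier constraints counteract further scale economies); an
integer-lines mode exists for realism but is excluded from all reported
figures. Default targets: 1×10⁹ doses/yr, the 2.4×10⁹ annual
single-dose booster demand (2.2 billion vulnerable + 0.2 billion
frontline), and the 11.3×10⁹ global demand gap.

```{r projection}
run <- run_pipeline("sarna", n = 2000)
glance(run)
```

## Numerical conventions and degenerate inputs

* Quantiles: linear interpolation between order statistics (R type 7),
  everywhere.
* Violin/box displays drop the bottom and top 5% for legibility
  (`trim_tails()`); reported medians and IQRs always use the full sample.
* Zero annual output (failure rate 100%) is flagged explicitly:
  `time_to_target_years = Inf`, `cost_per_dose = NA`, projections `NA`,
  each with a warning — never silently dropped.
* Triangular parameters may be degenerate (`mode == low` or
  `mode == high`); `low < high` is enforced.
* Reported batch counts for projections are batch starts; released
  batches are starts × (1 − failure) and both are in the KPI table.

## Limitations

* The lumped batch model reproduces the *functional form* of platform
  economics, not a flowsheet simulator: absolute medians are calibrated,
  so out-of-calibration quantities (e.g. AVV OpEx level) carry model
  error beyond the sampled uncertainty.
* Material usage per gram of RNA (cap analogue stoichiometry, lipid
  ratios) is a configuration estimate, not a measured recipe.
* Fill-to-finish is modelled at line level only — no lyophilisation,
  inspection, cold chain or container-supply constraints.
* The saRNA platform is modelled with the same cell-free chemistry and
  recipe as mRNA; its clinical immaturity (dose still uncertain over two
  orders of magnitude) is represented only through the wide dose factor.
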