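---
title: "Model and methods: lifetime cost-effectiveness of apixaban versus VKA in non-valvular AF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nvafce)
```

## The decision problem

Patients with non-valvular atrial fibrillation (AF) carry an elevated risk of
ischemic stroke and systemic embolism. Vitamin-K antagonists (VKAs) reduce
that risk effectively but have a narrow therapeutic window (INR 2.0--3.0),
demand continuous coagulation monitoring, and expose patients to bleeding,
including hemorrhagic stroke. Apixaban, a direct oral anticoagulant, needs no
INR monitoring and shows lower rates of stroke, major bleeding and treatment
discontinuation, at a much higher drug acquisition price. `nvafce` implements
a lifetime Markov cohort model that weighs these trade-offs from a healthcare
payer perspective and reports the incremental cost-effectiveness ratio (ICER)
in euros per quality-adjusted life year (QALY) and per life year (LY).

## Model structure

A closed cohort (1,000 patients by default, age 70, 35.3% female) starts on
the assigned anticoagulant and is re-evaluated every 6-week cycle
(`6/52.18` years; a calendar-exact year of 52.18 weeks). Health states:

* **Baseline AF** on apixaban, VKA or acetylsalicylic acid (ASA);
* **Post-ischemic-stroke (IS)** by severity (mild/moderate/severe), first or
  recurrent, still on the assigned anticoagulant;
* **Post-hemorrhagic-stroke (HS)** by severity, first or recurrent,
  maintenance treatment only;
* **Post-systemic-embolism (SE)** -- absorbing, anticoagulant continued;
* **Post-myocardial-infarction (MI)** -- absorbing, maintenance only;
* **Drug holiday** -- one cycle without anticoagulant protection after a
  survived non-HS intracranial hemorrhage (ICH) when the patient stays on
  therapy;
* **Dead**.

Bleeding events that do not change the state permanently (other ICH, other
major bleeding [MB] split into gastrointestinal and non-gastrointestinal,
and clinically relevant non-major [CRNM] bleeding) are modelled as annotated
transitions: they carry acute costs and time-limited utility decrements and
re-route therapy (stay versus switch to ASA, per configurable allocation
fractions), but do not occupy a cycle of their own. Other treatment
discontinuation moves patients to ASA. One recurrent stroke per patient is
representable -- recurrent-stroke states have no further recurrence exits,
which the test suite asserts structurally.

## Transition probabilities

Annual event rates per 100 patient-years are converted to per-cycle
probabilities with the standard constant-hazard rule
`p = 1 - exp(-(r/100) * t)` where `t` is the cycle length in years. The test
suite checks this against a micro-step compounding oracle to 1e-6 across
rates 0--50/100 py.

Within a cycle, competing events are composed cause-specifically: each cause
contributes its hazard share of the overall exit probability
`1 - exp(-H t)`, with `H` the total hazard including mortality. This keeps
every row stochastic to 1e-12 (asserted across a sweep of 50 perturbed
parameter sets) and makes the composition order-independent.

Risk adjustment layers:

* **INR control (TTR).** The four INR-control-dependent events (IS, ICH,
  other MB, CRNM) take their rates from a clinic-TTR stratum table with four
  strata (`<52.38%`, `52.38--66.02%`, `66.02--76.51%`, `>=76.51%`). The base
  case uses the stratum containing the national mean TTR of 72.48%. A
  scenario can instead select a single stratum, the unweighted mean of all
  strata ("equal distribution across clinics"), or a linear interpolation at
  the population TTR. We read "equally distributed" as the unweighted
  stratum mean -- the alternative (a mixed-cohort simulation) would require
  per-clinic cohort book-keeping the data do not support; the interpolation
  policy is offered as a configuration option because the functional link
  between a mean TTR and a stratum table is not uniquely determined.
* **CHADS2 case mix.** The IS rate is scaled by the ratio of the
  cohort-weighted per-score stroke rate to the same weighted rate under the
  reference score distribution (7/27/25/20/12/7/2% over scores 1--7), so the
  factor is exactly 1 in the base case and moves the rate when the user
  supplies a different case mix.
* **Age.** Stroke, bleeding and MI rates escalate multiplicatively per
  decade of attained age (defaults 1.4, 1.4, 1.3 per decade), stepwise at
  whole-year boundaries because life tables are annual.
* **Severity and fatality.** IS and HS flows split into
  mild/moderate/severe/fatal by therapy-specific distributions; SE, MI,
  other ICH and other MB carry case-fatality fractions. Recurrent strokes
  (2.97%/year after IS, 2.17%/year after HS) use the apixaban first-stroke
  severity distribution.
* **Mortality.** During the 1.8-year trial period, non-cardiovascular
  mortality is a flat trial-based rate; afterwards it comes from the
  sex-weighted synthetic life table. State-specific excess multipliers
  (AF 1.7; stroke 1.3/2.0/3.5 by severity; MI 1.6; SE 1.6) scale the
  other-cause rate competing-risk style.

The horizon runs to age 110; with the default life table the surviving
fraction at the cap is below 1e-9, i.e. the cohort is extinct.

## Outcomes

**QALYs.** Per-cycle utility is the joint state utility minus the
anticoagulant treatment decrement, clamped at zero, times the cycle length
in years. Joint utilities for comorbid states default to the multiplicative
combination `u_AF * u_event` (a `minimum` option exists); the published
joint-estimation method behind the original utilities is not reproducible
from public sources, and the multiplicative form is the standard
approximation with the right bounds (never above either input). Bleed
decrements are booked at the event cycle as decrement x duration -- for the
default durations (at most one cycle) this is exact; for longer durations it
ignores within-duration discounting and mortality, a deliberate
simplification that avoids convolving bleed memory into the state space.

**Life years** accrue one per person-year alive and, like QALYs, are
discounted at the effects rate (1.5% annually), so discounted LYs sit next
to discounted QALYs in the summary.

**Costs.** Drug costs accrue per person-cycle on therapy (VKA priced as the
80:20 acenocoumarol:phenprocoumon usage mix), routine care on all alive
person-cycles, INR monitoring only on VKA person-cycles, acute event costs
at the event cycle, and long-term monthly maintenance in post-stroke and
post-MI states. Costs are discounted at 4% annually. An inflation helper
(`inflate_cost()`) re-expresses historical costing inputs in the 2013 price
year from a consumer-price-index series supplied in the configuration.

**Discounting** starts after the first model year: a cycle starting at time
`t >= 1` years carries `(1+r)^-(t-1)`. Accrual uses cycle-start occupancy;
half-cycle correction is available as a configuration switch but defaults to
off, so absolute totals can shift slightly relative to engines that apply
it.

The ICER is computed from full-precision internals; report tables round only
at render time (which is why a ratio of rounded table cells can differ from
the reported ICER). Dominance labelling snaps incremental differences at
machine precision to zero so numerically identical arms are labelled
"equal"; the reported incrementals themselves remain exact arm differences.

## Uncertainty analysis

* **One-way (tornado).** Each swept parameter is set to its 95% bounds
  (mean ± 1.96 SE from its uncertainty descriptor, clamped to its domain)
  and the full deterministic model is rerun; entries are ranked by ICER
  spread. The default sweep covers the absolute stroke risks,
  discontinuation risks, ICH and other-MB risks in both arms, the AF
  utility, and the main cost drivers.
* **Probabilistic (PSA).** Event rates draw from gamma, utilities from
  beta, costs from log-normal distributions, parameterized by method of
  moments from (mean, SE); 95% CIs convert to SEs under normality via
  `ci_to_se()`. Draws are independent across parameters (no correlation
  structure is available to estimate one). Both arms are evaluated on the
  same draw. Each parameter has its own random substream derived from the
  master seed, the iteration and a hash of its path, so adding a parameter
  leaves existing draws untouched and a fixed seed reproduces the PSA bit
  for bit. The default is 2,000 iterations.
* **CEAC.** The acceptability curve reports, per willingness-to-pay
  threshold (defaults 20,000 and 30,000 euros/QALY), the fraction of draws
  with strictly positive net monetary benefit `lambda * dQALY - dCost`;
  ties at exactly zero count as not cost-effective (a zero-measure event
  under continuous draws).
* **Scenarios.** The four clinic-TTR scenarios (three alternative strata
  plus the equal mix) re-resolve the TTR-dependent rates and rerun the
  deterministic model; the grid echoes the adjusted rates and its
  incremental columns are exact per-arm differences.

## The synthetic reference parameter set

`reference_parameters()` assembles a complete, validated input set. It
embeds the published Dutch base-case anchors verbatim: the cohort profile,
mean TTR 72.48%, the clinic-TTR stratum rates for both arms (the unprinted
base-case stratum is implied by the equal-mix rates: four times the mix
minus the three printed strata), recurrence risks 2.97/2.17%/year, the
80:20 coumarin mix, 4%/1.5% discounting, the 6-week cycle, cohort 1,000,
2,000 PSA iterations and the 20k/30k WTP grid.

Everything whose primary source is not public is a documented synthetic
placeholder chosen once to be order-of-magnitude realistic for an elderly
anticoagulated AF population: per-score CHADS2 stroke rates, MI/SE/
discontinuation rates, ASA rates, severity and fatality splits, post-bleed
stay/switch allocations, utilities and decrements, unit costs, trial-period
mortality, and a Gompertz life table (male `2.2*exp(0.115*(age-70))`,
female `1.5*exp(0.122*(age-70))` per 100 py) that preserves the female
survival advantage and extinguishes the cohort by the age cap. Placeholder
SEs follow the conventions stated for the original inputs where available
(10% of the mean for point-estimate utilities, CV 0.25 for costs) and 15%
of the mean for rates.

Consequently the package's base-case numbers characterize the model
mechanics under a realistic but synthetic input set; they are not a
reproduction of the published base case, which depends on supplementary
values and prior-model inputs that are not in the public record. What the
passing tests do establish: the arithmetic of every adjustment layer, exact
conservation and stochasticity of the engine, agreement of the cohort
recursion with an individual-level microsimulation within Monte-Carlo
error, the qualitative event/cost structure of the comparison (fewer ICH
and CRNM events, higher drug cost, lower monitoring cost on apixaban), and
the internal consistency of the scenario and probabilistic machinery.

`perturbed_parameters()` generates valid neighbourhoods of the reference
set (multiplicative log-normal noise; utilities clamped to [0,1]; severity
splits renormalized) for property sweeps.

## Numerical choices and problem sizes

* Transition rows are built so the residual "stay" probability is one minus
  the computed exits; row sums are exact to machine precision.
* The microsimulation cross-check uses 200,000 trajectories on a 4-state
  chain and a 3-standard-error band; the row-stochasticity sweep uses 50
  perturbed sets; test-level PSAs use a handful of iterations while the
  acceptance script runs the full 2,000.
* Degenerate inputs are rejected at load time with the offending field
  path; `validate_parameters()` returns the full violation report without
  raising.

## Limitations

Beyond the placeholder inputs already discussed: event rates are constant
over life apart from the explicit age escalation; no more than one
recurrent stroke is representable and multiple thromboembolic sequences are
not modelled; post-stroke patients are not exposed to further bleeding or
MI risks (recurrence and mortality only); the drug-holiday cycle uses ASA
rates as the closest available proxy for unprotected risk; the analysis is
payer-perspective only, with no productivity costs.
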