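# nvafce

A lifetime Markov cohort cost-effectiveness model of apixaban versus
vitamin-K antagonists (VKAs) for stroke prevention in non-valvular atrial
fibrillation (AF), from a healthcare payer perspective.

The package is aimed at health-economic modellers who want a fully tested,
scriptable implementation of this class of anticoagulation decision model:
the risk-adjustment layer (clinic time-in-therapeutic-range, CHADS2 case
mix, age escalation), the cohort engine, the economic accounting, and the
standard uncertainty machinery (tornado, probabilistic sensitivity analysis
with acceptability curves, scenario analyses).

## The model in brief

A cohort of AF patients starts on apixaban or VKA and moves through health
states (baseline AF, post-ischemic-stroke and post-hemorrhagic-stroke by
severity with one recurrence allowed, post-systemic-embolism, post-MI,
drug holiday, dead) in 6-week cycles until extinction. Annual event rates
*r* (per 100 patient-years) become cycle probabilities via the
constant-hazard rule

> p = 1 − exp(−(r/100)·t),  t = 6/52.18 years,

competing causes are composed cause-specifically (each cause gets its
hazard share of 1 − e^(−Ht)), and discounted costs *C* and effects *E*
(QALYs, life years; 4%/1.5% annually after the first year) accumulate to
the incremental cost-effectiveness ratio

> ICER = (C_apix − C_VKA) / (E_apix − E_VKA).

Inputs live in a single validated YAML configuration;
`reference_parameters()` generates a complete reference set embedding the
published Dutch base-case anchors (age 70, 35.3% female, mean TTR 72.48%,
clinic-TTR stratum rate tables, recurrence risks 2.97/2.17 %/yr, 80:20
acenocoumarol:phenprocoumon mix) with documented synthetic placeholders for
values whose primary sources are not public — see the methods vignette
(`vignettes/nvafce-methods.Rmd`) for exactly which is which and what that
means for interpreting the numbers.

## Worked example

```r
library(nvafce)

params <- reference_parameters()   # validated base-case input set
fit <- nvaf_ce(params)             # both arms, lifetime horizon
print(fit)
#> Markov cohort cost-effectiveness: apixaban vs vka
#>   apixaban  cost     16152  QALYs   7.40  LYs   9.90
#>   vka       cost     13695  QALYs   7.29  LYs   9.83
#>   incremental cost 2457, QALYs 0.12, LYs 0.07
#>   ICER 21176 /QALY, 35095 /LY
```

Per patient and over a lifetime, apixaban costs about €2,460 more (the
drug premium less avoided event and INR-monitoring costs) and yields 0.12
more QALYs, i.e. roughly €21,000 per QALY gained under the synthetic
reference inputs. `summary(fit)` renders the per-arm event/cost breakdown
and the CE summary table; `plot(fit)` draws the survival curves.

Probabilistic and scenario analyses:

```r
ps <- run_psa(params, iterations = 200, seed = 42)
print(ps)
#> <nvaf_psa> 200 iterations (seed 42)
#>   mean incremental cost 2368, QALYs 0.118
#>   P(cost-effective at 20000/QALY) = 0.525
#>   P(cost-effective at 30000/QALY) = 0.815

sc <- run_scenarios(params)        # four clinic-TTR scenarios
sc[sc$treatment == "vka", c("scenario", "d_cost", "d_qaly", "icer_per_qaly")]
#>                         scenario d_cost d_qaly icer_per_qaly
#>                      cTTR<52.38%   1168 0.2149          5438
#>              52.38%<=cTTR<66.02%   2701 0.1205         22416
#>                     cTTR>=76.51%   2043 0.1516         13475
#>  Equal distribution across cTTRs   2086 0.1511         13808
```

The scenario grid shows the familiar pattern: the worse the INR control in
the comparator population, the better apixaban looks. `tornado(params)`
runs the one-way sweeps; `plot()` methods exist for the PSA (CE plane,
CEAC) and the tornado.

A thin command-line wrapper ships in `inst/cli/nvafce.R`:

```sh
Rscript inst/cli/nvafce.R run --config my_config.yaml --out results/
Rscript inst/cli/nvafce.R psa --config my_config.yaml --seed 7 --iterations 2000 --out results/
```

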