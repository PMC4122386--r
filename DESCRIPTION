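Package: nvafce
Title: Lifetime Markov Cohort Cost-Effectiveness Model of Oral
    Anticoagulation in Non-Valvular Atrial Fibrillation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A decision-analytic Markov cohort model comparing apixaban
    with vitamin-K antagonists (VKAs) for stroke prevention in patients
    with non-valvular atrial fibrillation, from a healthcare payer
    perspective. The model converts annual event rates into 6-week cycle
    transition probabilities with adjustment for INR control (time in
    therapeutic range), baseline CHADS2 stroke-risk distribution and
    age-related risk escalation; propagates a cohort over a lifetime
    horizon; and accrues discounted costs, quality-adjusted life years
    and life years to an incremental cost-effectiveness ratio. Includes
    one-way (tornado) sensitivity analysis, probabilistic sensitivity
    analysis with cost-effectiveness acceptability curves, scenario
    analyses over clinic-level INR control strata, a validated parameter
    configuration schema, and a synthetic reference parameter set.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
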