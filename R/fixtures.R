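# Synthetic reference inputs.
#
# The reference parameter set encodes the published Dutch base case for oral
# anticoagulation in non-valvular AF: a 70-year-old cohort (35.3% female,
# CHADS2 distribution 7/27/25/20/12/7/2% over scores 1..7), mean national TTR
# 72.48%, a 6-week cycle, 4%/1.5% annual discounting after the first year and
# clinic-TTR stratum rate tables for the four INR-control-dependent events.
# Quantities whose primary sources are not public (per-score stroke rates,
# utilities, unit costs, severity and fatality splits, post-bleed treatment
# allocations, trial-period mortality) are synthetic placeholders chosen to be
# order-of-magnitude realistic for this population; each carries an
# uncertainty descriptor so the probabilistic machinery exercises it.

#' Synthetic Gompertz life table
#'
#' Generates a smooth synthetic all-other-cause mortality table (rates per
#' 100 person-years) by sex, monotone non-decreasing in age. The level and
#' slope approximate elderly Dutch background mortality with the female
#' advantage retained; it is a synthetic stand-in, not national statistics.
#'
#' @param max_age last age covered (must exceed `min_age`)
#' @param min_age first age covered
#' @return data.frame with columns `age`, `male`, `female`
#' @export
synthetic_life_table <- function(max_age = 110, min_age = 60) {
  if (max_age <= min_age) stop_domain("max_age must exceed min_age")
  age <- min_age:max_age
  data.frame(age = age,
             male   = 2.2 * exp(0.115 * (age - 70)),
             female = 1.5 * exp(0.122 * (age - 70)))
}

# Clinic-TTR stratum tables (annual rates per 100 patient-years) for the four
# INR-control-dependent events.  Strata: <52.38%, 52.38-66.02%, 66.02-76.51%
# (the base-case stratum containing TTR 72.48%), >=76.51%.  The base-case
# column is implied by the equal-mix row: base = 4*mix - sum(other strata).
ttr_stratum_table <- function() {
  list(
    breaks = c(0, 0.5238, 0.6602, 0.7651, 1),
    labels = c("cTTR<52.38%", "52.38%<=cTTR<66.02%",
               "66.02%<=cTTR<76.51%", "cTTR>=76.51%"),
    rates = list(
      vka = list(
        ischemic_stroke = c(1.787, 1.159, 0.967, 0.831),
        ich             = c(0.959, 0.912, 0.621, 0.708),
        other_mb        = c(1.765, 2.093, 2.365, 2.857),
        crnm            = c(2.622, 2.657, 3.337, 3.364)),
      apixaban = list(
        ischemic_stroke = c(1.213, 1.316, 0.909, 0.738),
        ich             = c(0.292, 0.502, 0.345, 0.181),
        other_mb        = c(0.999, 1.384, 2.335, 2.442),
        crnm            = c(1.271, 1.788, 2.230, 3.043))))
}

#' Reference model parameter set
#'
#' Builds the complete base-case parameter set for the apixaban-versus-VKA
#' model. Published anchors (cohort profile, TTR strata, recurrence risks,
#' 80:20 coumarin mix, discounting, cycle length, probabilistic iteration
#' count, willingness-to-pay grid) are embedded verbatim; values without a
#' public source are documented synthetic placeholders (see the methods
#' vignette). The generator is deterministic: the same `seed` always yields
#' the identical object (the reference set itself uses no randomness).
#'
#' @param seed integer kept for interface symmetry with
#'   [perturbed_parameters()]; the reference set is seed-invariant
#' @return validated `nvaf_parameters` object
#' @export
reference_parameters <- function(seed = 1L) {
  chads2_w <- c(`1` = 7, `2` = 27, `3` = 25, `4` = 20, `5` = 12, `6` = 7, `7` = 2)
  strata <- ttr_stratum_table()
  base_idx <- 3L  # stratum containing the national mean TTR 72.48%

  base_rate <- function(tx, ev) strata$rates[[tx]][[ev]][base_idx]
  rates <- list(
    apixaban = list(
      ischemic_stroke = base_rate("apixaban", "ischemic_stroke"),
      ich             = base_rate("apixaban", "ich"),
      other_mb        = base_rate("apixaban", "other_mb"),
      crnm            = base_rate("apixaban", "crnm"),
      mi = 0.53, se = 0.09, other_discontinuation = 13.0),
    vka = list(
      ischemic_stroke = base_rate("vka", "ischemic_stroke"),
      ich             = base_rate("vka", "ich"),
      other_mb        = base_rate("vka", "other_mb"),
      crnm            = base_rate("vka", "crnm"),
      mi = 0.61, se = 0.10, other_discontinuation = 13.5),
    asa = list(
      ischemic_stroke = 3.30, ich = 0.40, other_mb = 1.40, crnm = 3.10,
      mi = 0.80, se = 0.10, other_discontinuation = 0))

  params <- list(
    schema_version = "1.0",
    cohort = list(
      start_age = 70, fraction_female = 0.353, cohort_size = 1000,
      chads2_weights = chads2_w,
      chads2_reference_weights = chads2_w,
      mean_ttr = 0.7248),
    rates = rates,
    ttr_strata = strata,
    # synthetic per-score annual stroke rates (per 100 py); only their
    # relative profile matters, the weighted mean is normalized away
    chads2_stroke_rates = c(`1` = 2.8, `2` = 4.0, `3` = 5.9, `4` = 8.5,
                            `5` = 12.5, `6` = 18.2, `7` = 26.0),
    modifiers = list(
      age_factors = list(stroke = 1.40, bleed = 1.40, mi = 1.30),
      hs_fraction_of_ich = 0.63,
      gi_fraction_of_other_mb = 0.38,
      stroke_severity = list(   # mild, moderate, severe, fatal
        is = list(apixaban = c(0.396, 0.344, 0.135, 0.125),
                  vka      = c(0.379, 0.363, 0.140, 0.118),
                  asa      = c(0.350, 0.360, 0.150, 0.140)),
        hs = list(apixaban = c(0.174, 0.278, 0.160, 0.388),
                  vka      = c(0.163, 0.164, 0.163, 0.510),
                  asa      = c(0.160, 0.200, 0.160, 0.480))),
      case_fatality = list(se = 0.094, mi = 0.158, other_ich = 0.130,
                           other_mb = 0.020, crnm = 0),
      post_bleed_stay = list(other_ich = 0.25, other_mb = 0.50, crnm = 0.75),
      recurrence_annual = list(post_is = 0.0297, post_hs = 0.0217),
      excess_mortality = list(
        af = 1.7,
        stroke = c(mild = 1.3, moderate = 2.0, severe = 3.5),
        mi = 1.6, se = 1.6),
      trial_period_years = 1.8,
      trial_noncv_mortality = list(apixaban = 1.75, vka = 1.80)),
    utilities = list(
      af_baseline = 0.779,
      events = list(stroke = c(mild = 0.85, moderate = 0.68, severe = 0.52),
                    mi = 0.84, se = 0.84),
      bleed_decrements = list(
        other_ich = list(decrement = 0.20,  duration_weeks = 6),
        other_mb  = list(decrement = 0.092, duration_weeks = 2),
        crnm      = list(decrement = 0.02,  duration_weeks = 2)),
      treatment_decrements = list(apixaban = 0.002, vka = 0.013, asa = 0.002),
      joint_method = "multiplicative"),
    costs = list(
      price_year = 2013,
      drug_per_cycle = list(apixaban = 92.0, acenocoumarol = 2.5,
                            phenprocoumon = 3.8, asa = 0.85),
      vka_mix = c(acenocoumarol = 0.8, phenprocoumon = 0.2),
      routine_care_per_cycle = 28.0,
      inr_monitoring_per_cycle = 14.0,
      acute = list(
        is = c(mild = 17000, moderate = 45000, severe = 55000, fatal = 2500),
        hs = c(mild = 18000, moderate = 50000, severe = 58000, fatal = 2600),
        other_ich = c(nonfatal = 17000, fatal = 0),
        other_mb = c(gi = 4500, non_gi = 4500, fatal = 0),
        crnm = c(event = 25),
        se = c(nonfatal = 4100, fatal = 0),
        mi = c(nonfatal = 4300, fatal = 0)),
      long_term_monthly = list(stroke = c(mild = 70, moderate = 330, severe = 400),
                               mi = 75),
      inflation_index = data.frame(
        year = 2008:2013,
        index = c(1.000, 1.012, 1.025, 1.049, 1.075, 1.102))),
    settings = list(
      cycle_length_weeks = 6, weeks_per_year = 52.18,
      max_age = 110, extinction_threshold = 1e-9,
      discount_rate_costs = 0.04, discount_rate_effects = 0.015,
      discount_free_years = 1,
      wtp_thresholds = c(20000, 30000),
      psa_iterations = 2000,
      half_cycle_correction = FALSE,
      ttr_policy = list(type = "population_ttr")),
    life_table = synthetic_life_table(110, 60))

  params$uncertainty <- build_uncertainty_descriptors(params)
  as_nvaf_parameters(params)
}

# Uncertainty descriptors: gamma for event rates, beta for utilities and
# utility decrements, log-normal for costs.  SEs are synthetic: 15% of the
# mean for rates, 10% for utilities (the convention for point-estimate-only
# utilities), CV 0.25 for costs.  Zero-valued parameters get no descriptor.
build_uncertainty_descriptors <- function(params) {
  out <- list()
  add <- function(path, family, rel_se) {
    m <- get_param(params, path)
    if (is.finite(m) && m > 0)
      out[[length(out) + 1L]] <<- list(path = path, family = family,
                                       se = rel_se * m)
  }
  for (tx in therapies()) for (ev in all_events())
    add(paste("rates", tx, ev, sep = "."), "gamma", 0.15)
  add("utilities.af_baseline", "beta", 0.10)
  for (sv in c("mild", "moderate", "severe"))
    add(paste0("utilities.events.stroke.", sv), "beta", 0.10)
  add("utilities.events.mi", "beta", 0.10)
  add("utilities.events.se", "beta", 0.10)
  for (tx in therapies())
    add(paste0("utilities.treatment_decrements.", tx), "beta", 0.10)
  for (b in names(params$utilities$bleed_decrements))
    add(paste0("utilities.bleed_decrements.", b, ".decrement"), "beta", 0.10)
  for (d in names(params$costs$drug_per_cycle))
    add(paste0("costs.drug_per_cycle.", d), "lognormal", 0.25)
  add("costs.routine_care_per_cycle", "lognormal", 0.25)
  add("costs.inr_monitoring_per_cycle", "lognormal", 0.25)
  for (grp in names(params$costs$acute))
    for (nm in names(params$costs$acute[[grp]]))
      add(paste("costs.acute", grp, nm, sep = "."), "lognormal", 0.25)
  for (sv in c("mild", "moderate", "severe"))
    add(paste0("costs.long_term_monthly.stroke.", sv), "lognormal", 0.25)
  add("costs.long_term_monthly.mi", "lognormal", 0.25)
  out
}

#' Perturbed parameter sets
#'
#' Draws `n` valid parameter sets around the reference set by independent
#' multiplicative log-normal perturbation of rates and costs and perturbation
#' of utilities with clamping into [0, 1]. Severity splits are perturbed and
#' renormalized. With `scale = 0` the reference set is returned unchanged.
#' Used for property sweeps (every returned set passes
#' [validate_parameters()]).
#'
#' @param n number of sets
#' @param scale perturbation scale (log-normal sigma), >= 0
#' @param seed integer seed; same seed gives identical output
#' @return list of `nvaf_parameters` objects
#' @export
perturbed_parameters <- function(n = 1L, scale = 0.1, seed = 1L) {
  if (n < 1L) stop_domain("n must be >= 1")
  if (scale < 0) stop_domain("perturbation scale must be >= 0")
  base <- reference_parameters()
  if (scale == 0) return(rep(list(base), n))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed((seed * 1000L + i) %% .Machine$integer.max)
    p <- unclass(base)
    jit <- function(x) x * exp(stats::rnorm(length(x), 0, scale))
    for (tx in therapies()) for (ev in all_events())
      p$rates[[tx]][[ev]] <- jit(p$rates[[tx]][[ev]])
    for (tx in c("apixaban", "vka")) for (ev in ttr_events())
      p$ttr_strata$rates[[tx]][[ev]] <- jit(p$ttr_strata$rates[[tx]][[ev]])
    clamp01 <- function(x) pmin(pmax(x, 0), 1)
    p$utilities$af_baseline <- clamp01(jit(p$utilities$af_baseline))
    p$utilities$events$stroke <- clamp01(jit(p$utilities$events$stroke))
    p$utilities$events$mi <- clamp01(jit(p$utilities$events$mi))
    p$utilities$events$se <- clamp01(jit(p$utilities$events$se))
    for (kind in c("is", "hs")) for (tx in therapies()) {
      s <- jit(p$modifiers$stroke_severity[[kind]][[tx]])
      p$modifiers$stroke_severity[[kind]][[tx]] <- s / sum(s)
    }
    for (d in names(p$costs$drug_per_cycle))
      p$costs$drug_per_cycle[[d]] <- jit(p$costs$drug_per_cycle[[d]])
    p$costs$routine_care_per_cycle <- jit(p$costs$routine_care_per_cycle)
    p$costs$inr_monitoring_per_cycle <- jit(p$costs$inr_monitoring_per_cycle)
    for (grp in names(p$costs$acute)) p$costs$acute[[grp]] <- jit(p$costs$acute[[grp]])
    p$costs$long_term_monthly$stroke <- jit(p$costs$long_term_monthly$stroke)
    p$costs$long_term_monthly$mi <- jit(p$costs$long_term_monthly$mi)
    out[[i]] <- as_nvaf_parameters(p)
  }
  out
}
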