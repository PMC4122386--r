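# Rate arithmetic: annual event rates (per 100 patient-years) -> per-cycle
# transition probabilities, with INR-control (TTR), CHADS2, age, severity,
# fatality and recurrence adjustment.

#' Convert an annual event rate to a per-cycle probability
#'
#' Uses the standard exponential (constant-hazard) conversion
#' `p = 1 - exp(-(rate/100) * (cycle_length / weeks_per_year))`.
#'
#' @param rate annual event rate per 100 patient-years (>= 0)
#' @param cycle_length_weeks cycle length in weeks (> 0)
#' @param weeks_per_year weeks per year (calendar-exact 52.18 by default)
#' @return probability in [0, 1)
#' @examples
#' rate_to_cycle_probability(50, 52.18)  # 1 - exp(-0.5)
#' @export
rate_to_cycle_probability <- function(rate, cycle_length_weeks,
                                      weeks_per_year = 52.18) {
  if (any(rate < 0)) stop_domain("event rate must be non-negative")
  if (cycle_length_weeks <= 0) stop_domain("cycle length must be positive")
  1 - exp(-(rate / 100) * (cycle_length_weeks / weeks_per_year))
}

#' CHADS2-weighted stroke rate
#'
#' Weights a per-score stroke rate by the proportion of the cohort at each
#' CHADS2 score.
#'
#' @param weights named proportions over scores (normalized internally)
#' @param per_score_rates named annual rates per 100 py, covering every score
#'   with positive weight
#' @return weighted mean rate
#' @export
chads2_weighted_stroke_rate <- function(weights, per_score_rates) {
  if (any(weights < 0) || sum(weights) <= 0)
    stop_domain("weights must be non-negative with positive sum")
  weights <- weights / sum(weights)
  need <- names(weights)[weights > 0]
  if (is.null(names(per_score_rates)) || !all(need %in% names(per_score_rates)))
    stop_domain("per-score rates must cover every score with positive weight")
  sum(weights[need] * per_score_rates[need])
}

# Multiplier carrying the cohort's CHADS2 case mix onto the stroke rate,
# normalized so the reference distribution gives exactly 1.
chads2_rate_factor <- function(params) {
  refw <- params$cohort$chads2_reference_weights
  if (is.null(refw)) return(1)
  chads2_weighted_stroke_rate(params$cohort$chads2_weights,
                              params$chads2_stroke_rates) /
    chads2_weighted_stroke_rate(refw, params$chads2_stroke_rates)
}

#' Adjust event rates for the level of INR control
#'
#' Returns the annual rates of the four INR-control-dependent events
#' (ischemic stroke, ICH, other major bleeding, CRNM bleeding) under a
#' clinic-TTR policy, for the apixaban and VKA arms:
#' \describe{
#'   \item{`stratum`}{rates of one named cTTR stratum (`label` or `index`)}
#'   \item{`equal_mix`}{unweighted mean across all strata (patients equally
#'     distributed across clinics)}
#'   \item{`population_ttr`}{rates of the stratum containing the population
#'     mean TTR}
#'   \item{`interpolated_ttr`}{linear interpolation on stratum midpoints at
#'     the population mean TTR}
#' }
#'
#' @param params `nvaf_parameters` with a complete `ttr_strata` table
#' @param policy list with element `type` and, for `stratum`, a `label` or
#'   `index`
#' @return the `rates` list of `params` with the four TTR-dependent rates
#'   replaced for the apixaban and VKA therapies
#' @export
ttr_adjust_rates <- function(params, policy = list(type = "population_ttr")) {
  st <- params$ttr_strata
  if (is.null(st)) stop_domain("no TTR stratum table configured")
  nstr <- length(st$labels)
  pick <- function(v) {
    switch(policy$type,
      stratum = {
        i <- if (!is.null(policy$index)) policy$index else match(policy$label, st$labels)
        if (is.na(i) || i < 1L || i > nstr)
          stop_domain("unknown cTTR stratum in policy")
        v[i]
      },
      equal_mix = mean(v),
      population_ttr = {
        ttr <- params$cohort$mean_ttr
        i <- findInterval(ttr, st$breaks, rightmost.closed = TRUE)
        if (i < 1L || i > nstr) stop_domain("population TTR outside all strata")
        v[i]
      },
      interpolated_ttr = {
        mids <- (st$breaks[-1L] + st$breaks[-(nstr + 1L)]) / 2
        stats::approx(mids, v, xout = params$cohort$mean_ttr, rule = 2)$y
      },
      stop_domain(paste0("unknown TTR policy type: ", policy$type)))
  }
  rates <- params$rates
  for (tx in c("apixaban", "vka"))
    for (ev in ttr_events())
      rates[[tx]][[ev]] <- pick(st$rates[[tx]][[ev]])
  rates
}

#' Escalate a rate for age
#'
#' Applies a per-decade multiplicative escalation factor:
#' `rate * factor^((current_age - baseline_age)/10)`.
#'
#' @param rate annual rate
#' @param baseline_age age at which `rate` was observed
#' @param current_age attained age
#' @param factor_per_decade multiplier per decade of age (> 0)
#' @return escalated rate
#' @export
age_escalate <- function(rate, baseline_age, current_age, factor_per_decade) {
  if (any(factor_per_decade <= 0)) stop_domain("age factor must be positive")
  rate * factor_per_decade^((current_age - baseline_age) / 10)
}

#' Split an ICH rate into hemorrhagic stroke and other ICH
#'
#' @param ich_rate total intracranial haemorrhage rate
#' @param hs_fraction fraction of ICHs that are haemorrhagic strokes, in [0,1]
#' @return named numeric `c(hs =, other_ich =)` summing to `ich_rate`
#' @export
split_ich <- function(ich_rate, hs_fraction) {
  if (hs_fraction < 0 || hs_fraction > 1) stop_domain("hs_fraction must be in [0,1]")
  c(hs = ich_rate * hs_fraction, other_ich = ich_rate * (1 - hs_fraction))
}

#' Partition an event flow by severity and fatality
#'
#' @param event_flow probability (or hazard) of the event
#' @param severity_split proportions over mild/moderate/severe/fatal
#'   (must sum to 1)
#' @return named numeric of component flows summing to `event_flow`
#' @export
apply_severity_and_fatality <- function(event_flow,
                                        severity_split) {
  if (abs(sum(severity_split) - 1) > 1e-9)
    stop_domain("severity split must sum to 1")
  out <- event_flow * severity_split
  names(out) <- c("mild", "moderate", "severe", "fatal")
  out
}

#' Per-cycle recurrent-stroke probability
#'
#' Annual recurrence risks (2.97%/year after a first ischemic stroke,
#' 2.17%/year after a first haemorrhagic stroke in the reference set) are
#' converted with the same exponential rate-to-probability rule as first
#' events.
#'
#' @param post_state `"post_is"` or `"post_hs"`
#' @param modifiers the `modifiers` component of a parameter set
#' @param cycle_length_weeks cycle length in weeks
#' @param weeks_per_year weeks per year
#' @return per-cycle probability of a recurrent stroke
#' @export
recurrence_probability <- function(post_state, modifiers,
                                   cycle_length_weeks, weeks_per_year = 52.18) {
  if (!post_state %in% c("post_is", "post_hs"))
    stop_domain("post_state must be 'post_is' or 'post_hs'")
  annual <- modifiers$recurrence_annual[[post_state]]
  rate_to_cycle_probability(100 * annual, cycle_length_weeks, weeks_per_year)
}

#' Therapy assignment after a survived event
#'
#' Encodes the treatment pathway: ischemic-stroke and systemic-embolism
#' survivors stay on their assigned anticoagulant; haemorrhagic-stroke and MI
#' survivors move to disease-specific maintenance only; survivors of other
#' ICH, other major bleeding or CRNM bleeding split between staying (other
#' ICH stayers take a one-cycle drug holiday first) and switching to ASA;
#' other treatment discontinuations switch to ASA.
#'
#' @param event one of `"is"`, `"se"`, `"hs"`, `"mi"`, `"other_ich"`,
#'   `"other_mb"`, `"crnm"`, `"other_discontinuation"`
#' @param current_therapy `"apixaban"`, `"vka"` or `"asa"`
#' @param modifiers the `modifiers` component of a parameter set (post-bleed
#'   stay fractions)
#' @return list with per-destination probabilities: `stay` (therapy kept,
#'   with `holiday = TRUE` if routed through a drug-holiday cycle),
#'   `switch_asa`, or `maintenance`
#' @export
post_event_therapy <- function(event, current_therapy, modifiers) {
  stopifnot(current_therapy %in% therapies())
  switch(event,
    is = ,
    se = list(stay = list(therapy = current_therapy, holiday = FALSE, p = 1)),
    hs = ,
    mi = list(maintenance = list(p = 1)),
    other_ich = {
      stay <- modifiers$post_bleed_stay$other_ich
      list(stay = list(therapy = current_therapy,
                       holiday = current_therapy != "asa", p = stay),
           switch_asa = list(p = 1 - stay))
    },
    other_mb = ,
    crnm = {
      stay <- modifiers$post_bleed_stay[[event]]
      list(stay = list(therapy = current_therapy, holiday = FALSE, p = stay),
           switch_asa = list(p = 1 - stay))
    },
    other_discontinuation = list(switch_asa = list(p = 1)),
    stop_domain(paste0("unknown event type: ", event)))
}

#' Layer background and excess mortality onto event hazards
#'
#' Adds an other-cause death hazard (trial-based during the trial period,
#' life-table-based afterwards) scaled by a state-specific excess-mortality
#' multiplier, then composes all competing hazards into per-cycle flows:
#' each cause receives its hazard share of the overall event probability
#' `1 - exp(-H t)`, which keeps the row stochastic and order-independent.
#'
#' @param event_hazards named non-negative annual hazards (per-1) of the
#'   competing non-fatal-cause exits
#' @param other_cause_rate annual other-cause mortality rate per 100 py
#' @param excess_multiplier state-specific multiplier (>= 1) on the
#'   other-cause rate
#' @param cycle_length_weeks,weeks_per_year cycle geometry
#' @return named per-cycle flow vector: the input causes, `death`, and the
#'   complementary `stay` probability; sums to 1 exactly
#' @export
layer_mortality <- function(event_hazards, other_cause_rate, excess_multiplier = 1,
                            cycle_length_weeks = 6, weeks_per_year = 52.18) {
  if (any(event_hazards < 0) || other_cause_rate < 0)
    stop_domain("hazards must be non-negative")
  h <- c(event_hazards, death = (other_cause_rate / 100) * excess_multiplier)
  t_years <- cycle_length_weeks / weeks_per_year
  H <- sum(h)
  flows <- if (H > 0) h / H * (1 - exp(-H * t_years)) else h * 0
  c(flows, stay = 1 - sum(flows))
}
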