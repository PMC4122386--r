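# Discounted QALY, life-year and cost accrual, and incremental
# cost-effectiveness.

#' Utility of a joint health state
#'
#' Combines the baseline AF utility with the utility of a comorbid
#' thromboembolic event. The default multiplicative combination bounds the
#' joint utility by the smaller of the two inputs; the `minimum` method takes
#' the smaller input directly.
#'
#' @param u_af baseline AF utility in [0,1]
#' @param u_event event-state utility in [0,1]
#' @param method `"multiplicative"` or `"minimum"`
#' @return joint utility
#' @export
joint_state_utility <- function(u_af, u_event, method = "multiplicative") {
  if (u_af < 0 || u_af > 1 || u_event < 0 || u_event > 1)
    stop_domain("utilities must lie in [0,1]")
  switch(method,
         multiplicative = u_af * u_event,
         minimum = min(u_af, u_event),
         stop_domain(paste0("unknown joint-utility method: ", method)))
}

# Per-state utility (after treatment decrements, clamped at 0) and per-cycle
# cost vectors derived from a parameter set.
state_values <- function(params, info, cycle_years) {
  ut <- params$utilities
  cs <- params$costs
  method <- ut$joint_method
  drug_cost <- c(
    apixaban = cs$drug_per_cycle$apixaban,
    vka = weighted_vka_drug_cost(cs$drug_per_cycle$acenocoumarol,
                                 cs$drug_per_cycle$phenprocoumon, cs$vka_mix),
    asa = cs$drug_per_cycle$asa, none = 0)
  S <- nrow(info)
  u <- drug <- routine <- inr <- longterm <- numeric(S)
  on_anticoag <- info$category %in% c("base", "post_is", "post_se")
  for (i in seq_len(S)) {
    cat_i <- info$category[i]; tx <- info$therapy[i]; sv <- info$severity[i]
    base_u <- switch(cat_i,
      base = , holiday = ut$af_baseline,
      post_is = , post_hs = joint_state_utility(ut$af_baseline,
                                                ut$events$stroke[[sv]], method),
      post_se = joint_state_utility(ut$af_baseline, ut$events$se, method),
      post_mi = joint_state_utility(ut$af_baseline, ut$events$mi, method),
      dead = 0)
    dec <- if (on_anticoag[i]) ut$treatment_decrements[[tx]] else 0
    u[i] <- max(base_u - dec, 0)
    drug[i] <- if (on_anticoag[i]) drug_cost[[tx]] else 0
    routine[i] <- if (info$alive[i]) cs$routine_care_per_cycle else 0
    inr[i] <- if (on_anticoag[i] && tx == "vka") cs$inr_monitoring_per_cycle else 0
    longterm[i] <- switch(cat_i,
      post_is = , post_hs = cs$long_term_monthly$stroke[[sv]] * 12 * cycle_years,
      post_mi = cs$long_term_monthly$mi * 12 * cycle_years,
      0)
  }
  list(utility = u, drug = drug, routine = routine, inr = inr,
       longterm = longterm)
}

# Per-event acute cost and lump utility decrement (decrement x duration in
# years, booked at the event cycle) keyed by event annotation.
event_values <- function(params) {
  cs <- params$costs$acute
  ut <- params$utilities$bleed_decrements
  wpy <- params$settings$weeks_per_year
  keys <- event_keys()
  cost <- stats::setNames(numeric(length(keys)), keys)
  dec <- stats::setNames(numeric(length(keys)), keys)
  sev <- c(severity_levels(), "fatal")
  for (s in sev) {
    cost[paste0("is_first_", s)] <- cs$is[[s]]
    cost[paste0("is_rec_", s)] <- cs$is[[s]]
    cost[paste0("hs_first_", s)] <- cs$hs[[s]]
    cost[paste0("hs_rec_", s)] <- cs$hs[[s]]
  }
  cost["se_nonfatal"] <- cs$se[["nonfatal"]]; cost["se_fatal"] <- cs$se[["fatal"]]
  cost["other_ich_nonfatal"] <- cs$other_ich[["nonfatal"]]
  cost["other_ich_fatal"] <- cs$other_ich[["fatal"]]
  cost["mb_gi_nonfatal"] <- cs$other_mb[["gi"]]
  cost["mb_nongi_nonfatal"] <- cs$other_mb[["non_gi"]]
  cost["mb_fatal"] <- cs$other_mb[["fatal"]]
  cost["crnm"] <- cs$crnm[[1L]]
  cost["mi_nonfatal"] <- cs$mi[["nonfatal"]]; cost["mi_fatal"] <- cs$mi[["fatal"]]
  lump <- function(b) b$decrement * b$duration_weeks / wpy
  dec["other_ich_nonfatal"] <- lump(ut$other_ich)
  dec[c("mb_gi_nonfatal", "mb_nongi_nonfatal")] <- lump(ut$other_mb)
  dec["crnm"] <- lump(ut$crnm)
  list(cost = cost, decrement = dec)
}

#' Accrue discounted QALYs and life years
#'
#' Per-cycle utility is the joint state utility minus the treatment
#' decrement (clamped at 0), times the cycle length in years, discounted at
#' the effects rate; bleed decrements are booked at the event cycle as
#' decrement x duration. Life years accrue one per person-year alive at the
#' same discount rate.
#'
#' @param trace `nvaf_trace`
#' @param params `nvaf_parameters`
#' @return list with per-patient `qaly` and `ly`
#' @export
accrue_qalys <- function(trace, params) {
  se <- params$settings
  n <- nrow(trace$events)
  cyc <- trace$cycle_years
  df <- discount_factor(seq_len(n) - 1L, se$discount_rate_effects, cyc,
                        se$discount_free_years)
  sv <- state_values(params, trace$info, cyc)
  evv <- event_values(params)
  occ <- accrual_occupancy(trace, isTRUE(se$half_cycle_correction))
  qaly <- sum(df * (occ %*% sv$utility) * cyc) -
    sum(df * (trace$events %*% evv$decrement))
  alive <- as.numeric(trace$info$alive)
  ly <- sum(df * (occ %*% alive) * cyc)
  list(qaly = qaly / trace$cohort_size, ly = ly / trace$cohort_size)
}

#' Accrue discounted costs
#'
#' Drug and routine-care costs accrue per person-cycle on therapy, INR
#' monitoring only on VKA person-cycles, acute event costs at the event
#' cycle, and long-term monthly maintenance per person-cycle in post-stroke
#' and post-MI states; everything discounted at the cost rate.
#'
#' @param trace `nvaf_trace`
#' @param params `nvaf_parameters`
#' @return list with per-patient `total`, `breakdown` (drug, routine_care,
#'   inr_monitoring, acute_events, long_term) and `acute_by_event`
#' @export
accrue_costs <- function(trace, params) {
  se <- params$settings
  n <- nrow(trace$events)
  cyc <- trace$cycle_years
  df <- discount_factor(seq_len(n) - 1L, se$discount_rate_costs, cyc,
                        se$discount_free_years)
  sv <- state_values(params, trace$info, cyc)
  evv <- event_values(params)
  occ <- accrual_occupancy(trace, isTRUE(se$half_cycle_correction))
  percycle <- function(v) sum(df * (occ %*% v)) / trace$cohort_size
  acute_by_event <- colSums(df * trace$events) * evv$cost / trace$cohort_size
  breakdown <- c(drug = percycle(sv$drug),
                 routine_care = percycle(sv$routine),
                 inr_monitoring = percycle(sv$inr),
                 acute_events = sum(acute_by_event),
                 long_term = percycle(sv$longterm))
  list(total = sum(breakdown), breakdown = breakdown,
       acute_by_event = acute_by_event)
}

#' Evaluate one treatment arm
#'
#' Builds the arm's transition model, propagates the cohort and accrues
#' discounted outcomes.
#'
#' @param params `nvaf_parameters`
#' @param arm initial therapy
#' @param edges precomputed edge table (internal reuse between arms)
#' @return object of class `nvaf_arm`: `arm`, `trace`, `tally` (lifetime
#'   expected event counts), `cost`, `qaly`, `ly`
#' @export
evaluate_arm <- function(params, arm, edges = NULL) {
  model <- build_transition_model(params, arm, edges = edges)
  trace <- run_cohort(model, params$cohort$cohort_size)
  eff <- accrue_qalys(trace, params)
  cost <- accrue_costs(trace, params)
  structure(list(arm = arm, trace = trace, tally = tally_events(trace),
                 cost = cost, qaly = eff$qaly, ly = eff$ly),
            class = "nvaf_arm")
}

#' Incremental cost-effectiveness of two arms
#'
#' Incrementals are reference minus comparator. The ICER is reported only in
#' the trade-off quadrants; dominance (cheaper and at least as effective, or
#' the reverse) is labelled instead of a ratio.
#'
#' @param reference `nvaf_arm` (or list with `cost$total`, `qaly`, `ly`) for
#'   the intervention
#' @param comparator same, for the comparator
#' @return object of class `nvaf_ce_result` with incrementals, ICERs per
#'   QALY and per LY, and a `dominance` label
#'   (`"dominant"`, `"dominated"`, `"tradeoff"`, `"equal"`)
#' @export
compute_icer <- function(reference, comparator) {
  d_cost <- reference$cost$total - comparator$cost$total
  d_qaly <- reference$qaly - comparator$qaly
  d_ly <- reference$ly - comparator$ly
  # labelling ignores differences at machine precision (mirror-path rounding);
  # the reported incrementals themselves stay exact
  zc <- abs(d_cost) <= 1e-9 * max(1, abs(comparator$cost$total))
  zq <- abs(d_qaly) <= 1e-12 * max(1, abs(comparator$qaly))
  label <-
    if (zc && zq) "equal"
    else if (d_cost <= 0 && d_qaly >= 0) "dominant"
    else if (d_cost >= 0 && d_qaly <= 0) "dominated"
    else "tradeoff"
  icer_qaly <- if (label == "tradeoff") d_cost / d_qaly else NA_real_
  icer_ly <- if (label == "tradeoff" && d_ly != 0) d_cost / d_ly else NA_real_
  structure(list(reference = reference, comparator = comparator,
                 d_cost = d_cost, d_qaly = d_qaly, d_ly = d_ly,
                 icer_per_qaly = icer_qaly, icer_per_ly = icer_ly,
                 dominance = label),
            class = "nvaf_ce_result")
}

#' @export
print.nvaf_ce_result <- function(x, ...) {
  cat("<nvaf_ce_result>\n")
  cat(sprintf("  incremental cost %.2f, QALYs %.4f, LYs %.4f\n",
              x$d_cost, x$d_qaly, x$d_ly))
  if (x$dominance == "tradeoff")
    cat(sprintf("  ICER %.0f per QALY (%.0f per LY)\n",
                x$icer_per_qaly, x$icer_per_ly))
  else cat("  dominance:", x$dominance, "\n")
  invisible(x)
}
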