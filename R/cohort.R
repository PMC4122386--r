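# Cohort propagation and event accounting.

#' Discount factor at a cycle start
#'
#' Costs and effects are discounted annually after the first year: cycles
#' starting within the first model year carry factor 1; a cycle starting at
#' time `t >= 1` years carries `(1 + rate)^-(t - 1)`.
#'
#' @param cycle_index 0-based cycle ordinal (cycle 0 starts at time 0)
#' @param annual_rate annual discount rate (proportion, >= 0)
#' @param cycle_years cycle length in years
#' @param free_years length of the undiscounted initial period (default 1)
#' @return multiplier in (0, 1]
#' @export
discount_factor <- function(cycle_index, annual_rate, cycle_years,
                            free_years = 1) {
  if (annual_rate < 0) stop_domain("discount rate must be >= 0")
  t <- cycle_index * cycle_years
  ifelse(t < free_years, 1, (1 + annual_rate)^(-(t - free_years)))
}

#' Propagate a cohort through a transition model
#'
#' Runs the Markov recursion cycle by cycle, recording state occupancy and
#' the expected per-cycle event flows annotated on the transitions.
#'
#' @param model `nvaf_transitions` object
#' @param cohort_size persons at cycle 0 (all in the model's start state)
#' @return object of class `nvaf_trace` with elements `occupancy`
#'   ((cycles+1) x states matrix, persons), `events` (cycles x event-keys
#'   matrix, expected persons experiencing each event in that cycle),
#'   `cycle_time`, `cycle_years`, `states`, `info`, `arm`
#' @export
run_cohort <- function(model, cohort_size = 1000) {
  if (!inherits(model, "nvaf_transitions")) stop_domain("model must be nvaf_transitions")
  for (m in model$P)
    if (any(abs(rowSums(m) - 1) > 1e-9))
      stop_domain("non-stochastic transition row")
  S <- length(model$states)
  n <- length(model$cycle_key)
  K <- length(model$event_keys)
  occ <- matrix(0, n + 1L, S, dimnames = list(NULL, model$states))
  events <- matrix(0, n, max(K, 0L),
                   dimnames = list(NULL, model$event_keys))
  occ[1L, model$start_state] <- cohort_size
  for (c in seq_len(n)) {
    k <- model$cycle_key[c]
    v <- occ[c, ]
    if (K > 0L) events[c, ] <- v %*% model$E[[k]]
    occ[c + 1L, ] <- v %*% model$P[[k]]
  }
  structure(list(occupancy = occ, events = events,
                 cycle_time = model$cycle_time,
                 cycle_age = model$cycle_age,
                 cycle_years = model$cycle_years,
                 states = model$states, info = model$info,
                 arm = model$arm, cohort_size = cohort_size),
            class = "nvaf_trace")
}

#' @export
print.nvaf_trace <- function(x, ...) {
  n <- nrow(x$occupancy) - 1L
  dead <- if ("dead" %in% colnames(x$occupancy)) x$occupancy[n + 1L, "dead"] else NA
  cat(sprintf("<nvaf_trace> arm %s: %d cycles, cohort %g, %.2f dead at horizon\n",
              x$arm, n, x$cohort_size, dead))
  invisible(x)
}

#' Tally expected events over the horizon
#'
#' Sums the per-cycle expected event flows into lifetime expected counts per
#' cohort, structured by event type, severity, fatality and first/recurrent
#' status.
#'
#' @param trace `nvaf_trace` from [run_cohort()]
#' @return named numeric vector of expected event counts (same keys as
#'   [event_keys()])
#' @export
tally_events <- function(trace) {
  if (ncol(trace$events) == 0L) return(stats::setNames(numeric(0), character(0)))
  colSums(trace$events)
}

#' Expected person-cycles by state
#'
#' Occupancy summed over cycle starts (optionally half-cycle corrected),
#' i.e. expected person-cycles spent in each state.
#'
#' @param trace `nvaf_trace`
#' @param half_cycle average adjacent cycle-start occupancies (trapezoid)
#' @return cycles x states matrix of effective occupancy used for accrual
#' @keywords internal
accrual_occupancy <- function(trace, half_cycle = FALSE) {
  n <- nrow(trace$occupancy) - 1L
  if (half_cycle)
    (trace$occupancy[seq_len(n), , drop = FALSE] +
       trace$occupancy[seq_len(n) + 1L, , drop = FALSE]) / 2
  else
    trace$occupancy[seq_len(n), , drop = FALSE]
}
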