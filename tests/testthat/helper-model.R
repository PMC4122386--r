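# Shared fixtures: the reference parameter set and its base-case fit are
# deterministic, so they are computed once per test run.

.fixture_cache <- new.env(parent = emptyenv())

ref_params <- function() {
  if (is.null(.fixture_cache$params))
    .fixture_cache$params <- reference_parameters()
  .fixture_cache$params
}

ref_fit <- function() {
  if (is.null(.fixture_cache$fit))
    .fixture_cache$fit <- nvaf_ce(ref_params())
  .fixture_cache$fit
}

# micro-step compounding oracle for the rate -> probability conversion:
# per-step event chance h*dt compounded over n sub-steps of the cycle
micro_step_probability <- function(rate, cycle_weeks, n = 1e4,
                                   weeks_per_year = 52.18) {
  dt <- (cycle_weeks / weeks_per_year) / n
  1 - (1 - (rate / 100) * dt)^n
}

# micro-step enumeration for two competing exits: at each sub-step the
# process can take exit 1, exit 2 or survive; accumulates cause-specific
# absorption probabilities exhaustively
micro_step_competing <- function(h1, h2, cycle_weeks, n = 2e4,
                                 weeks_per_year = 52.18) {
  dt <- (cycle_weeks / weeks_per_year) / n
  alive <- 1; p1 <- 0; p2 <- 0
  for (i in seq_len(n)) {
    p1 <- p1 + alive * h1 * dt
    p2 <- p2 + alive * h2 * dt
    alive <- alive * (1 - (h1 + h2) * dt)
  }
  c(p1 = p1, p2 = p2, stay = alive)
}

# individual-level Monte-Carlo microsimulation of a transition model:
# trajectories are propagated as multinomial counts per (cycle, state)
microsimulate <- function(model, n_traj, seed = 1L) {
  set.seed(seed)
  S <- length(model$states)
  counts <- matrix(0L, length(model$cycle_key) + 1L, S,
                   dimnames = list(NULL, model$states))
  counts[1L, model$start_state] <- n_traj
  for (c in seq_along(model$cycle_key)) {
    P <- model$P[[model$cycle_key[c]]]
    nxt <- numeric(S)
    for (s in which(counts[c, ] > 0L))
      nxt <- nxt + stats::rmultinom(1L, counts[c, s], P[s, ])[, 1L]
    counts[c + 1L, ] <- nxt
  }
  counts
}

# small hand-made chain used for engine cross-checks
toy_model <- function(P, n_cycles, start = rownames(P)[1L], cycle_years = 1) {
  transition_model(rownames(P), list(P), rep(1L, n_cycles), cycle_years,
                   start)
}

# parameter set in which the two anticoagulant arms are numerically
# indistinguishable (rates, mortality, splits, costs and decrements equal)
symmetric_params <- function() {
  p <- ref_params()
  p$rates$vka <- p$rates$apixaban
  p$ttr_strata$rates$vka <- p$ttr_strata$rates$apixaban
  p$modifiers$trial_noncv_mortality$vka <- p$modifiers$trial_noncv_mortality$apixaban
  p$modifiers$stroke_severity$is$vka <- p$modifiers$stroke_severity$is$apixaban
  p$modifiers$stroke_severity$hs$vka <- p$modifiers$stroke_severity$hs$apixaban
  p$utilities$treatment_decrements$vka <- p$utilities$treatment_decrements$apixaban
  p$costs$inr_monitoring_per_cycle <- 0
  p$costs$drug_per_cycle$acenocoumarol <- p$costs$drug_per_cycle$apixaban
  p$costs$drug_per_cycle$phenprocoumon <- p$costs$drug_per_cycle$apixaban
  as_nvaf_parameters(unclass(p))
}
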