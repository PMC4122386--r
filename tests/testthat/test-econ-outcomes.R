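test_that("joint-state utility combines AF and event utilities", {
  expect_equal(joint_state_utility(0.77, 1, "multiplicative"), 0.77)
  expect_equal(joint_state_utility(0.8, 0.5, "multiplicative"), 0.40)
  expect_equal(joint_state_utility(0.8, 0.5, "minimum"), 0.5)
  expect_lte(joint_state_utility(0.8, 0.5), min(0.8, 0.5))
  expect_error(joint_state_utility(0.8, 0.5, "geometric"),
               class = "nvafce_domain_error")
  expect_error(joint_state_utility(1.2, 0.5), class = "nvafce_domain_error")
})

# event-free immortal cohort: utility accrual becomes pure time alive
eventfree_params <- function(u_af = 1, cycle_weeks = 6, max_age = 110,
                             discount = 0) {
  p <- unclass(ref_params())
  for (tx in names(p$rates)) for (ev in names(p$rates[[tx]]))
    p$rates[[tx]][[ev]] <- 0
  p$modifiers$recurrence_annual <- list(post_is = 0, post_hs = 0)
  p$modifiers$trial_noncv_mortality <- list(apixaban = 0, vka = 0)
  p$life_table$male[] <- 0; p$life_table$female[] <- 0
  p$utilities$af_baseline <- u_af
  p$utilities$treatment_decrements <- list(apixaban = 0, vka = 0, asa = 0)
  p$settings$cycle_length_weeks <- cycle_weeks
  p$settings$max_age <- max_age
  p$settings$discount_rate_costs <- discount
  p$settings$discount_rate_effects <- discount
  p$cohort$cohort_size <- 1
  as_nvaf_parameters(p)
}

test_that("utility 1, no decrements, no discounting gives QALY = LY = time alive", {
  p <- eventfree_params(u_af = 1, cycle_weeks = 52.18, max_age = 71)
  arm <- evaluate_arm(p, "apixaban")
  expect_equal(arm$qaly, 1)
  expect_equal(arm$ly, 1)
})

test_that("utility 0.8 over 26.09 weeks accrues 0.4 QALYs", {
  p <- eventfree_params(u_af = 0.8, cycle_weeks = 26.09, max_age = 70.5)
  arm <- evaluate_arm(p, "apixaban")
  expect_equal(arm$qaly, 0.4)
  expect_equal(arm$ly, 0.5)
})

test_that("bleed decrements subtract decrement x duration at the event cycle", {
  p <- unclass(ref_params())
  p$settings$discount_rate_effects <- 0
  base <- as_nvaf_parameters(p)
  p$utilities$bleed_decrements$crnm <- list(decrement = 0.1, duration_weeks = 6)
  bumped <- as_nvaf_parameters(p)
  tr <- ref_fit()$arms$apixaban$trace  # same trace, only valuation changes
  q0 <- accrue_qalys(tr, base)$qaly
  q1 <- accrue_qalys(tr, bumped)$qaly
  crnm_events <- sum(tr$events[, "crnm"]) / tr$cohort_size
  old_lump <- 0.02 * 2 / 52.18
  new_lump <- 0.1 * 6 / 52.18
  expect_equal(q0 - q1, (new_lump - old_lump) * crnm_events, tolerance = 1e-9)
})

test_that("QALYs never exceed LYs and accounting is monotone", {
  fit <- ref_fit()
  for (arm in fit$arms) {
    expect_lte(arm$qaly, arm$ly)
    expect_gte(arm$qaly, 0)
    expect_equal(sum(arm$cost$breakdown), arm$cost$total, tolerance = 1e-9)
    expect_true(all(arm$cost$breakdown >= 0))
  }
  up_u <- set_param(ref_params(), "utilities.af_baseline", 0.9)
  expect_gt(evaluate_arm(up_u, "vka")$qaly, fit$arms$vka$qaly)
  up_c <- set_param(ref_params(), "costs.routine_care_per_cycle", 100)
  expect_gt(evaluate_arm(up_c, "vka")$cost$total, fit$arms$vka$cost$total)
})

test_that("INR monitoring cost accrues only on VKA person-time", {
  fit <- ref_fit()
  expect_gt(fit$arms$vka$cost$breakdown[["inr_monitoring"]], 0)
  expect_equal(fit$arms$apixaban$cost$breakdown[["inr_monitoring"]], 0)
  # zero costs everywhere give a zero breakdown
  p <- unclass(ref_params())
  p$costs$drug_per_cycle <- list(apixaban = 0, acenocoumarol = 0,
                                 phenprocoumon = 0, asa = 0)
  p$costs$routine_care_per_cycle <- 0
  p$costs$inr_monitoring_per_cycle <- 0
  for (grp in names(p$costs$acute)) p$costs$acute[[grp]][] <- 0
  p$costs$long_term_monthly$stroke[] <- 0
  p$costs$long_term_monthly$mi <- 0
  z <- accrue_costs(fit$arms$vka$trace, as_nvaf_parameters(p))
  expect_equal(z$total, 0)
})

test_that("acute event costs equal discounted event flows times unit costs", {
  p <- ref_params()
  tr <- ref_fit()$arms$vka$trace
  got <- accrue_costs(tr, p)$acute_by_event[["is_first_moderate"]]
  n <- nrow(tr$events)
  df <- discount_factor(0:(n - 1), p$settings$discount_rate_costs,
                        tr$cycle_years)
  want <- sum(df * tr$events[, "is_first_moderate"]) *
    p$costs$acute$is[["moderate"]] / tr$cohort_size
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("incremental cost-effectiveness reproduces the summary arithmetic", {
  mk <- function(cost, qaly, ly) list(arm = "x", cost = list(total = cost),
                                      qaly = qaly, ly = ly)
  ce <- compute_icer(mk(20205, 7.18, 10.44), mk(18353, 7.00, 10.26))
  expect_equal(ce$d_cost, 1852)
  expect_equal(ce$d_qaly, 0.18, tolerance = 1e-12)
  expect_identical(ce$dominance, "tradeoff")
  # ratio of the rounded published cells, distinct from unrounded internals
  expect_lt(abs(ce$icer_per_qaly - 10289), 1)
  eq <- compute_icer(mk(100, 1, 2), mk(100, 1, 2))
  expect_identical(eq$dominance, "equal")
  expect_true(is.na(eq$icer_per_qaly))
  expect_identical(compute_icer(mk(90, 2, 3), mk(100, 1, 2))$dominance,
                   "dominant")
  expect_identical(compute_icer(mk(110, 1, 2), mk(100, 2, 3))$dominance,
                   "dominated")
  # equal effects, higher cost: label only, no ratio
  ties <- compute_icer(mk(110, 1, 2), mk(100, 1, 2))
  expect_identical(ties$dominance, "dominated")
  expect_true(is.na(ties$icer_per_qaly))
})
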