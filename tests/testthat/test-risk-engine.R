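test_that("rate-to-probability conversion matches the compounding oracle", {
  expect_equal(rate_to_cycle_probability(0, 6), 0)
  expect_equal(rate_to_cycle_probability(50, 52.18), 1 - exp(-0.5),
               tolerance = 1e-4)
  expect_lt(abs(rate_to_cycle_probability(1.787, 6) -
                  micro_step_probability(1.787, 6)), 1e-6)
  for (r in seq(0, 50, length.out = 11))
    expect_lt(abs(rate_to_cycle_probability(r, 6) -
                    micro_step_probability(r, 6)), 1e-6)
  expect_error(rate_to_cycle_probability(-1, 6), class = "nvafce_domain_error")
  expect_error(rate_to_cycle_probability(1, 0), class = "nvafce_domain_error")
})

test_that("CHADS2 weighting is the case-mix mean of per-score rates", {
  rates <- c(`1` = 2.8, `2` = 4.0, `3` = 5.9, `4` = 8.5, `5` = 12.5,
             `6` = 18.2, `7` = 26.0)
  point <- c(`2` = 1)
  expect_equal(chads2_weighted_stroke_rate(point, rates), 4.0)
  w <- c(`1` = 7, `2` = 27, `3` = 25, `4` = 20, `5` = 12, `6` = 7, `7` = 2)
  # brute-force summation loop as the cross-check
  acc <- 0
  for (s in names(w)) acc <- acc + (w[[s]] / sum(w)) * rates[[s]]
  expect_equal(chads2_weighted_stroke_rate(w, rates), acc)
  uni <- stats::setNames(rep(1, 7), names(rates))
  expect_equal(chads2_weighted_stroke_rate(uni, rates + 0 * rates + 3 - rates),
               3)  # constant rates give the constant back
  expect_error(chads2_weighted_stroke_rate(c(`9` = 1), rates),
               class = "nvafce_domain_error")
})

test_that("TTR policies select, average or locate stratum rates", {
  p <- ref_params()
  top <- ttr_adjust_rates(p, list(type = "stratum", label = "cTTR>=76.51%"))
  expect_equal(top$vka$ischemic_stroke, 0.831)
  expect_equal(top$apixaban$ich, 0.181)
  base <- ttr_adjust_rates(p, list(type = "population_ttr"))
  expect_equal(base$vka$ischemic_stroke, 0.967)  # stratum containing 72.48%
  expect_equal(base$vka$mi, p$rates$vka$mi)      # non-TTR events untouched
  mix <- ttr_adjust_rates(p, list(type = "equal_mix"))
  expect_equal(mix$vka$ischemic_stroke, 1.186, tolerance = 1e-12)
  expect_equal(mix$vka$ich, 0.800, tolerance = 1e-12)
  expect_equal(mix$apixaban$crnm, 2.083, tolerance = 1e-12)
  interp <- ttr_adjust_rates(p, list(type = "interpolated_ttr"))
  rng <- range(p$ttr_strata$rates$vka$ischemic_stroke)
  expect_gte(interp$vka$ischemic_stroke, rng[1])
  expect_lte(interp$vka$ischemic_stroke, rng[2])
  expect_error(ttr_adjust_rates(p, list(type = "stratum", label = "cTTR=99%")),
               class = "nvafce_domain_error")
})

test_that("age escalation compounds per decade from the baseline age", {
  expect_equal(age_escalate(2, 70, 70, 1.4), 2)
  expect_equal(age_escalate(2, 70, 80, 1.4), 2.8)
  expect_equal(age_escalate(2, 70, 93, 1), 2)
  expect_equal(age_escalate(1, 70, 75, 1.44), 1.2)
  expect_error(age_escalate(1, 70, 80, 0), class = "nvafce_domain_error")
})

test_that("ICH splits and severity partitions conserve the incoming flow", {
  expect_equal(split_ich(3, 1), c(hs = 3, other_ich = 0))
  expect_equal(split_ich(3, 0), c(hs = 0, other_ich = 3))
  expect_equal(split_ich(2.0, 0.6), c(hs = 1.2, other_ich = 0.8))
  expect_equal(unname(apply_severity_and_fatality(0.2, c(1, 0, 0, 0))),
               c(0.2, 0, 0, 0))
  expect_equal(sum(apply_severity_and_fatality(0, c(0.4, 0.35, 0.13, 0.12))), 0)
  fl <- apply_severity_and_fatality(0.01, c(0.4, 0.35, 0.13, 0.12))
  expect_equal(unname(fl), c(0.004, 0.0035, 0.0013, 0.0012))
  expect_equal(sum(fl), 0.01, tolerance = 1e-12)
  expect_error(apply_severity_and_fatality(0.1, c(0.5, 0.5, 0.5, 0.5)),
               class = "nvafce_domain_error")
})

test_that("recurrence probabilities follow the annual risks and their order", {
  mo <- ref_params()$modifiers
  expect_lt(abs(recurrence_probability("post_is", mo, 6) -
                  micro_step_probability(2.97, 6)), 1e-6)
  expect_lt(recurrence_probability("post_hs", mo, 6),
            recurrence_probability("post_is", mo, 6))
  mo0 <- mo; mo0$recurrence_annual$post_is <- 0
  expect_equal(recurrence_probability("post_is", mo0, 6), 0)
  expect_error(recurrence_probability("post_mi", mo, 6),
               class = "nvafce_domain_error")
})

test_that("post-event therapy routing encodes the treatment pathway", {
  mo <- ref_params()$modifiers
  expect_equal(post_event_therapy("is", "apixaban", mo)$stay$therapy, "apixaban")
  expect_equal(post_event_therapy("se", "vka", mo)$stay$therapy, "vka")
  expect_equal(post_event_therapy("hs", "apixaban", mo)$maintenance$p, 1)
  expect_equal(post_event_therapy("mi", "vka", mo)$maintenance$p, 1)
  expect_equal(post_event_therapy("other_discontinuation", "vka", mo)$switch_asa$p, 1)
  mo1 <- mo; mo1$post_bleed_stay$other_ich <- 1
  r <- post_event_therapy("other_ich", "apixaban", mo1)
  expect_true(r$stay$holiday)
  expect_equal(r$stay$p, 1)
  expect_false(post_event_therapy("other_mb", "apixaban", mo)$stay$holiday)
  expect_false(post_event_therapy("other_ich", "asa", mo)$stay$holiday)
  expect_error(post_event_therapy("volcano", "vka", mo),
               class = "nvafce_domain_error")
})

test_that("mortality layering composes competing hazards exactly", {
  ev <- c(stroke = 0.02)
  none <- layer_mortality(ev, other_cause_rate = 0, excess_multiplier = 1)
  expect_equal(none[["death"]], 0)
  expect_equal(sum(none), 1)
  expect_equal(none[["stroke"]], rate_to_cycle_probability(2, 6), tolerance = 1e-12)
  # excess multiplier 1 equals other-cause alone
  expect_identical(layer_mortality(ev, 5, 1), layer_mortality(ev, 5))
  # toy two-exit row against the exhaustive micro-step enumeration
  row <- layer_mortality(c(event = 0.10), other_cause_rate = 5)
  oracle <- micro_step_competing(0.10, 0.05, 6)
  expect_equal(row[["event"]], oracle[["p1"]], tolerance = 1e-6)
  expect_equal(row[["death"]], oracle[["p2"]], tolerance = 1e-6)
  expect_equal(row[["stay"]], oracle[["stay"]], tolerance = 1e-6)
  expect_error(layer_mortality(c(a = -1), 5), class = "nvafce_domain_error")
})

test_that("transition rows are stochastic for every age and arm", {
  for (arm in c("apixaban", "vka")) {
    m <- build_transition_model(ref_params(), arm)
    for (P in m$P) {
      expect_lt(max(abs(rowSums(P) - 1)), 1e-12)
      expect_true(all(P >= 0 & P <= 1))
    }
    expect_equal(unname(m$P[[1]]["dead", ]),
                 as.numeric(m$states == "dead"))
  }
})

test_that("zero rates and zero mortality give identity rows", {
  p <- unclass(ref_params())
  for (tx in names(p$rates)) for (ev in names(p$rates[[tx]]))
    p$rates[[tx]][[ev]] <- 0
  p$modifiers$trial_noncv_mortality <- list(apixaban = 0, vka = 0)
  p$modifiers$recurrence_annual <- list(post_is = 0, post_hs = 0)
  p$life_table$male[] <- 0; p$life_table$female[] <- 0
  m <- build_transition_model(as_nvaf_parameters(p), "apixaban")
  for (P in m$P) expect_equal(P["base_apixaban", "base_apixaban"], 1)
})

test_that("arms with identical inputs produce identical transition models", {
  p <- symmetric_params()
  ma <- build_transition_model(p, "apixaban")
  mv <- build_transition_model(p, "vka")
  expect_identical(ma$P, mv$P)
  expect_identical(ma$E, mv$E)
})

test_that("a baseline row reproduces the hand-composed flow product", {
  p <- ref_params()
  m <- build_transition_model(p, "apixaban")
  P <- m$P[[1]]  # age 70, trial period
  r <- p$rates$apixaban
  mo <- p$modifiers
  h <- c(is = r$ischemic_stroke, ich = r$ich, mb = r$other_mb, crnm = r$crnm,
         mi = r$mi, se = r$se, disc = r$other_discontinuation) / 100
  h <- c(h, death = mo$trial_noncv_mortality$apixaban / 100 * mo$excess_mortality$af)
  t_years <- 6 / 52.18
  H <- sum(h)
  p_any <- 1 - exp(-H * t_years)
  expect_flow <- h[["is"]] * mo$stroke_severity$is$apixaban[1] / H * p_any
  expect_equal(P["base_apixaban", "pis_first_mild_apixaban"], expect_flow,
               tolerance = 1e-12)
  # drug holiday receives the staying non-fatal other-ICH flow
  oich <- h[["ich"]] * (1 - mo$hs_fraction_of_ich) *
    (1 - mo$case_fatality$other_ich) * mo$post_bleed_stay$other_ich / H * p_any
  expect_equal(P["base_apixaban", "holiday_apixaban"], oich, tolerance = 1e-12)
})

test_that("event flows are monotone in their own rate and competing in others", {
  p <- ref_params()
  E0 <- build_transition_model(p, "apixaban")$E[[1]]
  up <- set_param(p, "rates.apixaban.ischemic_stroke", 2.0)
  E1 <- build_transition_model(up, "apixaban")$E[[1]]
  is_keys <- paste0("is_first_", c("mild", "moderate", "severe", "fatal"))
  expect_gt(sum(E1["base_apixaban", is_keys]), sum(E0["base_apixaban", is_keys]))
  # raising a competing rate weakly lowers the IS flow
  up2 <- set_param(p, "rates.apixaban.other_mb", 20)
  E2 <- build_transition_model(up2, "apixaban")$E[[1]]
  expect_lt(sum(E2["base_apixaban", is_keys]), sum(E0["base_apixaban", is_keys]))
  # total event outflow never exceeds 1
  expect_lte(max(rowSums(E2)), 1)
})

test_that("at most one recurrent stroke is representable", {
  m <- build_transition_model(ref_params(), "apixaban")
  rec_states <- grep("_rec_", m$states, value = TRUE)
  for (P in m$P) for (s in rec_states) {
    dests <- m$states[P[s, ] > 0]
    expect_true(all(dests %in% c(s, "dead")), label = s)
  }
})
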